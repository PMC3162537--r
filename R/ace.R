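# Per-family null parameters implied by (delta, f_n): for each amino acid,
# the within-family codon probabilities P_ij, the per-site mean score
# mu_i = sum_j P_ij d_ij, the per-site variance s2_i = sum_j P_ij d_ij^2 - mu_i^2,
# and its square root sigma_i.
family_null_params <- function(delta, f_n) {
  code <- attr(delta, "code")
  stopifnot_same_code(code, attr(f_n, "code"))
  d <- as.numeric(delta); p <- as.numeric(f_n)
  names(d) <- names(p) <- code$codons
  aa <- code$aa
  mu <- m2 <- stats::setNames(numeric(length(aa)), aa)
  fam <- lapply(stats::setNames(aa, aa), family_codons, code = code)
  for (a in aa) {
    cods <- fam[[a]]
    mu[a] <- sum(p[cods] * d[cods])
    m2[a] <- sum(p[cods] * d[cods]^2)
  }
  s2 <- pmax(m2 - mu^2, 0)
  list(code = code, d = d, p = p, fam = fam,
       mu = mu, s2 = s2, sigma = sqrt(s2))
}

#' Summed Codon Bias of each gene
#'
#' The Summed Codon Bias (SCB) is the sum over all codons of the gene of
#' the per-codon adaptiveness score: SCB = sum_i alpha_i with
#' alpha_i = sum_j C_ij * delta_ij, grouped by amino acid i.
#'
#' @param genes A [gene_set()].
#' @param delta A [delta_table()] covering the genes' codons.
#' @return Named numeric vector, one SCB per gene.
#' @export
scb <- function(genes, delta) {
  stopifnot_same_code(genes$code, attr(delta, "code"))
  if (any(n_codons(genes) == 0))
    stop("gene(s) with zero codons: ",
         paste(gene_ids(genes)[n_codons(genes) == 0], collapse = ", "),
         call. = FALSE)
  drop(genes$counts %*% as.numeric(delta))
}

#' Null mean and variance of the SCB
#'
#' Under the no-selection null, each site's codon is drawn independently
#' within its amino-acid family with probabilities P_ij = f_n(cdn_ij),
#' conditioned on the gene's amino-acid counts C_i. The expected SCB is
#' sum_i C_i * mu_i with mu_i = sum_j P_ij delta_ij, and because sites are
#' independent the variance is the sum over sites:
#' Var = sum_i C_i * (sum_j P_ij delta_ij^2 - mu_i^2).
#'
#' @inheritParams scb
#' @param f_n The unselected [codon_table()] providing P_ij (must be
#'   strictly positive on codons with nonzero delta).
#' @return data.frame with columns `gene_id`, `expected_scb`,
#'   `variance_scb`.
#' @export
null_moments <- function(genes, delta, f_n) {
  fp <- family_null_params(delta, f_n)
  stopifnot_same_code(genes$code, fp$code)
  A <- aa_counts(genes)
  data.frame(gene_id = gene_ids(genes),
             expected_scb = drop(A %*% fp$mu[colnames(A)]),
             variance_scb = drop(A %*% fp$s2[colnames(A)]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fit Adaptive Codon Enrichment scores to a set of genes
#'
#' The central fitting function. For each gene the observed SCB is
#' compared with its analytic null distribution given the gene's
#' amino-acid composition and the unselected codon frequencies f_n:
#' \describe{
#'   \item{ACE}{observed SCB minus expected SCB;}
#'   \item{ACE_z}{ACE divided by the null standard deviation — a Z-value
#'     testable against N(0,1);}
#'   \item{ACE_u}{ACE normalized per informative codon, dividing by
#'     sum_i C_i * sigma_i so that amino acids contribute according to the
#'     variance they carry (not simply by protein length).}
#' }
#' Genes with zero null variance (e.g. when f_o = f_n, or a gene of only
#' Met/Trp codons) get ACE = 0 with ACE_z and ACE_u set to `NA` — a
#' signal, not an error. Met and Trp, having single codons, contribute
#' nothing to any score, so their inclusion or exclusion is irrelevant.
#'
#' The per-gene error variance (the sampling variance the SCB would have
#' if the expected codon frequencies equalled the gene's observed
#' frequencies) supports two-sample t-tests between genes via
#' [gene_ttest()].
#'
#' @param genes A [gene_set()].
#' @param f_o Optimized-reference [codon_table()] (ignored when `delta` is
#'   given).
#' @param f_n Unselected-reference [codon_table()]; provides the null
#'   probabilities P_ij.
#' @param delta Optionally, a precomputed [delta_table()].
#' @param u_method How ACE_u pools across amino acids: `"pooled-sd"`
#'   (default; scalar divisor sum_i C_i sigma_i, the form consistent with
#'   defining the ACE_u error variance as the ACE error variance divided by
#'   the squared denominator) or `"mean-z"` (mean of per-family Z-values,
#'   (1/N) sum_i (alpha_i - C_i mu_i)/sigma_i over informative families).
#' @return An object of class `"ace_fit"`; its `results` element is a
#'   data.frame with one row per gene (`gene_id`, `n_codons`,
#'   `n_informative`, `scb`, `expected_scb`, `variance_scb`, `ace`,
#'   `ace_z`, `ace_u`, `error_variance`, `error_variance_u`). Methods:
#'   `print`, `summary` (genome-wide ACE chi-square), `coef`, `residuals`,
#'   `plot`, `simulate`.
#' @examples
#' f_n <- codon_table(c(AAA = 0.75, AAG = 0.25), fill = "uniform")
#' f_o <- codon_table(c(AAA = 0.5, AAG = 0.5), role = "f_o", fill = "uniform")
#' g <- gene_set(c(AAA = 2, AAG = 2), gene_ids = "toy")
#' fit <- ace(g, f_o = f_o, f_n = f_n)
#' fit$results$ace_z  # about 1.155
#' @export
ace <- function(genes, f_o = NULL, f_n, delta = NULL,
                u_method = c("pooled-sd", "mean-z")) {
  u_method <- match.arg(u_method)
  if (is.null(delta)) {
    if (is.null(f_o)) stop("supply either f_o or delta", call. = FALSE)
    delta <- delta_table(f_o, f_n)
  }
  fp <- family_null_params(delta, f_n)
  stopifnot_same_code(genes$code, fp$code)
  C <- genes$counts
  A <- aa_counts(genes)
  aa <- colnames(A)
  obs <- drop(C %*% fp$d)
  expected <- drop(A %*% fp$mu[aa])
  varscb <- drop(A %*% fp$s2[aa])
  informative <- names(fp$s2)[fp$s2 > 0]
  n_informative <- as.integer(round(rowSums(A[, informative, drop = FALSE])))
  ace_v <- obs - expected
  z <- ifelse(varscb > 0, ace_v / sqrt(varscb), NA_real_)
  denom <- drop(A %*% fp$sigma[aa])
  # error variance: Var[SCB] evaluated at the gene's own observed
  # within-family frequencies (linear in the amino-acid counts)
  evar <- numeric(nrow(C))
  alpha_minus_mean_z <- numeric(nrow(C))
  for (a in degenerate_aas(genes$code)) {
    cods <- fp$fam[[a]]
    Ai <- A[, a]
    t1 <- drop(C[, cods, drop = FALSE] %*% (fp$d[cods]^2))
    s1 <- drop(C[, cods, drop = FALSE] %*% fp$d[cods])
    has <- Ai > 0
    evar[has] <- evar[has] + t1[has] - s1[has]^2 / Ai[has]
    if (fp$sigma[a] > 0)
      alpha_minus_mean_z <- alpha_minus_mean_z +
        (s1 - Ai * fp$mu[a]) / fp$sigma[a]
  }
  u <- if (u_method == "pooled-sd") {
    ifelse(denom > 0, ace_v / denom, NA_real_)
  } else {
    ifelse(n_informative > 0, alpha_minus_mean_z / n_informative, NA_real_)
  }
  evar_u <- ifelse(denom > 0, evar / denom^2, NA_real_)
  results <- data.frame(
    gene_id = gene_ids(genes),
    n_codons = as.integer(round(n_codons(genes))),
    n_informative = n_informative,
    scb = obs, expected_scb = expected, variance_scb = varscb,
    ace = ace_v, ace_z = z, ace_u = u,
    error_variance = evar, error_variance_u = evar_u,
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(results = results, delta = delta, f_n = f_n,
                 aa_counts = A, u_method = u_method, call = match.call()),
            class = "ace_fit")
}

#' @export
print.ace_fit <- function(x, ...) {
  r <- x$results
  cat("ACE fit: ", nrow(r), " gene(s)\n", sep = "")
  ok <- !is.na(r$ace_z)
  if (any(ok))
    cat(sprintf("  ACE_z mean %.3f, var %.3f; ACE chi2 %.3f (n = %d)\n",
                mean(r$ace_z[ok]), stats::var(r$ace_z[ok]),
                mean(r$ace_z[ok]^2), sum(ok)))
  if (any(!ok))
    cat("  ", sum(!ok), " gene(s) with zero null variance (ACE_z undefined)\n",
        sep = "")
  invisible(x)
}

#' @export
summary.ace_fit <- function(object, ...) {
  r <- object$results
  gs <- ace_chi2(object)
  out <- list(n_genes = nrow(r), chi2 = gs,
              ace_u = stats::quantile(r$ace_u, na.rm = TRUE))
  class(out) <- "summary.ace_fit"
  out
}

#' @export
print.summary.ace_fit <- function(x, ...) {
  cat("ACE fit over ", x$n_genes, " gene(s)\n", sep = "")
  print(x$chi2)
  cat("ACE_u quantiles:\n")
  print(round(x$ace_u, 4))
  invisible(x)
}

#' @export
coef.ace_fit <- function(object,
                         type = c("ace_u", "ace", "ace_z", "scb"), ...) {
  type <- match.arg(type)
  stats::setNames(object$results[[type]], object$results$gene_id)
}

#' @export
residuals.ace_fit <- function(object, ...) {
  stats::setNames(object$results$ace, object$results$gene_id)
}

#' @export
plot.ace_fit <- function(x, ...) {
  z <- x$results$ace_z
  z <- z[!is.na(z)]
  graphics::hist(z, breaks = "FD", freq = FALSE,
                 main = "ACE_z against the standard normal null",
                 xlab = "ACE_z", ...)
  xs <- seq(min(z), max(z), length.out = 256)
  graphics::lines(xs, stats::dnorm(xs), lwd = 2)
  invisible(x)
}

#' Error variance of the ACE
#'
#' The sampling variance the SCB would have if the expected codon
#' frequencies were the gene's own observed within-family frequencies;
#' used as the per-gene error variance in [gene_ttest()]. Linear in the
#' codon counts.
#'
#' @inheritParams scb
#' @return Named numeric vector, one value per gene.
#' @export
error_variance <- function(genes, delta) {
  code <- genes$code
  stopifnot_same_code(code, attr(delta, "code"))
  d <- as.numeric(delta); names(d) <- code$codons
  C <- genes$counts
  A <- aa_counts(genes)
  evar <- numeric(nrow(C))
  for (a in degenerate_aas(code)) {
    cods <- family_codons(code, a)
    Ai <- A[, a]
    t1 <- drop(C[, cods, drop = FALSE] %*% (d[cods]^2))
    s1 <- drop(C[, cods, drop = FALSE] %*% d[cods])
    has <- Ai > 0
    evar[has] <- evar[has] + t1[has] - s1[has]^2 / Ai[has]
  }
  stats::setNames(evar, gene_ids(genes))
}

#' Compare the codon selection of two genes by t-test
#'
#' Welch-style two-independent-sample t-test on the ACE_u values of two
#' genes, using each gene's ACE_u error variance; degrees of freedom by
#' the Welch–Satterthwaite form with each gene's informative-codon count
#' as its sample size.
#'
#' @param fit An [ace()] fit.
#' @param a,b Gene identifiers (or row indices) within the fit.
#' @return List with `t`, `df`, `p_value` (two-sided), and the two ACE_u
#'   values.
#' @export
gene_ttest <- function(fit, a, b) {
  stopifnot(inherits(fit, "ace_fit"))
  r <- fit$results
  rownames(r) <- r$gene_id
  pick <- function(g) if (is.character(g)) r[g, ] else r[as.integer(g), ]
  ra <- pick(a); rb <- pick(b)
  if (any(is.na(c(ra$ace_u, rb$ace_u))))
    stop("ACE_u undefined for one of the genes", call. = FALSE)
  v1 <- ra$error_variance_u; v2 <- rb$error_variance_u
  if (!isTRUE(v1 > 0) || !isTRUE(v2 > 0))
    stop("both genes need positive ACE_u error variance", call. = FALSE)
  tt <- (ra$ace_u - rb$ace_u) / sqrt(v1 + v2)
  n1 <- ra$n_informative; n2 <- rb$n_informative
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = tt, df = df, p_value = 2 * stats::pt(-abs(tt), df),
       ace_u = stats::setNames(c(ra$ace_u, rb$ace_u),
                               c(ra$gene_id, rb$gene_id)))
}

#' Genome-wide ACE chi-square summary
#'
#' The mean of the squared per-gene ACE_z values. Because each ACE_z is
#' approximately standard normal under the no-selection null, the mean of
#' their squares approaches 1.0 in the absence of codon selection; values
#' above 1 measure genome-wide codon selection. A departure Z-statistic is
#' reported from the normal approximation to the mean of n chi-square(1)
#' variables: Z = (chi2 - 1) * sqrt(n/2), with a one-sided upper p-value.
#'
#' @param x An [ace()] fit, or a numeric vector of ACE_z values.
#' @param label Optional gene-set label recorded in the summary.
#' @return Object of class `"ace_chi2"`: list with `ace_chi2`, `n_genes`,
#'   `departure_z`, `p_value`, `z_scores`, `label`.
#' @export
ace_chi2 <- function(x, label = NULL) {
  z <- if (inherits(x, "ace_fit")) x$results$ace_z else as.numeric(x)
  if (length(z) == 0) stop("no genes supplied", call. = FALSE)
  if (all(is.na(z)))
    stop("ACE_z undefined for every gene", call. = FALSE)
  if (anyNA(z)) {
    warning(sum(is.na(z)), " gene(s) with undefined ACE_z dropped")
    z <- z[!is.na(z)]
  }
  chi2 <- mean(z^2)
  n <- length(z)
  dz <- (chi2 - 1) * sqrt(n / 2)
  structure(list(ace_chi2 = chi2, n_genes = n, departure_z = dz,
                 p_value = stats::pnorm(dz, lower.tail = FALSE),
                 z_scores = z, label = label %||% "gene set"),
            class = "ace_chi2")
}

#' @export
print.ace_chi2 <- function(x, ...) {
  cat(sprintf("ACE chi2 = %.3f over %d genes (%s); departure Z = %.1f, one-sided P = %.3g\n",
              x$ace_chi2, x$n_genes, x$label, x$departure_z, x$p_value))
  invisible(x)
}
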