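# Deterministic per-gene seed: a string hash of the gene id folded into the
# top-level seed, so per-gene replicate streams do not depend on the order
# in which genes are processed. Kept below 2^31 - 1.
derive_seed <- function(seed, gene_id) {
  h <- 5381
  for (b in utf8ToInt(as.character(gene_id)))
    h <- (h * 33 + b) %% 2147483647
  as.integer((as.numeric(seed) + h) %% 2147483647)
}

#' Monte Carlo null distribution of a gene's SCB
#'
#' Resamples the gene's codons under the null: the amino-acid composition
#' is held fixed and each site's codon is drawn independently within its
#' family from P_ij = f_n(cdn_ij). The replicate SCBs validate the
#' analytic moments of [null_moments()] and, via [normality_check()], the
#' normal approximation behind ACE_z. Deterministic given `seed` (per-gene
#' streams are derived from the seed and the gene id, independent of
#' processing order).
#'
#' @param genes A one-gene [gene_set()] (or use [simulate.ace_fit()] for a
#'   whole fit).
#' @param delta A [delta_table()].
#' @param f_n Unselected [codon_table()].
#' @param n_reps Number of Monte Carlo replicates (>= 2); 2000 is the
#'   conventional choice.
#' @param seed Integer seed.
#' @return Object of class `"null_sample"`: list with `gene_id`, `scb`
#'   (replicates), `seed`, `mean`, `variance`, `skewness`, `kurtosis`.
#' @export
mc_null <- function(genes, delta, f_n, n_reps = 2000L, seed = 1L) {
  if (length(genes) != 1L)
    stop("mc_null() operates on a single gene; subset the gene set",
         call. = FALSE)
  if (n_reps < 2L) stop("n_reps must be at least 2", call. = FALSE)
  fp <- family_null_params(delta, f_n)
  stopifnot_same_code(genes$code, fp$code)
  A <- drop(aa_counts(genes))
  gid <- gene_ids(genes)
  reps <- numeric(n_reps)
  set.seed(derive_seed(seed, gid))
  for (a in names(A)) {
    Ai <- A[[a]]
    if (Ai == 0) next
    cods <- fp$fam[[a]]
    if (length(cods) == 1L) next  # delta is 0; contributes nothing
    draws <- stats::rmultinom(n_reps, Ai, fp$p[cods])
    reps <- reps + drop(crossprod(draws, fp$d[cods]))
  }
  m <- mean(reps)
  structure(list(gene_id = gid, scb = reps, seed = seed,
                 mean = m, variance = stats::var(reps),
                 skewness = sample_skewness(reps),
                 kurtosis = sample_kurtosis(reps)),
            class = "null_sample")
}

#' @export
print.null_sample <- function(x, ...) {
  cat(sprintf("Monte Carlo SCB null for %s: %d replicates; mean %.4f, var %.4f\n",
              x$gene_id, length(x$scb), x$mean, x$variance))
  invisible(x)
}

#' Monte Carlo null samples for genes of an ACE fit
#'
#' @param object An [ace()] fit.
#' @param nsim Replicates per gene (default 2000).
#' @param seed Integer seed; per-gene streams are derived from it and the
#'   gene id.
#' @param genes Gene ids to simulate (default: all genes in the fit).
#' @param ... Unused.
#' @return Named list of `"null_sample"` objects (a single object when one
#'   gene is requested).
#' @export
simulate.ace_fit <- function(object, nsim = 2000L, seed = 1L,
                             genes = NULL, ...) {
  ids <- genes %||% object$results$gene_id
  A <- object$aa_counts[ids, , drop = FALSE]
  gs_from_aa <- function(id) {
    # rebuild a counts row that reproduces the amino-acid composition;
    # the null depends on the gene only through its amino-acid counts
    fp_code <- attr(object$delta, "code")
    v <- stats::setNames(numeric(length(fp_code$codons)), fp_code$codons)
    for (a in colnames(A)) {
      if (A[id, a] > 0) v[family_codons(fp_code, a)[1]] <- A[id, a]
    }
    gene_set(v, code = fp_code, gene_ids = id)
  }
  out <- lapply(ids, function(id)
    mc_null(gs_from_aa(id), object$delta, object$f_n,
            n_reps = nsim, seed = seed))
  names(out) <- ids
  if (length(out) == 1L) out[[1]] else out
}

sample_skewness <- function(x) {
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  mean((x - m)^3) / m2^1.5
}

sample_kurtosis <- function(x) {
  m <- mean(x)
  mean((x - m)^4) / mean((x - m)^2)^2
}

#' D'Agostino–Pearson omnibus normality check
#'
#' Tests the replicate SCBs of a Monte Carlo null sample (or any numeric
#' vector) for departure from normality by combining the D'Agostino
#' skewness test and the Anscombe–Glynn kurtosis test into the K-squared
#' omnibus statistic, referred to chi-square with 2 degrees of freedom.
#' Used to flag genes whose SCB null is not well approximated by a normal
#' (typically short genes in strongly composition-biased genomes).
#'
#' @param sample A `"null_sample"` from [mc_null()], or a numeric vector
#'   of at least 20 values.
#' @return List with `skewness`, `kurtosis` (non-excess), `k2`, `p_value`.
#' @export
normality_check <- function(sample) {
  x <- if (inherits(sample, "null_sample")) sample$scb else as.numeric(sample)
  n <- length(x)
  if (n < 20L) stop("at least 20 replicates required", call. = FALSE)
  if (stats::var(x) == 0) stop("sample is constant; test degenerate", call. = FALSE)
  g1 <- sample_skewness(x)
  b2 <- sample_kurtosis(x)
  # D'Agostino (1970) transformed skewness
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  dd <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- dd * log(y / alpha + sqrt((y / alpha)^2 + 1))
  # Anscombe & Glynn (1983) transformed kurtosis
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  aa <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  z2 <- ((1 - 2 / (9 * aa)) -
           ((1 - 2 / aa) / (1 + xk * sqrt(2 / (aa - 4))))^(1 / 3)) /
    sqrt(2 / (9 * aa))
  k2 <- z1^2 + z2^2
  list(skewness = g1, kurtosis = b2, k2 = k2,
       p_value = stats::pchisq(k2, df = 2, lower.tail = FALSE))
}
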