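#' Codon Adaptation Index
#'
#' Sharp–Li CAI: relative adaptiveness weights are w_ij = RSCU_ij /
#' max_j RSCU_ij computed from a reference gene set (zero-count reference
#' codons get a 0.5 pseudocount before RSCU), and a gene's CAI is the
#' geometric mean of w over its codons, ignoring methionine and
#' tryptophan. Accumulated in natural logs to avoid underflow on long
#' genes.
#'
#' @param genes A [gene_set()] to score.
#' @param reference A [gene_set()] of reference (highly expressed) genes.
#' @return Named numeric vector of CAI values in (0, 1].
#' @export
cai <- function(genes, reference) {
  code <- genes$code
  stopifnot_same_code(code, reference$code)
  ref <- colSums(reference$counts)
  w <- stats::setNames(numeric(length(code$codons)), code$codons)
  for (a in code$aa) {
    cods <- family_codons(code, a)
    cnt <- ref[cods]
    cnt[cnt == 0] <- 0.5
    w[cods] <- cnt / max(cnt)  # RSCU ratio reduces to count ratio
  }
  single <- names(code$codon_aa)[code$synonym_count[code$codon_aa] == 1L]
  keep <- setdiff(code$codons, single)
  Ck <- genes$counts[, keep, drop = FALSE]
  tot <- rowSums(Ck)
  if (any(tot == 0))
    stop("gene(s) with only single-codon (Met/Trp) amino acids: ",
         paste(gene_ids(genes)[tot == 0], collapse = ", "), call. = FALSE)
  exp(drop(Ck %*% log(w[keep])) / tot)
}

#' Length-normalized Summed Codon Bias (GCB form)
#'
#' The SCB divided by the gene's codon count: the mean per-codon
#' adaptiveness score.
#'
#' @inheritParams scb
#' @return Named numeric vector.
#' @export
gcb <- function(genes, delta) {
  scb(genes, delta) / n_codons(genes)
}

# Wright-style class-averaged homozygosity -> effective codon number.
# f_hat_by_family: function(aa, counts_in_family) -> F estimate or NA.
enc_from_fhat <- function(genes, fhat_fun) {
  code <- genes$code
  deg <- code$synonym_count
  classes <- list(`2` = 9, `3` = 1, `4` = 5, `6` = 3)  # families per class
  out <- stats::setNames(numeric(length(genes)), gene_ids(genes))
  for (g in seq_len(length(genes))) {
    cnt <- genes$counts[g, ]
    fbar <- stats::setNames(rep(NA_real_, 4), names(classes))
    for (k in names(classes)) {
      aas <- names(deg)[deg == as.integer(k)]
      fs <- vapply(aas, function(a) {
        fam <- cnt[family_codons(code, a)]
        n <- sum(fam)
        if (n < 2) return(NA_real_)
        fhat_fun(fam, n, length(fam))
      }, numeric(1))
      fs <- fs[!is.na(fs) & fs > 0]
      if (length(fs) > 0) fbar[k] <- mean(fs)
    }
    if (all(is.na(fbar)))
      stop("too few codons to estimate any homozygosity class for gene ",
           gene_ids(genes)[g], call. = FALSE)
    # impute a missing class mean by the average of the available ones
    fbar[is.na(fbar)] <- mean(fbar, na.rm = TRUE)
    val <- 2 + 9 / fbar["2"] + 1 / fbar["3"] + 5 / fbar["4"] + 3 / fbar["6"]
    out[g] <- min(max(val, 20), 61)
  }
  out
}

#' Effective Number of Codons (ENC)
#'
#' Wright's estimator: per-family homozygosity
#' F = (n * sum p^2 - 1)/(n - 1) is averaged within degeneracy classes
#' (with Ser/Leu/Arg treated as six-fold amino-acid families), a missing
#' class is imputed by the mean of the available classes, and
#' ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6, clamped to [20, 61].
#'
#' @param genes A [gene_set()].
#' @return Named numeric vector in [20, 61].
#' @export
enc <- function(genes) {
  enc_from_fhat(genes, function(fam, n, m) {
    (n * sum((fam / n)^2) - 1) / (n - 1)
  })
}

#' Background-corrected effective number of codons (ENC')
#'
#' Novembre's correction: the family homozygosity is replaced by
#' F' = (chi2 + n - m) / (m * (n - 1)), where chi2 is the Pearson
#' chi-square of the family's observed codon counts against the expected
#' frequencies from the unselected table f_n, m the family size and n the
#' family codon count; class averaging and the 2 + 9/F2 + 1/F3 + 5/F4 +
#' 3/F6 combination as in [enc()].
#'
#' @param genes A [gene_set()].
#' @param f_n Unselected [codon_table()] of expected frequencies.
#' @return Named numeric vector in [20, 61].
#' @export
enc_prime <- function(genes, f_n) {
  stopifnot_same_code(genes$code, attr(f_n, "code"))
  p <- as.numeric(f_n); names(p) <- genes$code$codons
  enc_from_fhat(genes, function(fam, n, m) {
    e <- p[names(fam)]
    e <- e / sum(e)
    chi2 <- sum((fam - n * e)^2 / (n * e))
    (chi2 + n - m) / (m * (n - 1))
  })
}

#' Per-codon chi-square of codon usage against the background
#'
#' Pearson chi-square of each gene's within-family codon counts against
#' the counts expected from f_n, summed over families present in the gene
#' and divided by the gene's total codon count — a scale-free ranking
#' score for "most biased" genes.
#'
#' @inheritParams enc_prime
#' @return Named numeric vector (>= 0).
#' @export
codon_chi2 <- function(genes, f_n) {
  code <- genes$code
  stopifnot_same_code(code, attr(f_n, "code"))
  p <- as.numeric(f_n); names(p) <- code$codons
  A <- aa_counts(genes)
  tot <- numeric(length(genes))
  for (a in code$aa) {
    cods <- family_codons(code, a)
    if (length(cods) == 1L) next
    Ai <- A[, a]
    has <- Ai > 0
    if (!any(has)) next
    E <- outer(Ai[has], p[cods])
    O <- genes$counts[has, cods, drop = FALSE]
    tot[has] <- tot[has] + rowSums((O - E)^2 / E)
  }
  stats::setNames(tot / n_codons(genes), gene_ids(genes))
}

# per-sequence mononucleotide and overlapping dinucleotide counts
nt_counts <- function(sequences) {
  x <- Biostrings::DNAStringSet(sequences)
  list(mono = Biostrings::oligonucleotideFrequency(x, 1)[, c("A", "C", "G", "T"), drop = FALSE],
       di = Biostrings::oligonucleotideFrequency(x, 2)[,
         paste0(rep(c("A", "C", "G", "T"), each = 4), c("A", "C", "G", "T")),
         drop = FALSE])
}

rho_from_counts <- function(mono, di) {
  fm <- mono / sum(mono)
  fd <- di / sum(di)
  # expected f(X)f(Y) in the same XY order as the dinucleotide columns
  ex <- as.vector(t(outer(fm, fm)))
  names(ex) <- paste0(rep(names(fm), each = 4), names(fm))
  ex <- ex[names(fd)]
  # a dinucleotide whose bases are absent has relative abundance 0
  ifelse(ex > 0, fd / ex, 0)
}

#' Karlin dinucleotide signature distance
#'
#' The mean absolute difference in dinucleotide relative abundances
#' rho(XY) = f(XY) / (f(X) f(Y)) between each gene and a reference pool:
#' delta* = (1/16) * sum_XY |rho_gene(XY) - rho_ref(XY)|. Computed on the
#' coding strand only, since inputs are strand-resolved CDS. A marker of
#' compositional atypicality (e.g. recent lateral transfer).
#'
#' @param genes A [gene_set()] with retained sequences.
#' @param reference Either a [gene_set()] with sequences whose pool defines
#'   the genome signature, or `NULL` to use the pooled `genes` themselves.
#' @return Named numeric vector (>= 0).
#' @export
karlin_delta_star <- function(genes, reference = NULL) {
  if (is.null(genes$sequences))
    stop("dinucleotide signature requires retained sequences", call. = FALSE)
  if (any(nchar(genes$sequences) < 2))
    stop("sequence(s) shorter than 2 bases", call. = FALSE)
  nc <- nt_counts(genes$sequences)
  ref <- if (is.null(reference)) {
    list(mono = colSums(nc$mono), di = colSums(nc$di))
  } else {
    if (is.null(reference$sequences))
      stop("reference gene set has no sequences", call. = FALSE)
    rc <- nt_counts(reference$sequences)
    list(mono = colSums(rc$mono), di = colSums(rc$di))
  }
  rho_ref <- rho_from_counts(ref$mono, ref$di)
  out <- vapply(seq_len(length(genes)), function(g) {
    rho_g <- rho_from_counts(nc$mono[g, ], nc$di[g, ])
    mean(abs(rho_g - rho_ref))
  }, numeric(1))
  stats::setNames(out, gene_ids(genes))
}

#' Karlin's B metric of codon-usage difference
#'
#' B(gene | reference) = sum_aa p_aa(gene) * sum_j |f_gene(cdn_ij) -
#' f_ref(cdn_ij)|, where p_aa is the amino acid's share of the gene's
#' codons and f are within-family codon frequencies. Zero iff the gene's
#' within-family frequencies match the reference for every amino acid it
#' uses; invariant to gene length at fixed frequencies.
#'
#' @param genes A [gene_set()].
#' @param reference A [codon_table()] of reference frequencies.
#' @return Named numeric vector (>= 0).
#' @export
karlin_b <- function(genes, reference) {
  code <- genes$code
  stopifnot_same_code(code, attr(reference, "code"))
  fr <- as.numeric(reference); names(fr) <- code$codons
  A <- aa_counts(genes)
  tot <- n_codons(genes)
  out <- numeric(length(genes))
  for (a in code$aa) {
    cods <- family_codons(code, a)
    Ai <- A[, a]
    has <- Ai > 0
    if (!any(has)) next
    fg <- genes$counts[has, cods, drop = FALSE] / Ai[has]
    dist <- rowSums(abs(fg - matrix(fr[cods], sum(has), length(cods),
                                    byrow = TRUE)))
    out[has] <- out[has] + (Ai[has] / tot[has]) * dist
  }
  stats::setNames(out, gene_ids(genes))
}
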