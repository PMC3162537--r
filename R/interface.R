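#' Correlate codon-selection scores with expression data
#'
#' Pearson correlation between a per-gene codon statistic and
#' log-transformed expression values over genes shared by identifier.
#' Non-positive expression values are dropped (their count is reported),
#' since the log transform requires positive abundances. Spearman rank
#' correlation is available for comparison but typically weaker.
#'
#' @param scores An [ace()] fit, or a named numeric vector of per-gene
#'   scores.
#' @param expression A two-column data.frame (gene id, value) or the path
#'   to such a TSV.
#' @param statistic Which fit column to use when `scores` is an `ace_fit`
#'   (default `"ace_u"`).
#' @param method `"pearson"` (on ln expression; default) or `"spearman"`.
#' @return List with `r`, `n`, `n_dropped_nonpositive`, `method`,
#'   `statistic`.
#' @export
correlate_expression <- function(scores, expression, statistic = "ace_u",
                                 method = c("pearson", "spearman")) {
  method <- match.arg(method)
  s <- if (inherits(scores, "ace_fit")) {
    stats::setNames(scores$results[[statistic]], scores$results$gene_id)
  } else {
    statistic <- "score"
    scores
  }
  if (is.character(expression) && length(expression) == 1L)
    expression <- utils::read.table(expression, sep = "\t", header = FALSE,
                                    stringsAsFactors = FALSE,
                                    col.names = c("gene_id", "value"))
  ev <- stats::setNames(as.numeric(expression[[2]]),
                        as.character(expression[[1]]))
  shared <- intersect(names(s)[!is.na(s)], names(ev))
  dropped <- sum(ev[shared] <= 0 | is.na(ev[shared]))
  shared <- shared[ev[shared] > 0 & !is.na(ev[shared])]
  if (length(shared) < 3)
    stop("fewer than 3 genes shared between scores and expression",
         call. = FALSE)
  r <- if (method == "pearson") {
    stats::cor(s[shared], log(ev[shared]))
  } else {
    stats::cor(s[shared], ev[shared], method = "spearman")
  }
  list(r = r, n = length(shared), n_dropped_nonpositive = dropped,
       method = method, statistic = statistic)
}

#' Write per-gene ACE results and the genome summary as TSV
#'
#' `write_ace_results()` writes one row per gene (gene_id, n_codons,
#' n_informative, scb, expected_scb, variance_scb, ace, ace_z, ace_u,
#' error_variance); `write_genome_summary()` writes the gene-set-level
#' ACE chi-square line (label, n_genes, ace_chi2, departure_z).
#'
#' @param fit An [ace()] fit.
#' @param summary An [ace_chi2()] object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ace_results <- function(fit, path) {
  cols <- c("gene_id", "n_codons", "n_informative", "scb", "expected_scb",
            "variance_scb", "ace", "ace_z", "ace_u", "error_variance")
  utils::write.table(fit$results[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_ace_results
#' @export
write_genome_summary <- function(summary, path) {
  df <- data.frame(set = summary$label, n_genes = summary$n_genes,
                   ace_chi2 = summary$ace_chi2,
                   departure_z = summary$departure_z)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
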