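#' Annotation feature tables
#'
#' A light container for annotation features, used for two things only:
#' looking up translation-apparatus gene names when seeding the optimized
#' reference set ([seed_fo()]), and counting tRNA genes
#' ([count_trna_genes()]).
#'
#' `read_feature_table()` imports a GFF3 file via
#' [rtracklayer::import()]; `feature_table()` builds the same structure
#' from a data.frame with columns `type`, `gene`, `locus_tag`, `length`
#' (bp) and optionally `product`, `start`, `end`, `strand`.
#'
#' @param path Path to a GFF3 annotation file.
#' @param df A data.frame as described above.
#' @return An object of class `"feature_table"` (a data.frame).
#' @export
read_feature_table <- function(path) {
  gr <- rtracklayer::import(path)
  md <- as.data.frame(gr)
  get_col <- function(nm) if (nm %in% names(md)) as.character(md[[nm]]) else NA_character_
  feature_table(data.frame(
    type = get_col("type"),
    gene = get_col("gene"),
    locus_tag = get_col("locus_tag"),
    start = md$start, end = md$end,
    strand = as.character(md$strand),
    length = md$width,
    product = get_col("product"),
    stringsAsFactors = FALSE
  ))
}

#' @rdname read_feature_table
#' @export
feature_table <- function(df) {
  stopifnot(is.data.frame(df))
  needed <- c("type", "gene", "locus_tag", "length")
  for (nm in needed) if (!nm %in% names(df)) df[[nm]] <- NA
  if (!"product" %in% names(df)) df$product <- NA_character_
  df$length <- as.numeric(df$length)
  if (any(!is.na(df$length) & df$length <= 0))
    stop("feature lengths must be positive", call. = FALSE)
  if (all(c("start", "end") %in% names(df))) {
    bad <- !is.na(df$start) & !is.na(df$end) &
      abs(df$end - df$start) + 1 != df$length
    if (any(bad))
      stop("feature coordinates inconsistent with length for ",
           sum(bad), " feature(s)", call. = FALSE)
  }
  class(df) <- c("feature_table", "data.frame")
  df
}

#' Count tRNA genes in an annotation
#'
#' Counts structural-RNA features between 60 and 100 bp long, excluding
#' any feature identified as the selenocysteine (Sec) tRNA. This per-genome
#' count is the quantity whose species averages track genome-wide codon
#' selection.
#'
#' @param features A [feature_table()].
#' @return Integer count; 0 with a warning when the table has no RNA
#'   features at all.
#' @export
count_trna_genes <- function(features) {
  stopifnot(inherits(features, "feature_table"))
  is_rna <- grepl("RNA", features$type, ignore.case = TRUE) &
    !grepl("^mRNA$", features$type, ignore.case = TRUE)
  if (!any(is_rna)) {
    warning("no RNA features in the annotation; returning 0")
    return(0L)
  }
  rna <- features[is_rna, , drop = FALSE]
  in_range <- !is.na(rna$length) & rna$length >= 60 & rna$length <= 100
  txt <- paste(rna$gene, rna$product, rna$locus_tag)
  is_sec <- grepl("tRNA-Sec|selenocyst|\\bselC\\b|\\bSec\\b", txt,
                  ignore.case = TRUE)
  sum(in_range & !is_sec)
}
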