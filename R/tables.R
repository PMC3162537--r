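#' Build a within-family codon frequency table
#'
#' Normalizes pooled codon counts within each amino-acid family: the
#' frequency of a codon is its count divided by the total count for the
#' same amino acid. Any codon absent from the pool is assigned a
#' pseudocount (default 0.5) before normalization, so all frequencies are
#' strictly positive. The two roles are `"f_n"` (unselected, genome-wide
#' background) and `"f_o"` (optimized genes).
#'
#' @param genes A [gene_set()] whose pooled counts define the table.
#' @param role `"f_n"` or `"f_o"`.
#' @param pseudocount Non-negative count assigned to zero-count codons
#'   before normalization (default 0.5).
#' @param source Provenance text; defaults to gene and codon totals.
#' @param fill What to do when an amino-acid family with two or more
#'   synonyms has no observed codons at all: `"error"` (default; the table
#'   is unusable) or `"uniform"` (assign equal frequencies, convenient for
#'   partially specified tables).
#' @return An object of class `"codon_freq_table"`: named numeric vector
#'   over the 61 sense codons with attributes `role`, `pseudocount`,
#'   `source` and `code`.
#' @examples
#' gs <- gene_set(c(AAA = 3, AAG = 1))
#' ft <- codon_frequencies(gs, fill = "uniform")
#' ft[["AAA"]]  # 0.75
#' @export
codon_frequencies <- function(genes, role = c("f_n", "f_o"),
                              pseudocount = 0.5, source = NULL,
                              fill = c("error", "uniform")) {
  role <- match.arg(role)
  fill <- match.arg(fill)
  if (pseudocount < 0) stop("pseudocount must be non-negative", call. = FALSE)
  counts <- colSums(genes$counts)
  codon_table(counts, role = role, pseudocount = pseudocount,
              code = genes$code, fill = fill,
              source = source %||% sprintf("%d gene(s), %d codons",
                                           length(genes), sum(counts)))
}

#' Construct a codon frequency table from counts or frequencies
#'
#' Lower-level constructor behind [codon_frequencies()]; also convenient
#' for specifying tables directly (e.g. planted tables for simulation or
#' worked examples). Values are interpreted as non-negative weights and
#' normalized within each amino-acid family. Families with at least two
#' synonyms that are entirely absent raise an error unless
#' `fill = "uniform"`, in which case every unspecified or all-zero family
#' becomes uniform.
#'
#' @param x Named non-negative numeric vector (codon -> count or weight);
#'   may cover only some families when `fill = "uniform"`.
#' @inheritParams codon_frequencies
#' @param code A [genetic_code()].
#' @export
codon_table <- function(x, role = c("f_n", "f_o"), pseudocount = 0.5,
                        code = genetic_code(), source = "user-specified",
                        fill = c("error", "uniform")) {
  role <- match.arg(role)
  fill <- match.arg(fill)
  if (is.null(names(x))) stop("values must be named by codon", call. = FALSE)
  bad <- setdiff(names(x), code$codons)
  if (length(bad) > 0)
    stop("not sense codons: ", paste(bad, collapse = ", "), call. = FALSE)
  v <- stats::setNames(numeric(length(code$codons)), code$codons)
  v[names(x)] <- x
  if (any(v < 0)) stop("negative codon weights", call. = FALSE)
  out <- v
  for (aa in code$aa) {
    cods <- family_codons(code, aa)
    fam <- v[cods]
    if (sum(fam) == 0) {
      if (length(cods) == 1L || fill == "uniform") {
        out[cods] <- 1 / length(cods)
        next
      }
      stop("no observed codons for amino acid family ", aa, call. = FALSE)
    }
    fam[fam == 0] <- pseudocount
    if (any(fam == 0))
      stop("zero frequency in family ", aa,
           " (pseudocount is 0); frequencies must be strictly positive",
           call. = FALSE)
    out[cods] <- fam / sum(fam)
  }
  structure(out, role = role, pseudocount = pseudocount, source = source,
            code = code, class = "codon_freq_table")
}

#' @export
print.codon_freq_table <- function(x, ...) {
  cat("Codon frequency table (role ", attr(x, "role"),
      ", pseudocount ", attr(x, "pseudocount"), ")\n",
      "  source: ", attr(x, "source"), "\n", sep = "")
  invisible(x)
}

#' Per-codon adaptiveness scores (delta)
#'
#' The adaptiveness of codon j of amino acid i is the natural-log ratio of
#' its within-family frequency in the optimized table to that in the
#' unselected table: delta_ij = ln(f_o(cdn_ij) / f_n(cdn_ij)). The log
#' makes a gene's total codon optimization the sum of its per-codon
#' scores. Single-codon families (Met, Trp) have delta = 0, and swapping
#' the two tables negates every score.
#'
#' @param f_o,f_n [codon_table()] objects built with the same genetic code.
#' @return Object of class `"delta_table"`: named numeric vector over the
#'   61 sense codons, with `code` and `source` attributes.
#' @examples
#' f_n <- codon_table(c(AAA = 0.75, AAG = 0.25), fill = "uniform")
#' f_o <- codon_table(c(AAA = 0.5, AAG = 0.5), role = "f_o", fill = "uniform")
#' delta_table(f_o, f_n)[["AAG"]]  # log(2)
#' @export
delta_table <- function(f_o, f_n) {
  code <- attr(f_n, "code")
  stopifnot_same_code(attr(f_o, "code"), code)
  d <- log(as.numeric(f_o) / as.numeric(f_n))
  names(d) <- code$codons
  single <- code$codon_aa[code$synonym_count[code$codon_aa] == 1L]
  d[names(single)] <- 0
  structure(d, code = code,
            source = paste0("f_o: ", attr(f_o, "source"),
                            " | f_n: ", attr(f_n, "source")),
            class = "delta_table")
}

#' @export
print.delta_table <- function(x, ...) {
  cat("Delta table (ln f_o/f_n); range [",
      sprintf("%.3f", min(x)), ", ", sprintf("%.3f", max(x)), "]\n",
      "  ", attr(x, "source"), "\n", sep = "")
  invisible(x)
}

#' Normalize per-codon values for display
#'
#' For presentation tables, each amino-acid family's values are divided by
#' the family maximum, so the preferred codon reads 1.000. Frequencies are
#' normalized directly; delta scores are first mapped through `exp()` (a
#' monotone, sign-free transform), so the normalized column preserves the
#' delta ranking. Display normalization is presentation-only: all
#' computation uses the raw tables.
#'
#' @param values A `codon_freq_table`, `delta_table`, or named per-codon
#'   numeric vector covering whole families.
#' @param code A [genetic_code()] (taken from the object when available).
#' @return Named numeric vector with each family's maximum equal to 1.
#' @export
display_normalize <- function(values, code = NULL) {
  code <- code %||% attr(values, "code") %||% genetic_code()
  v <- as.numeric(values)
  names(v) <- names(values)
  if (inherits(values, "delta_table")) v <- exp(v)
  out <- v
  for (aa in code$aa) {
    cods <- intersect(family_codons(code, aa), names(v))
    if (length(cods) == 0) next
    m <- max(v[cods])
    if (m <= 0) stop("family maximum is not positive for ", aa, call. = FALSE)
    out[cods] <- v[cods] / m
  }
  out
}

#' Write / read codon score tables as TSV
#'
#' Columns: `codon`, `amino_acid`, `value`, `role`, `source`. Values are
#' written with enough precision for the round trip to agree to at least
#' 12 decimal places.
#'
#' @param x A `codon_freq_table` or `delta_table`.
#' @param path File path.
#' @param code A [genetic_code()] (for reading).
#' @return `read_codon_table()` returns a `codon_freq_table` or
#'   `delta_table` according to the stored role.
#' @export
write_codon_table <- function(x, path) {
  code <- attr(x, "code")
  role <- if (inherits(x, "delta_table")) "delta" else attr(x, "role")
  df <- data.frame(codon = names(x),
                   amino_acid = unname(code$codon_aa[names(x)]),
                   value = sprintf("%.15g", as.numeric(x)),
                   role = role,
                   source = attr(x, "source"),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_codon_table
#' @export
read_codon_table <- function(path, code = genetic_code()) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  v <- stats::setNames(as.numeric(df$value), df$codon)[code$codons]
  role <- df$role[1]
  if (identical(role, "delta")) {
    structure(v, code = code, source = df$source[1], class = "delta_table")
  } else {
    structure(v, role = role, pseudocount = NA_real_, source = df$source[1],
              code = code, class = "codon_freq_table")
  }
}
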