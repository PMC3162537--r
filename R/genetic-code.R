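#' Genetic-code model used throughout the package
#'
#' Wraps an NCBI translation table as the package's working representation:
#' the 61 sense codons in fixed alphabetical order, their amino acids
#' (one-letter code), the stop codons, and per-amino-acid synonym counts
#' (degeneracy). The default is translation table 11 (bacterial/archaeal/
#' plant plastid); table 1 (standard) is selectable for yeasts and other
#' nuclear genomes. Both share the same sense-codon-to-amino-acid mapping,
#' so degeneracy classes are identical; they differ only in start-codon
#' policy, which is irrelevant here because the first codon of every CDS is
#' dropped positionally.
#'
#' @param id NCBI translation table identifier (integer or character),
#'   passed to [Biostrings::getGeneticCode()]. Default `11`.
#' @return An object of class `"genetic_code"`: a list with elements
#'   `code_id`, `codons` (61 sense codons, alphabetical), `codon_aa`
#'   (named map codon -> amino acid), `stop_codons`, `aa` (the 20 amino
#'   acids), and `synonym_count` (named integer, N_i per amino acid).
#' @examples
#' gc <- genetic_code()
#' gc$synonym_count[["L"]]  # leucine is six-fold degenerate
#' @export
genetic_code <- function(id = 11L) {
  full <- Biostrings::getGeneticCode(as.character(id))
  stops <- sort(names(full)[full == "*"])
  sense <- sort(names(full)[full != "*"])
  codon_aa <- full[sense]
  syn <- table(codon_aa)
  structure(
    list(
      code_id = as.character(id),
      codons = sense,
      codon_aa = codon_aa,
      stop_codons = stops,
      aa = sort(unique(unname(codon_aa))),
      synonym_count = stats::setNames(as.integer(syn), names(syn))
    ),
    class = "genetic_code"
  )
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("Genetic code (NCBI table ", x$code_id, "): ",
      length(x$codons), " sense codons, stops ",
      paste(x$stop_codons, collapse = "/"), "\n", sep = "")
  invisible(x)
}

# codons of one amino acid, in table order
family_codons <- function(code, aa) {
  code$codons[code$codon_aa == aa]
}

# amino acids with >= 2 synonymous codons
degenerate_aas <- function(code) {
  names(code$synonym_count)[code$synonym_count >= 2L]
}

# 61 x 20 indicator matrix mapping codons to their amino-acid family
aa_indicator <- function(code) {
  m <- matrix(0, length(code$codons), length(code$aa),
              dimnames = list(code$codons, code$aa))
  m[cbind(code$codons, unname(code$codon_aa))] <- 1
  m
}

stopifnot_same_code <- function(a, b) {
  if (!identical(a$codons, b$codons))
    stop("objects were built with different genetic codes", call. = FALSE)
  invisible(TRUE)
}
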