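#' Default amino-acid composition for simulated genes
#'
#' An E. coli-like average protein composition (fractions over the 20
#' amino acids, one-letter code), used when a simulation does not specify
#' its own.
#'
#' @return Named numeric vector summing to 1.
#' @export
default_aa_composition <- function() {
  x <- c(A = 9.5, R = 5.5, N = 4.0, D = 5.2, C = 1.2, Q = 4.4, E = 5.8,
         G = 7.4, H = 2.2, I = 6.0, L = 10.5, K = 4.7, M = 2.8, F = 3.9,
         P = 4.4, S = 5.8, T = 5.4, W = 1.5, Y = 2.9, V = 7.1)
  x / sum(x)
}

#' Shift a codon table's wobble-position GC content
#'
#' Produces a compositionally distinct table from `f` by reweighting each
#' codon by `exp(shift)` when its third base is G or C, then renormalizing
#' within families. Used to plant an "alien" (laterally transferred-like)
#' gene class whose nucleotide and dinucleotide composition differs from
#' the background while amino-acid usage is untouched.
#'
#' @param f A [codon_table()].
#' @param shift Log-scale weight applied to GC-ending codons (positive =
#'   more GC3).
#' @return A [codon_table()] with the same role.
#' @export
gc_shift_table <- function(f, shift = 1.5) {
  code <- attr(f, "code")
  v <- as.numeric(f); names(v) <- code$codons
  gc3 <- substr(names(v), 3, 3) %in% c("G", "C")
  v[gc3] <- v[gc3] * exp(shift)
  codon_table(v, role = attr(f, "role"), pseudocount = 0,
              code = code, source = sprintf("GC3-shifted (%+.2f)", shift))
}

#' Simulate a CDS set with controlled codon-usage structure
#'
#' Generates genes under the stochastic sampling model the ACE null
#' assumes: each gene's amino acids are drawn iid from a composition, and
#' each site's codon is drawn independently within its family from the
#' gene's class table. Classes are `null` (background f_null), optionally
#' `selected` (a fraction drawn from f_sel, or in gradient mode a per-gene
#' mixture weight w ~ U(0,1) blending f_null and f_sel), and optionally
#' `alien` (a compositionally shifted table, default
#' `gc_shift_table(f_null, 1.5)`, giving dinucleotide atypicality
#' signal). Sequences carry an ATG start and TAA stop, so parsing the
#' written FASTA reproduces the counts. Deterministic given `seed`.
#'
#' @param n_genes Number of genes.
#' @param f_null Background [codon_table()] (the f_n truth).
#' @param f_sel Optional selected-class [codon_table()].
#' @param selected_fraction Fraction of genes in the selected class.
#' @param gradient If `TRUE`, replace the two-class structure with per-gene
#'   mixture weights in [0, 1].
#' @param alien_fraction Fraction of genes drawn from the alien table.
#' @param f_alien Optional alien [codon_table()] (default: GC3 shift of
#'   `f_null`).
#' @param mean_length,min_length,max_length Gene length in codons: drawn
#'   from a log-normal (sdlog 0.45) around `mean_length`, truncated to
#'   [min_length, max_length]. Set min = max for fixed lengths.
#' @param aa_composition Amino-acid composition (default
#'   [default_aa_composition()]).
#' @param seed Integer seed.
#' @return A [gene_set()] with sequences and an extra element `labels`:
#'   data.frame of `gene_id`, `class` (`"null"`, `"selected"`, `"alien"`)
#'   and `weight` (selected-table mixture weight).
#' @export
simulate_genome <- function(n_genes = 500L, f_null, f_sel = NULL,
                            selected_fraction = 0, gradient = FALSE,
                            alien_fraction = 0, f_alien = NULL,
                            mean_length = 300L, min_length = 100L,
                            max_length = 900L,
                            aa_composition = default_aa_composition(),
                            seed = 1L) {
  code <- attr(f_null, "code")
  if (selected_fraction + alien_fraction > 1)
    stop("class fractions sum to more than 1", call. = FALSE)
  if ((selected_fraction > 0 || gradient) && is.null(f_sel))
    stop("selected_fraction > 0 (or gradient mode) requires f_sel",
         call. = FALSE)
  if (alien_fraction > 0 && is.null(f_alien))
    f_alien <- gc_shift_table(f_null, 1.5)
  aa_composition <- aa_composition[code$aa] / sum(aa_composition[code$aa])
  set.seed(as.integer(seed) %% 2147483647L)
  lens <- if (min_length == max_length) rep(min_length, n_genes) else {
    l <- stats::rlnorm(n_genes, log(mean_length), 0.45)
    as.integer(pmin(pmax(round(l), min_length), max_length))
  }
  n_alien <- round(alien_fraction * n_genes)
  n_sel <- if (gradient) 0L else round(selected_fraction * n_genes)
  cls <- rep("null", n_genes)
  if (n_alien > 0) cls[sample.int(n_genes, n_alien)] <- "alien"
  if (n_sel > 0) cls[sample(which(cls == "null"), n_sel)] <- "selected"
  w <- ifelse(cls == "selected", 1, 0)
  if (gradient) w[cls == "null"] <- stats::runif(sum(cls == "null"))
  # per-codon sampling probability for a table: p(aa) * f(codon | family)
  codon_probs <- function(tab) {
    p <- as.numeric(tab); names(p) <- code$codons
    p * aa_composition[unname(code$codon_aa[names(p)])]
  }
  p_null <- codon_probs(f_null)
  p_sel <- if (!is.null(f_sel)) codon_probs(f_sel)
  p_alien <- if (!is.null(f_alien)) codon_probs(f_alien)
  counts <- matrix(0, n_genes, length(code$codons),
                   dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                                   code$codons))
  seqs <- character(n_genes)
  for (g in seq_len(n_genes)) {
    p <- switch(cls[g],
                alien = p_alien,
                selected = p_sel,
                null = if (gradient && w[g] > 0)
                  (1 - w[g]) * p_null + w[g] * p_sel else p_null)
    cods <- sample(code$codons, lens[g], replace = TRUE, prob = p)
    counts[g, ] <- tabulate(factor(cods, levels = code$codons),
                            nbins = length(code$codons))
    seqs[g] <- paste0("ATG", paste(cods, collapse = ""), "TAA")
  }
  gs <- gene_set(counts, sequences = seqs, code = code)
  gs$labels <- data.frame(gene_id = rownames(counts), class = cls,
                          weight = w, stringsAsFactors = FALSE)
  gs
}

#' Write a gene set as multi-FASTA
#'
#' Standard multi-FASTA with 70-column wrapping. Headers carry the gene id
#' and, for simulated sets, `class=` / `weight=` truth labels, so the
#' round trip through [read_cds_fasta()] preserves both counts and truth.
#'
#' @param genes A [gene_set()] with sequences.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genes, path) {
  if (length(genes) == 0) stop("empty gene set", call. = FALSE)
  if (is.null(genes$sequences))
    stop("gene set has no sequences to write", call. = FALSE)
  ids <- gene_ids(genes)
  if (!is.null(genes$labels))
    ids <- sprintf("%s class=%s weight=%g", ids,
                   genes$labels$class, genes$labels$weight)
  x <- Biostrings::DNAStringSet(genes$sequences)
  names(x) <- ids
  Biostrings::writeXStringSet(x, filepath = path, width = 70L)
  invisible(path)
}
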