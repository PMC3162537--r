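#' Construct a gene set from codon counts
#'
#' The package's working container for one or more genes: a matrix of
#' per-gene sense-codon counts (C_ij), with optional retained nucleotide
#' sequences (needed only by the dinucleotide-signature comparator).
#' Start and stop codons are assumed already excluded from the counts;
#' [read_cds_fasta()] enforces that policy when parsing.
#'
#' @param counts Named numeric vector (one gene) or matrix (genes x codons)
#'   of non-negative codon counts. Column/element names must be sense
#'   codons of `code`; missing codons are filled with zero. Row names (or
#'   `gene_ids`) identify genes.
#' @param sequences Optional character vector of nucleotide sequences, one
#'   per gene (used by [karlin_delta_star()] and [refine_fn()]).
#' @param code A [genetic_code()].
#' @param gene_ids Optional gene identifiers overriding row names.
#' @param flags Optional list of per-gene character vectors of quality notes.
#' @return An object of class `"gene_set"`: list with `counts` (integer-like
#'   matrix n_genes x 61), `sequences` (or NULL), `flags`, `code`.
#' @examples
#' gs <- gene_set(c(AAA = 2, AAG = 2), gene_ids = "toy")
#' n_codons(gs)
#' @export
gene_set <- function(counts, sequences = NULL, code = genetic_code(),
                     gene_ids = NULL, flags = NULL) {
  if (is.vector(counts)) {
    counts <- matrix(counts, nrow = 1,
                     dimnames = list(gene_ids %||% "gene1", names(counts)))
  }
  if (is.null(colnames(counts)))
    stop("codon counts must be named by codon", call. = FALSE)
  if (!is.null(gene_ids)) rownames(counts) <- gene_ids
  if (is.null(rownames(counts)) && nrow(counts) > 0)
    rownames(counts) <- paste0("gene", seq_len(nrow(counts)))
  bad <- setdiff(colnames(counts), code$codons)
  if (length(bad) > 0)
    stop("not sense codons of the genetic code: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (any(counts < 0)) stop("codon counts must be non-negative", call. = FALSE)
  full <- matrix(0, nrow(counts), length(code$codons),
                 dimnames = list(rownames(counts), code$codons))
  full[, colnames(counts)] <- as.matrix(counts)
  if (!is.null(sequences)) {
    sequences <- toupper(as.character(sequences))
    if (length(sequences) != nrow(full))
      stop("one sequence per gene required", call. = FALSE)
    names(sequences) <- rownames(full)
  }
  structure(list(counts = full, sequences = sequences,
                 flags = flags %||% rep(list(character(0)), nrow(full)),
                 code = code),
            class = "gene_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.gene_set <- function(x, ...) {
  n <- nrow(x$counts)
  cat("Gene set: ", n, " gene(s), ", sum(x$counts), " codons total",
      if (!is.null(x$sequences)) ", sequences retained", "\n", sep = "")
  flagged <- sum(lengths(x$flags) > 0)
  if (flagged > 0) cat("  ", flagged, " gene(s) carry quality flags\n", sep = "")
  invisible(x)
}

#' @export
`[.gene_set` <- function(x, i, ...) {
  idx <- seq_len(nrow(x$counts))
  names(idx) <- rownames(x$counts)
  i <- idx[i]
  gene_set(x$counts[i, , drop = FALSE],
           sequences = if (!is.null(x$sequences)) x$sequences[i],
           code = x$code, flags = x$flags[i])
}

#' @export
length.gene_set <- function(x) nrow(x$counts)

#' Gene identifiers and codon totals
#'
#' @param genes A [gene_set()].
#' @return `gene_ids()`: character vector; `n_codons()`: named numeric vector
#'   of total codon counts per gene (start/stop already excluded);
#'   `aa_counts()`: matrix of per-gene amino-acid counts C_i.
#' @export
gene_ids <- function(genes) rownames(genes$counts)

#' @rdname gene_ids
#' @export
n_codons <- function(genes) rowSums(genes$counts)

#' @rdname gene_ids
#' @export
aa_counts <- function(genes) genes$counts %*% aa_indicator(genes$code)

#' Read in-frame CDS sequences from a multi-FASTA file
#'
#' Each record is one protein-coding gene, already strand-resolved (5'->3',
#' frame 0). The first codon is dropped positionally regardless of identity
#' (so non-ATG starts do not distort Val/Leu counts), and a terminal stop
#' codon, if present, is dropped. Codons containing characters outside
#' A/C/G/T are skipped and noted in the gene's flags.
#'
#' In strict mode (default) records whose remaining length is not a
#' multiple of 3, or that contain an internal stop codon, are rejected with
#' a reason (reported in `attr(, "rejected")`); in lenient mode the trailing
#' partial codon is truncated and internal stops are skipped, both flagged.
#'
#' @param path Path to a nucleotide multi-FASTA of CDS records.
#' @param code A [genetic_code()].
#' @param strict Reject frame/stop-violating records (`TRUE`, default) or
#'   repair-and-flag them (`FALSE`).
#' @param keep_sequences Retain the full record sequences in the result
#'   (required by dinucleotide-based analyses). Default `TRUE`.
#' @return A [gene_set()]; genes rejected in strict mode are listed in the
#'   `"rejected"` attribute (data.frame of gene_id, reason).
#' @export
read_cds_fasta <- function(path, code = genetic_code(), strict = TRUE,
                           keep_sequences = TRUE) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0) stop("no FASTA records in ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(seqs))
  chr <- toupper(as.character(seqs))
  parsed <- lapply(seq_along(chr), function(k) parse_one_cds(chr[[k]], code, strict))
  ok <- vapply(parsed, function(p) is.null(p$reason), logical(1))
  rejected <- data.frame(
    gene_id = ids[!ok],
    reason = vapply(parsed[!ok], `[[`, character(1), "reason"),
    stringsAsFactors = FALSE
  )
  if (!any(ok)) stop("no records retained from ", path, call. = FALSE)
  counts <- do.call(rbind, lapply(parsed[ok], `[[`, "counts"))
  rownames(counts) <- ids[ok]
  gs <- gene_set(counts,
                 sequences = if (keep_sequences) chr[ok] else NULL,
                 code = code,
                 flags = lapply(parsed[ok], `[[`, "flags"))
  attr(gs, "rejected") <- rejected
  gs
}

parse_one_cds <- function(s, code, strict) {
  flags <- character(0)
  n <- nchar(s)
  if (n < 6L) return(list(reason = "shorter than two codons"))
  s <- substr(s, 4L, n)  # positional start-codon removal
  n <- n - 3L
  if (n %% 3L != 0L) {
    if (strict) return(list(reason = "length not a multiple of 3"))
    flags <- c(flags, sprintf("truncated %d trailing base(s)", n %% 3L))
    n <- n - n %% 3L
    s <- substr(s, 1L, n)
  }
  if (n == 0L) return(list(reason = "no codons after start removal"))
  cods <- substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
  if (cods[length(cods)] %in% code$stop_codons) cods <- cods[-length(cods)]
  if (length(cods) == 0L) return(list(reason = "no codons between start and stop"))
  ambig <- !grepl("^[ACGT]{3}$", cods)
  if (any(ambig)) {
    flags <- c(flags, sprintf("skipped %d codon(s) with ambiguous bases", sum(ambig)))
    cods <- cods[!ambig]
  }
  internal_stop <- cods %in% code$stop_codons
  if (any(internal_stop)) {
    if (strict) return(list(reason = "internal stop codon"))
    flags <- c(flags, sprintf("skipped %d internal stop codon(s)", sum(internal_stop)))
    cods <- cods[!internal_stop]
  }
  if (length(cods) == 0L) return(list(reason = "no scorable codons"))
  counts <- table(factor(cods, levels = code$codons))
  list(counts = stats::setNames(as.numeric(counts), code$codons),
       flags = flags)
}

#' Pool the codon counts of several genes into one record
#'
#' Element-wise sum of codon counts, used wherever a set of ORFs is
#' collapsed into a single reference table.
#'
#' @param genes A [gene_set()].
#' @param id Identifier for the pooled record; the default records the pool
#'   provenance.
#' @return A one-gene [gene_set()].
#' @export
pool_genes <- function(genes, id = NULL) {
  if (length(genes) == 0) stop("cannot pool an empty gene set", call. = FALSE)
  id <- id %||% sprintf("pool(n=%d)", length(genes))
  gene_set(colSums(genes$counts), code = genes$code, gene_ids = id)
}

#' Write / read per-gene codon counts as TSV
#'
#' Columns: `gene_id`, then the 61 sense codons in fixed alphabetical
#' order. The round trip through `write_gene_counts()` and
#' `read_gene_counts()` reproduces counts exactly.
#'
#' @param genes A [gene_set()].
#' @param path Output (input) file path.
#' @param code A [genetic_code()] (for reading).
#' @return `read_gene_counts()` returns a [gene_set()] without sequences.
#' @export
write_gene_counts <- function(genes, path) {
  df <- data.frame(gene_id = gene_ids(genes), genes$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_counts
#' @export
read_gene_counts <- function(path, code = genetic_code()) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  gene_set(m, code = code)
}
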