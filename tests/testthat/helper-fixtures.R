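# Shared fixtures: small codon tables and gene sets built in code.

CODE <- genetic_code()

# table with within-family weights given by w(k) for a k-codon family
ramp_table <- function(w, role = "f_n", code = CODE) {
  v <- stats::setNames(numeric(length(code$codons)), code$codons)
  for (a in code$aa) {
    cods <- code$codons[code$codon_aa == a]
    v[cods] <- w(length(cods))
  }
  codon_table(v, role = role, code = code)
}

# background ramp (1..k) and a strongly selected table concentrated on the
# last codon of each family
fixture_f_n <- function() ramp_table(function(k) seq_len(k))
fixture_f_sel <- function() {
  ramp_table(function(k) { x <- rep(1, k); x[k] <- 6 * k; x }, role = "f_o")
}

# the shared two-codon worked example: Lys family only, all other families
# uniform in both tables (delta 0 outside Lys)
toy_tables <- function() {
  list(f_n = codon_table(c(AAA = 0.75, AAG = 0.25), fill = "uniform"),
       f_o = codon_table(c(AAA = 0.5, AAG = 0.5), role = "f_o",
                         fill = "uniform"))
}

toy_gene <- function() gene_set(c(AAA = 2, AAG = 2), gene_ids = "G1")

# exact SCB moments by exhaustive enumeration of all codon assignments,
# weighting each assignment by its product of within-family probabilities.
# Independent of the analytic formulas: sums over the full product space.
enumerate_scb_moments <- function(genes, delta, f_n) {
  code <- genes$code
  d <- as.numeric(delta); names(d) <- code$codons
  p <- as.numeric(f_n); names(p) <- code$codons
  cnt <- drop(genes$counts)
  sites <- list()
  for (a in code$aa) {
    cods <- code$codons[code$codon_aa == a]
    n_a <- sum(cnt[cods])
    if (n_a > 0) sites <- c(sites, rep(list(cods), n_a))
  }
  grid <- expand.grid(sites, stringsAsFactors = FALSE)
  scbs <- rowSums(matrix(d[as.matrix(grid)], nrow(grid)))
  probs <- apply(matrix(p[as.matrix(grid)], nrow(grid)), 1, prod)
  stopifnot(abs(sum(probs) - 1) < 1e-9)
  m <- sum(probs * scbs)
  list(mean = m, variance = sum(probs * scbs^2) - m^2)
}

write_temp_fasta <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}
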