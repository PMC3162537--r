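#' The Translation40 gene-name list
#'
#' The 40 ribosomal-protein and translation-elongation genes convention-
#' ally used as an a priori optimized reference set: tufA, tsf, fusA,
#' rplA-rplF, rplI-rplT and rpsB-rpsT.
#'
#' @return Character vector of 40 gene names.
#' @export
translation40_names <- function() {
  rpl <- paste0("rpl", LETTERS[c(1:6, 9:20)])
  rps <- paste0("rps", LETTERS[2:20])
  c("tufA", "tsf", "fusA", rpl, rps)
}

#' Refine the unselected reference set by removing atypical genes
#'
#' Derives an unselected (f_n) gene set from genome sequence alone by
#' iteratively discarding the most compositionally atypical genes:
#' dinucleotide-signature distance ([karlin_delta_star()]), codon-usage
#' distance ([karlin_b()]), or both (summed ranks), each recomputed
#' against the shrinking pool. The first 1% removal fixes the reference
#' direction of each codon's adaptiveness shift (delta changes only
#' through f_n, so shifts are read off the background frequencies
#' directly); subsequent removals are kept only while a significant
#' majority of codons keep shifting in that initial direction (one-sided
#' exact binomial test against 0.5, p < alpha). A failed step is
#' reverted. Shrinkage never passes `floor_fraction` of the genes.
#'
#' @param genes A [gene_set()] (sequences required for the dinucleotide
#'   criteria) of at least 200 genes.
#' @param step Fraction of the original gene count removed per step
#'   (default 0.01).
#' @param alpha Binomial-test significance threshold to continue
#'   (default 0.05).
#' @param criterion `"dinucleotide"`, `"karlin_b"`, or `"both"`.
#' @param floor_fraction Minimum retained fraction (default 0.5).
#' @param pseudocount Passed to [codon_frequencies()].
#' @return Object of class `"fn_refinement"`: list with `genes` (retained
#'   [gene_set()]), `f_n` (its frequency table), `trace` (data.frame of
#'   step, fraction_retained, n_agree, n_tested, p_value), and
#'   `final_fraction`.
#' @export
refine_fn <- function(genes, step = 0.01, alpha = 0.05,
                      criterion = c("dinucleotide", "karlin_b", "both"),
                      floor_fraction = 0.5, pseudocount = 0.5) {
  criterion <- match.arg(criterion)
  n <- length(genes)
  if (n < 200)
    stop("at least 200 genes required for a meaningful 1% step", call. = FALSE)
  if (criterion %in% c("dinucleotide", "both") && is.null(genes$sequences))
    stop("criterion '", criterion, "' requires retained sequences",
         call. = FALSE)
  k <- max(1L, as.integer(round(step * n)))
  retained <- rep(TRUE, n)
  deg_cods <- unlist(lapply(degenerate_aas(genes$code),
                            family_codons, code = genes$code),
                     use.names = FALSE)
  freq_of <- function(keep)
    codon_frequencies(genes[which(keep)], pseudocount = pseudocount)
  atypicality <- function(keep) {
    sub <- genes[which(keep)]
    sc <- switch(criterion,
      dinucleotide = karlin_delta_star(sub),
      karlin_b = karlin_b(sub, freq_of(keep)),
      both = rank(karlin_delta_star(sub)) +
             rank(karlin_b(sub, freq_of(keep))))
    stats::setNames(sc, which(keep))
  }
  f_prev <- freq_of(retained)
  ref_dir <- NULL
  trace <- list()
  step_i <- 0L
  repeat {
    if ((sum(retained) - k) / n < floor_fraction) break
    step_i <- step_i + 1L
    sc <- atypicality(retained)
    drop_idx <- as.integer(names(sort(sc, decreasing = TRUE)[seq_len(k)]))
    candidate <- retained
    candidate[drop_idx] <- FALSE
    f_new <- freq_of(candidate)
    # delta shift when f_n shrinks from f_prev to f_new (f_o fixed):
    # d_new - d_old = ln f_prev - ln f_new
    shift <- log(as.numeric(f_prev)[match(deg_cods, names(f_prev))]) -
             log(as.numeric(f_new)[match(deg_cods, names(f_new))])
    names(shift) <- deg_cods
    if (is.null(ref_dir)) {
      ref_dir <- sign(shift)[shift != 0]
      trace[[step_i]] <- data.frame(step = step_i,
                                    fraction_retained = sum(candidate) / n,
                                    n_agree = NA_integer_,
                                    n_tested = NA_integer_,
                                    p_value = NA_real_)
      retained <- candidate
      f_prev <- f_new
      next
    }
    test <- shift[names(ref_dir)]
    usable <- test != 0
    x <- sum(sign(test[usable]) == ref_dir[usable])
    m <- sum(usable)
    p <- stats::pbinom(x - 1, m, 0.5, lower.tail = FALSE)
    trace[[step_i]] <- data.frame(step = step_i,
                                  fraction_retained = sum(candidate) / n,
                                  n_agree = x, n_tested = m, p_value = p)
    if (p < alpha) {
      retained <- candidate
      f_prev <- f_new
    } else break
  }
  trace <- do.call(rbind, trace)
  out <- genes[which(retained)]
  structure(list(genes = out, f_n = freq_of(retained), trace = trace,
                 final_fraction = sum(retained) / n,
                 criterion = criterion),
            class = "fn_refinement")
}

#' @export
print.fn_refinement <- function(x, ...) {
  cat(sprintf("f_n refinement (%s): retained %.1f%% of genes over %d step(s)\n",
              x$criterion, 100 * x$final_fraction,
              if (is.null(x$trace)) 0L else nrow(x$trace)))
  invisible(x)
}

#' Seed an optimized reference gene set
#'
#' Picks an initial set of genes plausibly under strong codon selection:
#' by annotation (`"translation40"`: genes whose annotated name matches
#' the [translation40_names()] list), or by a comparator ranking — lowest
#' [enc()] or [enc_prime()], or highest per-codon codon-usage chi-square
#' ([codon_chi2()]).
#'
#' @param genes A [gene_set()].
#' @param criterion One of `"translation40"`, `"enc"`, `"enc_prime"`,
#'   `"chi2"`.
#' @param annotations A [feature_table()] whose `locus_tag` (or `gene`)
#'   matches the FASTA gene ids; required for `"translation40"`.
#' @param k Number of genes for the comparator criteria (default 40).
#' @param f_n Unselected [codon_table()]; required by `"enc_prime"` and
#'   `"chi2"`.
#' @return Character vector of selected gene ids.
#' @export
seed_fo <- function(genes, criterion = c("translation40", "enc",
                                         "enc_prime", "chi2"),
                    annotations = NULL, k = 40L, f_n = NULL) {
  criterion <- match.arg(criterion)
  ids <- gene_ids(genes)
  if (criterion == "translation40") {
    if (is.null(annotations))
      stop("translation40 seeding requires an annotation feature table",
           call. = FALSE)
    want <- tolower(translation40_names())
    hit <- tolower(as.character(annotations$gene)) %in% want
    sel_ids <- unique(stats::na.omit(c(
      annotations$locus_tag[hit], annotations$gene[hit])))
    sel <- intersect(c(sel_ids, annotations$gene[hit]), ids)
    if (length(sel) == 0)
      stop("no Translation40 gene names matched the gene set", call. = FALSE)
    if (length(sel) < 20)
      warning("only ", length(sel), " Translation40 genes matched")
    return(sel)
  }
  if (k > length(genes))
    stop("k exceeds the number of genes", call. = FALSE)
  score <- switch(criterion,
    enc = -enc(genes),
    enc_prime = {
      if (is.null(f_n)) stop("enc_prime seeding requires f_n", call. = FALSE)
      -enc_prime(genes, f_n)
    },
    chi2 = {
      if (is.null(f_n)) stop("chi2 seeding requires f_n", call. = FALSE)
      codon_chi2(genes, f_n)
    })
  ids[order(-score, ids)][seq_len(k)]
}

#' Iteratively derive the optimized reference set
#'
#' Starting from a seed gene set, builds an f_o table, scores every gene's
#' ACE_u against (current f_o, fixed f_n), and selects the top-ranked
#' genes (stable tie-break: ACE_u descending, gene id ascending) until a
#' per-round codon budget is filled. Budgets interpolate geometrically
#' from `start_fraction` of the genome's codon total down to
#' `target_codons` across `n_rounds` rounds; after the schedule, selection
#' at the final budget is repeated until the set is stable (a convergence
#' warning is issued if it oscillates). Because every round rescales all
#' genes, genes may re-enter after being dropped.
#'
#' @param genes A [gene_set()] (the whole genome).
#' @param seed_set Character vector of gene ids seeding round 0 (e.g. from
#'   [seed_fo()]).
#' @param f_n Fixed unselected [codon_table()].
#' @param target_codons Final f_o table size in codons (default 10000).
#' @param n_rounds Number of shrinkage rounds (default 15).
#' @param start_fraction Initial codon budget as a fraction of the genome
#'   codon total (default 0.40).
#' @param pseudocount Passed to [codon_frequencies()].
#' @return Object of class `"fo_iteration"`: list with `gene_ids` (final
#'   set), `f_o` (its table), `states` (per-round data.frame of round,
#'   budget, n_genes, codon_total), and `converged`.
#' @export
iterate_fo <- function(genes, seed_set, f_n, target_codons = 10000L,
                       n_rounds = 15L, start_fraction = 0.40,
                       pseudocount = 0.5) {
  ids <- gene_ids(genes)
  seed_set <- intersect(seed_set, ids)
  if (length(seed_set) == 0) stop("empty seed set", call. = FALSE)
  sizes <- n_codons(genes)
  total <- sum(sizes)
  if (target_codons >= start_fraction * total)
    stop("target_codons must be below the starting codon budget", call. = FALSE)
  budgets <- exp(seq(log(start_fraction * total), log(target_codons),
                     length.out = n_rounds))
  current <- seed_set
  build_fo <- function(set)
    codon_frequencies(genes[set], role = "f_o", pseudocount = pseudocount)
  f_o <- build_fo(current)
  if (max(abs(as.numeric(delta_table(f_o, f_n)))) < 1e-12)
    stop("seed set yields delta identical to zero (f_o = f_n); ",
         "iteration is degenerate", call. = FALSE)
  select_top <- function(f_o, budget) {
    u <- stats::setNames(ace(genes, f_n = f_n,
                             delta = delta_table(f_o, f_n))$results$ace_u, ids)
    ord <- ids[order(-u, ids)]
    cum <- cumsum(sizes[ord])
    ord[seq_len(which(cum >= budget)[1])]
  }
  states <- list()
  for (r in seq_len(n_rounds)) {
    current <- select_top(f_o, budgets[r])
    f_o <- build_fo(current)
    states[[r]] <- data.frame(round = r, budget = budgets[r],
                              n_genes = length(current),
                              codon_total = sum(sizes[current]))
  }
  converged <- FALSE
  for (extra in seq_len(20L)) {
    nxt <- select_top(f_o, target_codons)
    if (setequal(nxt, current)) { converged <- TRUE; break }
    current <- nxt
    f_o <- build_fo(current)
  }
  if (!converged)
    warning("f_o iteration did not stabilize; returning the last state")
  structure(list(gene_ids = sort(current), f_o = f_o,
                 states = do.call(rbind, states), converged = converged),
            class = "fo_iteration")
}

#' @export
print.fo_iteration <- function(x, ...) {
  st <- x$states[nrow(x$states), ]
  cat(sprintf(
    "f_o iteration: %d gene(s), %d codons in the final table (%sconverged)\n",
    length(x$gene_ids), st$codon_total, if (x$converged) "" else "not "))
  invisible(x)
}
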