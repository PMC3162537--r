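Package: codonACE
Title: Adaptive Codon Enrichment Statistics for Quantifying Codon Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Measures selection on synonymous codon usage in microbial
    genomes with the Adaptive Codon Enrichment (ACE) framework. Per-codon
    adaptiveness scores are log-ratios of codon frequencies between an
    optimized (f_o) and an unselected (f_n) reference table; a gene's
    Summed Codon Bias is evaluated against its analytic stochastic null
    (mean and variance under independent within-family codon sampling),
    yielding ACE, ACE_z and ACE_u scores, per-gene error variances and
    t-tests, and a genome-wide ACE chi-square summary. Includes algorithms
    that derive both reference tables from genome sequence alone
    (atypicality-based refinement of f_n, iterative enrichment of f_o),
    classic comparator statistics (CAI, GCB, ENC, ENC', codon-usage
    chi-square, Karlin dinucleotide and B signatures), Monte Carlo null
    validation with a D'Agostino-Pearson normality check, and a synthetic
    CDS-set generator for controlled experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    rtracklayer,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
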