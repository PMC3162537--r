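---
title: "Measuring codon selection with Adaptive Codon Enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring codon selection with Adaptive Codon Enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonACE)
```

## The model

Synonymous codon usage in microbial genomes reflects two separable
forces: genome-wide processes (mutational bias, gene conversion,
whole-genome selection on nucleotide composition) and codon selection —
selection for translationally efficient codons, strongest in highly
expressed genes. codonACE separates the two with a pair of within-family
codon frequency tables:

* `f_n` — the frequency of each codon among its synonyms in genes that
  have **not** been optimized by codon selection (the background);
* `f_o` — the same frequencies in a reference set of optimized
  (typically translation-apparatus) genes.

The adaptiveness of codon $j$ of amino acid $i$ is the log-ratio

$$\delta_{ij} = \ln \frac{f_o(cdn_{ij})}{f_n(cdn_{ij})},$$

so a gene's total codon optimization is additive: the Summed Codon Bias
is $SCB = \sum_i \alpha_i$ with $\alpha_i = \sum_j C_{ij}\,\delta_{ij}$,
where $C_{ij}$ are the gene's codon counts. Expressing bias through the
*difference* between the two tables (rather than the distance from
either) means the most extreme scores go to the genes most enriched for
preferred codons, and codons that are abundant in optimized genes merely
because of mutational bias do not inflate the score.

### The stochastic null

Under the null hypothesis of no codon selection, each site's codon is an
independent draw within its amino-acid family with probabilities
$P_{ij} = f_n(cdn_{ij})$, conditioned on the gene's amino-acid counts
$C_i$. Then

$$\mathrm{E}[SCB] = \sum_i C_i \mu_i, \qquad
  \mu_i = \sum_j P_{ij}\delta_{ij},$$
$$\mathrm{Var}[SCB] = \sum_i C_i \sigma_i^2, \qquad
  \sigma_i^2 = \sum_j P_{ij}\delta_{ij}^2 - \mu_i^2,$$

because independent sites contribute additive variance. The Adaptive
Codon Enrichment and its two normalizations are

$$ACE = SCB - \mathrm{E}[SCB], \qquad
  ACE_z = \frac{ACE}{\sqrt{\mathrm{Var}[SCB]}}, \qquad
  ACE_u = \frac{ACE}{\sum_i C_i \sigma_i}.$$

$ACE_z$ is a Z-value testable against N(0,1) by the central limit
theorem; $ACE_u$ is the deviation per codon, weighting each amino acid
by the variance it actually contributes, so amino-acid composition does
not move the score under the null. Methionine and tryptophan, having
single codons, contribute identically to observed and expected values
and therefore cannot influence any ACE quantity — the package's tests
assert this exactly, and `n_informative` counts only codons of families
with $\sigma_i > 0$.

For a gene set, the genome-wide summary is the mean squared Z-score,

$$ACE\chi^2 = \frac{1}{n}\sum_g ACE_z(g)^2,$$

which approaches 1.0 in the absence of codon selection. Departure from
1.0 is reported as $Z = (ACE\chi^2 - 1)\sqrt{n/2}$, the normal
approximation to the mean of $n$ $\chi^2_1$ variables.

### Error variance and gene-to-gene tests

Sampling error in a single gene's ACE is estimated by evaluating the
variance formula at the gene's *observed* within-family frequencies; on
the $ACE_u$ scale this error variance is divided by the square of the
$ACE_u$ denominator. Two genes are then compared with a Welch-style
two-sample t-test (`gene_ttest()`), using each gene's informative-codon
count as its sample size in the Welch–Satterthwaite degrees of freedom.
That last identification is a modelling choice: the error variance is
analytic, not an empirical variance with its own df, and the informative
codon count is the natural measure of how much data it rests on.

## Numerical and design choices

* **Natural logarithm for δ.** Any base rescales SCB, ACE and $ACE_u$ by
  a constant and leaves $ACE_z$ and $ACE\chi^2$ unchanged; ln makes the
  length-normalized SCB identical to the GCB comparator.
* **$ACE_u$ denominator.** Two readings are defensible: the scalar
  divisor $\sum_i C_i\sigma_i$ (default, `u_method = "pooled-sd"`) and
  the mean per-family Z,
  $\frac{1}{N}\sum_i (\alpha_i - C_i\mu_i)/\sigma_i$
  (`u_method = "mean-z"`). The scalar form is the default because the
  $ACE_u$ error variance is defined as the ACE error variance divided by
  the squared denominator — which requires the denominator to be a
  scalar. The two differ only when $\sigma_i$ varies across families.
* **Pseudocount 0.5.** Codons absent from a reference pool get a count
  of 0.5 before normalization, keeping every frequency positive so the
  logs exist. The package applies this to any table it builds (not only
  `f_o`): genome-scale `f_n` pools rarely need it, but small custom
  background sets do.
* **Zero-variance genes** (e.g. `f_o = f_n`, or a gene of only Met/Trp)
  report ACE = 0 with `NA` for $ACE_z$/$ACE_u$ — a signal, never NaN
  propagation or a crash.
* **Start and stop codons.** The first codon is dropped positionally
  (GTG/TTG starts would otherwise distort Val/Leu counts) and a
  terminal stop is dropped; strict parsing rejects frame errors and
  internal stops (lenient mode repairs and flags them), because silent
  truncation corrupts the reading frame. How genes with such defects
  should be treated is genuinely open; strict rejection is this
  package's choice.
* **Display normalization.** Presentation tables divide each family by
  its maximum; δ columns are first mapped through exp(), a monotone
  sign-free transform. Display output never feeds back into
  computation.
* **Genetic code.** NCBI table 11 by default, table 1 selectable; both
  share the sense-codon mapping, and Ser/Leu/Arg are treated as single
  six-fold families because all formulas group codons by encoded amino
  acid.

## Reference-set algorithms

**Background refinement (`refine_fn`).** Genome-wide pools are
contaminated from both tails: strongly selected genes and recent
lateral acquisitions. Genes are ranked by compositional atypicality —
Karlin's dinucleotide signature distance $\delta^*$, Karlin's B
codon-usage distance, or both — recomputed against the shrinking pool
(the pool average is itself being purified), and removed 1% at a time.
The first removal fixes each codon's direction of frequency shift;
shrinking continues while a significant majority of codons keep
shifting in that direction (one-sided exact binomial test against 0.5,
p < 0.05), the failed step is reverted, and shrinkage never passes 50%
of the genes. Note that δ shifts depend only on `f_n`, so no `f_o` is
needed during refinement. On synthetic genomes the codon-usage
criterion separates a planted compositionally shifted class more
sharply than the dinucleotide signature, whose relative abundances
deliberately normalize out mononucleotide content; both are provided
since real lateral transfers perturb dinucleotides more richly than the
generator's single GC-shift axis does.

**Optimized-set iteration (`iterate_fo`).** A seed set of plausibly
selected genes (Translation40 names from an annotation, or low ENC/ENC',
or high per-codon codon-usage χ²) builds an initial `f_o`; each round
scores *all* genes by $ACE_u$ against the current `f_o` and the fixed
`f_n`, then refills the set from the top until a codon budget is met.
Budgets shrink geometrically from 40% of the genome's codons to a
10,000-codon target across 15 rounds (start, end and round count are the
conventional parameterization; the geometric schedule is this package's
choice — it shrinks smoothly and avoids cliff effects). Ranking ties
break by gene id for reproducibility; genes may re-enter after being
dropped, since every round rescores everything. After the schedule, the
selection is repeated at the final budget until it is a fixed point
(with a convergence warning if it oscillates). Because scoring is always
normalized by the fixed `f_n`, iteration converges on genes exemplifying
the `f_o`-vs-genome trend rather than amplifying an arbitrary dominant
bias; on null genomes the final set's held-out $ACE\chi^2$ stays at 1
within sampling error — the suite checks this.

## What the synthetic generator emulates

`simulate_genome()` draws each gene's amino acids iid from a
composition (default: an *E. coli*-like average protein composition)
and each codon independently within its family — exactly the stochastic
model the null assumes. Gene lengths follow a truncated log-normal
(sdlog 0.45, default mean 300 codons, range 100–900), matching the
right skew of real ORF lengths. Optional classes: a *selected* class
drawn from a distinct table (or graded per-gene mixtures), and an
*alien* class built by shifting the background table's wobble-position
GC content (+1.5 on the log scale by default), which perturbs nucleotide
and dinucleotide composition the way laterally acquired DNA does while
leaving amino-acid usage untouched.

What it does **not** emulate: site-to-site variation in selection
strength within genes, neighbour-dependent codon effects, mRNA-structure
or Shine–Dalgarno avoidance constraints, strand- or position-dependent
mutational gradients, and amino-acid composition differences between
gene classes. Passing tests therefore demonstrate the statistics'
correctness under the stated sampling model and their power against
planted class structure — not that real genomes satisfy the model.
On real data the normal approximation is itself checked per gene by
`mc_null()` (2000 composition-fixed resamples, per-gene seeds derived
from one top-level seed independent of processing order) and the
D'Agostino–Pearson K² omnibus test (`normality_check()`), implemented
from the published skewness/kurtosis transforms and verified against an
independent implementation.

## Problem sizes and runtimes

The validation suite uses genomes of 300–1000 genes of 150–300 codons:
large enough that the null calibration ($ACE\chi^2 = 1.0 \pm$ sampling
error, KS agreement of $ACE_z$ with N(0,1)) and the planted-class
recoveries (refinement removing a 20% alien class; iteration recovering
a 20% selected class from different seeds with near-identical final
sets) are sharp, small enough that the whole suite runs in a few
minutes on one CPU. Exhaustive enumeration cross-checks the analytic
moments on genes of ≤ 10 degenerate codons (product spaces of a few
thousand assignments) to 10⁻¹⁰.

## Known limitations

* ACE measures the *effect* of codon selection on usage, not the
  population-genetic coefficient $s$; it is linear in preferred-codon
  frequency where selection is not.
* A single `f_n` assumes one uniform genome-wide process; isochore
  structure or strong strand asymmetry violates this (mildly, in
  bacteria).
* Seeding by tRNA adaptation index or cross-genome conservation, and
  ortholog-based analyses, are out of scope; `count_trna_genes()`
  provides only the per-genome structural-RNA count (60–100 bp,
  excluding the Sec tRNA).
* Annotation input is GFF3 (or any data.frame via `feature_table()`);
  GenBank flat files are not parsed.
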