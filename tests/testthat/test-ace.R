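test_that("the worked two-codon example reproduces its hand-computed scores", {
  tt <- toy_tables()
  d <- delta_table(tt$f_o, tt$f_n)
  g <- toy_gene()
  expect_equal(unname(scb(g, d)), 2 * log(2 / 3) + 2 * log(2),
               tolerance = 1e-12)
  nm <- null_moments(g, d, tt$f_n)
  expect_equal(nm$expected_scb, 4 * (0.75 * log(2 / 3) + 0.25 * log(2)),
               tolerance = 1e-12)
  expect_equal(nm$variance_scb, 0.9052117, tolerance = 1e-6)
  fit <- ace(g, f_o = tt$f_o, f_n = tt$f_n)
  r <- fit$results
  expect_equal(r$scb, 0.5753641, tolerance = 1e-6)
  expect_equal(r$ace, 1.0986123, tolerance = 1e-6)
  expect_equal(r$ace_z, 1.1546, tolerance = 1e-4)
  expect_equal(r$ace_u, 0.5773503, tolerance = 1e-6)
  expect_equal(r$error_variance, 1.2069, tolerance = 1e-4)
  expect_equal(r$n_informative, 4L)
  expect_equal(unname(error_variance(g, d)), r$error_variance)
  # doubling all counts doubles the error variance (linear in C_i)
  g2 <- gene_set(c(AAA = 4, AAG = 4))
  expect_equal(unname(error_variance(g2, d)), 2 * r$error_variance)
})

test_that("scb is zero for identical tables and for single-codon genes", {
  tt <- toy_tables()
  d0 <- delta_table(structure(tt$f_n, role = "f_o"), tt$f_n)
  g <- toy_gene()
  expect_equal(unname(scb(g, d0)), 0)
  met <- gene_set(c(ATG = 10))
  d <- delta_table(tt$f_o, tt$f_n)
  expect_equal(unname(scb(met, d)), 0)
  expect_error(scb(gene_set(c(AAA = 0)), d), "zero codons")
})

test_that("ace = scb - expected to machine precision on random inputs", {
  set.seed(21)
  for (s in 1:5) {
    f_o <- ramp_table(function(k) runif(k, 0.05, 1), role = "f_o")
    f_n <- ramp_table(function(k) runif(k, 0.05, 1))
    gs <- simulate_genome(20, f_null = f_n, mean_length = 120,
                          min_length = 50, max_length = 300, seed = s)
    fit <- ace(gs, f_o = f_o, f_n = f_n)
    r <- fit$results
    expect_equal(r$ace, r$scb - r$expected_scb, tolerance = 1e-14)
    ok <- r$variance_scb > 0
    expect_equal(r$ace_z[ok], r$ace[ok] / sqrt(r$variance_scb[ok]),
                 tolerance = 1e-14)
  }
})

test_that("analytic moments agree with exhaustive enumeration to 1e-10", {
  tt <- toy_tables()
  set.seed(31)
  f_o <- ramp_table(function(k) runif(k, 0.1, 1), role = "f_o")
  f_n <- ramp_table(function(k) runif(k, 0.1, 1))
  d <- delta_table(f_o, f_n)
  cases <- list(
    toy_gene(),
    gene_set(c(AAA = 3, ATA = 2, GCA = 2)),          # 2-, 3-, 4-fold families
    gene_set(c(TTA = 2, AGA = 1, GGA = 2, TGG = 3)), # 6-fold families + Trp
    gene_set(c(AAA = 1, AAG = 1, TTT = 2, CAT = 2, GAA = 2)))
  for (g in cases) {
    ref <- enumerate_scb_moments(g, d, f_n)
    nm <- null_moments(g, d, f_n)
    expect_equal(nm$expected_scb, ref$mean, tolerance = 1e-10)
    expect_equal(nm$variance_scb, ref$variance, tolerance = 1e-10)
  }
  # and with the toy tables, where the answer is known in closed form
  d2 <- delta_table(tt$f_o, tt$f_n)
  ref <- enumerate_scb_moments(toy_gene(), d2, tt$f_n)
  expect_equal(ref$mean, -0.5232481, tolerance = 1e-6)
  expect_equal(ref$variance, 0.9052117, tolerance = 1e-6)
})

test_that("Monte Carlo null matches the analytic moments and is reproducible", {
  set.seed(41)
  f_o <- fixture_f_sel()
  f_n <- fixture_f_n()
  d <- delta_table(f_o, f_n)
  gs <- simulate_genome(1, f_null = f_n, min_length = 200, max_length = 200,
                        seed = 6)
  ns <- mc_null(gs, d, f_n, n_reps = 2000, seed = 5)
  nm <- null_moments(gs, d, f_n)
  se_mean <- sqrt(nm$variance_scb / 2000)
  se_var <- nm$variance_scb * sqrt(2 / 1999)
  expect_lt(abs(ns$mean - nm$expected_scb), 3 * se_mean)
  expect_lt(abs(ns$variance - nm$variance_scb), 3 * se_var)
  # determinism under a fixed seed
  ns2 <- mc_null(gs, d, f_n, n_reps = 2000, seed = 5)
  expect_identical(ns$scb, ns2$scb)
  # identical tables give every replicate SCB = 0
  d0 <- delta_table(structure(f_n, role = "f_o"), f_n)
  ns0 <- mc_null(gs, d0, f_n, n_reps = 50, seed = 5)
  expect_equal(ns0$scb, rep(0, 50))
})

test_that("ACE fields are indifferent to Met/Trp codons", {
  tt <- toy_tables()
  g <- toy_gene()
  fit <- ace(g, f_o = tt$f_o, f_n = tt$f_n)
  for (extra in list(c(ATG = 100), c(TGG = 57), c(ATG = 13, TGG = 29))) {
    counts <- drop(g$counts)
    counts[names(extra)] <- counts[names(extra)] + extra
    g2 <- gene_set(counts)
    fit2 <- ace(g2, f_o = tt$f_o, f_n = tt$f_n)
    for (col in c("scb", "expected_scb", "variance_scb", "ace", "ace_z",
                  "ace_u", "error_variance", "n_informative"))
      expect_equal(fit2$results[[col]], fit$results[[col]],
                   tolerance = 1e-12)
  }
})

test_that("zero-variance genes report ACE 0 with undefined z and u", {
  tt <- toy_tables()
  d0 <- delta_table(structure(tt$f_n, role = "f_o"), tt$f_n)
  fit <- ace(toy_gene(), f_n = tt$f_n, delta = d0)
  expect_equal(fit$results$ace, 0)
  expect_true(is.na(fit$results$ace_z))
  expect_true(is.na(fit$results$ace_u))
  met <- gene_set(c(ATG = 5, TGG = 2))
  fitm <- ace(met, f_o = tt$f_o, f_n = tt$f_n)
  expect_equal(fitm$results$ace, 0)
  expect_true(is.na(fitm$results$ace_z))
})

test_that("a gene exactly at its expected composition has ACE 0", {
  tt <- toy_tables()
  g <- gene_set(c(AAA = 3, AAG = 1))  # matches f_n 0.75 / 0.25 with C = 4
  fit <- ace(g, f_o = tt$f_o, f_n = tt$f_n)
  expect_equal(fit$results$ace, 0, tolerance = 1e-12)
})

test_that("swapping a codon for a higher-delta synonym strictly increases all scores", {
  set.seed(51)
  f_o <- ramp_table(function(k) runif(k, 0.05, 1), role = "f_o")
  f_n <- ramp_table(function(k) runif(k, 0.05, 1))
  d <- delta_table(f_o, f_n)
  gs <- simulate_genome(5, f_null = f_n, mean_length = 150, min_length = 100,
                        max_length = 200, seed = 52)
  for (g in seq_len(5)) {
    counts <- gs$counts[g, ]
    lys <- c("AAA", "AAG")
    lo <- lys[which.min(d[lys])]; hi <- lys[which.max(d[lys])]
    if (counts[lo] == 0) next
    before <- ace(gene_set(counts), f_n = f_n, delta = d)$results
    counts[lo] <- counts[lo] - 1; counts[hi] <- counts[hi] + 1
    after <- ace(gene_set(counts), f_n = f_n, delta = d)$results
    expect_gt(after$scb, before$scb)
    expect_gt(after$ace, before$ace)
    expect_gt(after$ace_z, before$ace_z)
    expect_gt(after$ace_u, before$ace_u)
    # the null moments depend only on amino-acid composition
    expect_equal(after$expected_scb, before$expected_scb)
    expect_equal(after$variance_scb, before$variance_scb)
  }
})

test_that("the ACE_z of null genes is standard normal and ACE chi2 near 1", {
  f_n <- fixture_f_n()
  f_o <- fixture_f_sel()
  gs <- simulate_genome(300, f_null = f_n, min_length = 300,
                        max_length = 300, seed = 61)
  fit <- ace(gs, f_o = f_o, f_n = f_n)
  z <- fit$results$ace_z
  expect_gt(stats::ks.test(z, "pnorm")$p.value, 0.01)
  gsum <- ace_chi2(fit)
  expect_equal(gsum$ace_chi2, mean(z^2), tolerance = 1e-12)
  expect_lt(abs(gsum$ace_chi2 - 1), 3 * sqrt(2 / 300))
  expect_equal(gsum$departure_z, (gsum$ace_chi2 - 1) * sqrt(300 / 2))
})

test_that("ace_chi2 handles the trivial and degenerate inputs", {
  expect_equal(ace_chi2(c(1, -1))$ace_chi2, 1)
  expect_error(ace_chi2(numeric(0)), "no genes")
  expect_error(ace_chi2(c(NA_real_, NA_real_)), "undefined")
})

test_that("ACE_u distributions are invariant to amino-acid composition under the null", {
  f_n <- fixture_f_n()
  f_o <- fixture_f_sel()
  comp1 <- default_aa_composition()
  comp2 <- comp1; comp2[] <- 1 / 20  # uniform amino-acid usage
  g1 <- simulate_genome(200, f_null = f_n, aa_composition = comp1,
                        min_length = 300, max_length = 300, seed = 71)
  g2 <- simulate_genome(200, f_null = f_n, aa_composition = comp2,
                        min_length = 300, max_length = 300, seed = 72)
  u1 <- ace(g1, f_o = f_o, f_n = f_n)$results$ace_u
  u2 <- ace(g2, f_o = f_o, f_n = f_n)$results$ace_u
  expect_gt(stats::ks.test(u1, u2)$p.value, 0.01)
})

test_that("gene t-tests separate planted differences and not identical genes", {
  f_n <- fixture_f_n()
  f_o <- fixture_f_sel()
  d <- delta_table(f_o, f_n)
  gs <- simulate_genome(2, f_null = f_n, min_length = 500,
                                       max_length = 500, seed = 81)
  # plant a frequency difference: re-draw gene 2 from the selected table
  sel <- simulate_genome(1, f_null = fixture_f_sel(), min_length = 500,
                         max_length = 500, seed = 82)
  counts <- rbind(a = gs$counts[1, ], b = sel$counts[1, ])
  fit <- ace(gene_set(counts), f_n = f_n, delta = d)
  tt_same <- gene_ttest(ace(gene_set(rbind(x = counts["a", ],
                                           y = counts["a", ])),
                            f_n = f_n, delta = d), "x", "y")
  expect_equal(tt_same$t, 0)
  expect_equal(tt_same$p_value, 1)
  tt_diff <- gene_ttest(fit, "a", "b")
  expect_lt(tt_diff$p_value, 0.01)
})

test_that("the K2 normality check matches an independent oracle on a frozen sample", {
  # oracle values computed once with an independent implementation of the
  # D'Agostino-Pearson omnibus test on this exact frozen vector
  set.seed(99)
  x <- round(rnorm(200), 6)
  nc <- normality_check(x)
  expect_equal(nc$k2, 2.4264887695, tolerance = 1e-9)
  expect_equal(nc$p_value, 0.2972313804, tolerance = 1e-9)
  expect_equal(nc$skewness, -0.2645131913, tolerance = 1e-9)
  expect_equal(nc$kurtosis, 2.9014203790, tolerance = 1e-9)
  # strong skew is detected
  nc2 <- normality_check(exp(x))
  expect_equal(nc2$k2, 103.5175539545, tolerance = 1e-8)
  expect_lt(nc2$p_value, 1e-3)
  expect_error(normality_check(rnorm(10)), "20")
  expect_error(normality_check(rep(1, 50)), "constant")
})

test_that("the K2 test holds its type-I level on normal samples", {
  set.seed(101)
  ps <- replicate(150, normality_check(rnorm(500))$p_value)
  expect_lt(mean(ps < 0.05), 0.12)
  expect_gt(mean(ps < 0.5), 0.3)  # p-values spread over (0,1)
})

test_that("simulate() on a fit reproduces per-gene null samples independent of order", {
  f_n <- fixture_f_n()
  f_o <- fixture_f_sel()
  gs <- simulate_genome(3, f_null = f_n, min_length = 100, max_length = 100,
                        seed = 91)
  fit <- ace(gs, f_o = f_o, f_n = f_n)
  sims <- simulate(fit, nsim = 200, seed = 7)
  one <- simulate(fit, nsim = 200, seed = 7, genes = gene_ids(gs)[2])
  expect_identical(sims[[2]]$scb, one$scb)
  nm <- null_moments(gs, fit$delta, f_n)
  for (k in 1:3)
    expect_lt(abs(sims[[k]]$mean - nm$expected_scb[k]),
              4 * sqrt(nm$variance_scb[k] / 200))
})
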