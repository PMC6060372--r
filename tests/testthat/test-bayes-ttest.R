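test_that("quadrature BF10 matches the dense Riemann oracle on a lattice", {
  for (t in c(0, 2, 5)) for (n in c(8, 16, 32))
    for (r in c(0.5, sqrt(2) / 2, 1)) {
      got <- jzs_bf_from_t(t, n, r)$bf10
      want <- riemann_jzs_bf10(t, n, r)
      expect_lt(abs(got - want) / want, 1e-4)
    }
})

test_that("null-consistent data give BF10 below 1, with the exact integral value", {
  # antisymmetric differences: t = 0 exactly
  x <- c(-4, -3, -2, -1, 1, 2, 3, 4, -8, 8, -6, 6, -5, 5, -7, 7)
  bf <- jzs_paired_bf(x + 10, rep(10, 16))
  expect_equal(bf$bf10, 0.2553957, tolerance = 1e-6)
  expect_identical(bf$category, "Substantial evidence for H0")
  for (n in c(2, 4, 16, 64)) expect_lt(jzs_bf_from_t(0, n)$bf10, 1)
})

test_that("BF10 is strictly increasing in |t| and symmetric in sign", {
  ts <- seq(0, 8, by = 0.5)
  bfs <- sapply(ts, function(t) jzs_bf_from_t(t, 16)$bf10)
  expect_true(all(diff(bfs) > 0))
  expect_equal(jzs_bf_from_t(-3.3, 16)$bf10, jzs_bf_from_t(3.3, 16)$bf10)
})

test_that("the alternative collapses onto the null as the prior scale vanishes", {
  for (t in c(1, 3)) {
    expect_equal(jzs_bf_from_t(t, 16, 1e-8)$bf10, 1, tolerance = 1e-6)
  }
})

test_that("a large true effect is detected in nearly all replicates", {
  # exact rates from the noncentral-t distribution (ncp = 1.5*sqrt(16),
  # df = 15): P(BF10 > 100) = 0.867, P(BF10 > 30) = 0.958
  set.seed(61)
  decisive <- 0L; very_strong <- 0L
  for (i in 1:200) {
    d <- rnorm(16, mean = 1.5, sd = 1)
    bf <- jzs_paired_bf(d, rep(0, 16))$bf10
    if (bf > 100) decisive <- decisive + 1L
    if (bf > 30) very_strong <- very_strong + 1L
  }
  expect_gte(decisive / 200, 0.80)   # 0.867 minus simulation error
  expect_gte(very_strong / 200, 0.90)
})

test_that("degenerate paired inputs are rejected", {
  expect_error(jzs_paired_bf(rep(1, 10), rep(0, 10)), "zero-variance")
  expect_error(jzs_paired_bf(1, 0), "at least 2")
  expect_error(jzs_paired_bf(rnorm(5), rnorm(6)), "equal length")
})

test_that("evidence categories partition the positive axis per the study's scale", {
  expect_identical(classify_bf(14.82)$category, "Strong evidence for H1")
  expect_identical(classify_bf(0.24)$category, "Substantial evidence for H0")
  expect_identical(classify_bf(1)$category, "No evidence")
  # boundaries go to the stronger-evidence side
  expect_identical(classify_bf(30)$category, "Very strong evidence for H1")
  expect_identical(classify_bf(100)$category, "Decisive evidence for H1")
  expect_identical(classify_bf(3)$category, "Substantial evidence for H1")
  expect_identical(classify_bf(1 / 3)$category, "Substantial evidence for H0")
  expect_identical(classify_bf(1 / 100)$category, "Decisive evidence for H0")
  # display censoring at 1000 affects rendering only
  expect_identical(classify_bf(1000)$display, ">=1000")
  expect_identical(classify_bf(2.5e7)$display, ">=1000")
  expect_match(classify_bf(999.4)$display, "999")
  expect_error(classify_bf(0), "positive")
  expect_error(classify_bf(-2), "positive")

  # totality: every positive real maps to exactly one label
  set.seed(3)
  for (b in c(10^runif(50, -4, 4), 1, Inf)) {
    expect_length(classify_bf(b)$category, 1L)
  }
})

test_that("pairwise matrices are symmetric with an omitted diagonal", {
  tab <- simulate_metric_table(n_subjects = 8, mu = 0.6, noise_sd = 0.05,
                               rng_seed = 44)
  m <- pairwise_bf_matrix(tab, "value", "STN", bayes_prior_spec())
  expect_identical(dim(m), c(17L, 17L))
  expect_true(all(is.na(diag(m))))
  expect_equal(m[upper.tri(m)], t(m)[upper.tri(m)])
})

test_that("an area shifted by three within-subject SDs dominates its row", {
  shift <- setNames(rep(0, 17), cortical_areas())
  shift["SMA"] <- 3 * 0.05
  tab <- simulate_metric_table(n_subjects = 16, mu = 0.6, noise_sd = 0.02,
                               subject_sd = 0.03, hemisphere_sd = 0,
                               area_effects = shift, rng_seed = 13)
  m <- pairwise_bf_matrix(tab, "value", "STR", bayes_prior_spec())
  expect_true(all(m["SMA", setdiff(cortical_areas(), "SMA")] > 100))
})

test_that("per-area structure contrasts report paired evidence and summaries", {
  tab <- simulate_metric_table(n_subjects = 16, structure_effect = 0.05,
                               noise_sd = 0.02, rng_seed = 21)
  out <- structure_contrast_bf(tab, "value")
  expect_identical(out$area, cortical_areas())
  expect_true(all(out$mean_str > out$mean_stn))
  expect_true(all(out$bf10 > 3))
  expect_identical(out$n, rep(16L, 17))
})
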