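small_table <- function(n_subjects = 4, rng_seed = 5) {
  tab <- expand.grid(subject = seq_len(n_subjects), hemisphere = c("L", "R"),
                     structure = c("STN", "STR"), area = c("A", "B"),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  set.seed(rng_seed)
  tab$value <- 0.5 + 0.1 * (tab$structure == "STR") + rnorm(nrow(tab), 0, 0.05)
  tab
}

test_that("the Monte-Carlo marginal matches a dense-grid dense-matrix oracle", {
  tab <- small_table()
  prior <- bayes_prior_spec(mc_iterations = 20000, rng_seed = 2)
  classes <- subcortfp:::anova_design(tab, "value",
                                      c("structure", "participant"), prior)
  got <- subcortfp:::mc_marginal(tab$value, classes, prior)
  want <- dense_grid_marginal_2g(tab$value,
                                 classes$structure$X, prior$fixed_rscale,
                                 classes$participant$X, prior$random_rscale,
                                 n_grid = 120, lim = 14)
  expect_lt(abs(got$logm - want), 0.05)
  expect_lt(got$rel_se, 0.05)
})

test_that("identical full and reduced models give a Bayes factor of exactly 1", {
  tab <- small_table()
  bf <- jzs_mixed_anova_bf(tab, "value", bayes_prior_spec(),
                           full = c("structure", "area"),
                           reduced = c("structure", "area"))
  expect_identical(bf$bf10, 1)
  expect_identical(bf$mc_error, 0)
})

test_that("the mixed-model BF is reproducible under a fixed seed", {
  tab <- simulate_metric_table(n_subjects = 8, structure_effect = 0.03,
                               rng_seed = 3)
  prior <- bayes_prior_spec(mc_iterations = 2000, rng_seed = 7)
  b1 <- jzs_mixed_anova_bf(tab, "value", prior)
  b2 <- jzs_mixed_anova_bf(tab, "value", prior)
  expect_identical(b1$log_bf10, b2$log_bf10)
})

test_that("an interaction-bearing cohort is detected decisively", {
  inter <- matrix(0, 2, 17,
                  dimnames = list(subcortical_structures(), cortical_areas()))
  inter["STN", c("OFC", "VMPFC")] <- 0.12
  inter["STR", c("OFC", "VMPFC")] <- -0.12
  tab <- simulate_metric_table(n_subjects = 16, structure_effect = 0.04,
                               interaction = inter, rng_seed = 19)
  bf <- jzs_mixed_anova_bf(tab, "value", bayes_prior_spec(mc_iterations = 5000))
  expect_gt(bf$bf10, 100)
})

test_that("additive cohorts favour the reduced model in most replicates", {
  prior <- bayes_prior_spec(mc_iterations = 2000)
  wins <- 0L
  for (i in 1:50) {
    tab <- simulate_metric_table(n_subjects = 16, structure_effect = 0.04,
                                 area_effects = setNames(
                                   seq(-0.08, 0.08, length.out = 17),
                                   cortical_areas()),
                                 rng_seed = 3000 + i)
    if (jzs_mixed_anova_bf(tab, "value", prior)$bf10 < 1) wins <- wins + 1L
  }
  expect_gte(wins / 50, 0.9)
})

test_that("Monte-Carlo error shrinks as the square root of the budget", {
  tab <- simulate_metric_table(n_subjects = 12, structure_effect = 0.03,
                               rng_seed = 55)
  e_small <- jzs_mixed_anova_bf(tab, "value",
                                bayes_prior_spec(mc_iterations = 2000))$mc_error
  e_large <- jzs_mixed_anova_bf(tab, "value",
                                bayes_prior_spec(mc_iterations = 32000))$mc_error
  # budget ratio 16 => expected error ratio 4
  expect_gt(e_small / e_large, 2)
  expect_lt(e_small / e_large, 8)
})

test_that("incomplete designs error unless deletion is acknowledged", {
  tab <- simulate_metric_table(n_subjects = 4, rng_seed = 9)
  tab <- tab[-1, ]
  expect_error(jzs_mixed_anova_bf(tab, "value"), "empty cells")
  bf <- jzs_mixed_anova_bf(tab, "value",
                           bayes_prior_spec(mc_iterations = 2000),
                           allow_incomplete = TRUE)
  expect_true(is.finite(bf$log_bf10))
})

test_that("rank-deficient designs are rejected", {
  tab <- small_table()
  tab$area <- tab$structure  # area aliases structure
  expect_error(jzs_mixed_anova_bf(tab, "value",
                                  bayes_prior_spec(mc_iterations = 1000),
                                  allow_incomplete = TRUE),
               "rank")
})
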