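test_that("phantom masks are disjoint, labelled, and volume-asymmetric", {
  spec <- small_spec()
  masks <- generate_roi_masks(spec)
  expect_setequal(names(masks$L), c("STN", "STR", cortical_areas()))
  expect_setequal(names(masks$R), names(masks$L))
  all_vox <- unlist(lapply(c(masks$L, masks$R), `[[`, "voxels"))
  expect_identical(anyDuplicated(all_vox), 0L)
  expect_lte(mask_size(masks$L$STN) * 10, mask_size(masks$L$STR))

  masks2 <- generate_roi_masks(spec)
  expect_identical(masks, masks2)
})

test_that("mask generation rejects impossible geometry", {
  expect_error(generate_roi_masks(small_spec() |>
    (\(s) { s$grid_dim <- 20L; s })()), "too small")
  expect_error(generate_roi_masks(small_spec(),
                                  cortical_dims = c(0, 6, 6)), "positive")
})

test_that("count maps follow the two-component binomial model", {
  mask <- big_test_mask()

  # disconnected phantom with no spurious background: all zero
  m0 <- generate_count_map(mask, f = 0, p = 0.5, p0 = 0, n_samples = 5000,
                           rng_seed = 5)
  expect_true(all(m0$values == 0))

  # fully connected at p = 0.5: every count within 2500 +/- 250
  # (per-voxel binomial tail outside the band < 1e-10, checked here)
  tail_prob <- pbinom(2249, 5000, 0.5) + pbinom(2750, 5000, 0.5, lower.tail = FALSE)
  expect_lt(tail_prob, 1e-10)
  m1 <- generate_count_map(mask, f = 1, p = 0.5, p0 = 0, n_samples = 5000,
                           rng_seed = 5)
  expect_true(all(m1$values >= 2250 & m1$values <= 2750))

  # determinism
  expect_identical(m1, generate_count_map(mask, 1, 0.5, 0, 5000, 5))

  # sample mean within 4 binomial SDs of n*p at 1000 voxels
  expect_lt(abs(mean(m1$values) - 2500), 4 * sqrt(5000 * 0.25) / sqrt(1000))

  expect_error(generate_count_map(mask, 1.2, 0.5, 0, 5000, 5), "\\[0, 1\\]")
})

test_that("resting-state generator hits the requested correlation structure", {
  # degenerate duplication: off-diagonal 1 reproduces the series exactly
  rho <- matrix(c(1, 1, 0, 1, 1, 0, 0, 0, 1), 3, 3,
                dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  ser <- generate_rsfmri_series(rho, 200, rng_seed = 3)
  expect_equal(cor(ser$A$samples, ser$B$samples), 1, tolerance = 1e-12)

  # identity rho: every off-diagonal sample correlation inside the
  # Fisher 99.9% band 3.29/sqrt(T-3) at T = 1000
  k <- 5
  id <- diag(k); dimnames(id) <- list(letters[1:k], letters[1:k])
  ser2 <- generate_rsfmri_series(id, 1000, rng_seed = 9)
  x <- sapply(ser2, `[[`, "samples")
  cc <- cor(x)
  expect_lt(max(abs(cc[upper.tri(cc)])), 3.29 / sqrt(1000 - 3))

  bad <- matrix(c(1, 0.9, 0.9, 0.9, 1, -0.9, 0.9, -0.9, 1), 3, 3)
  expect_error(generate_rsfmri_series(bad, 100, 1), "semidefinite")
})

test_that("cohort generation is deterministic and respects subject_sd", {
  spec <- small_spec(n_subjects = 2, n_timepoints = 40)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1, c2)

  spec0 <- small_spec(n_subjects = 3, n_timepoints = 40)
  spec0$subject_sd <- 0
  c0 <- generate_cohort(spec0)
  f_wide <- reshape(c0$subject_f[c("subject", "structure", "area", "f")],
                    direction = "wide", idvar = c("structure", "area"),
                    timevar = "subject")
  expect_true(all(f_wide$f.1 == f_wide$f.2 & f_wide$f.2 == f_wide$f.3))
})

test_that("the packaged ground truth orders mean tract strength as encoded", {
  spec <- ground_truth_spec(n_subjects = 8, n_timepoints = 10, rng_seed = 17)
  coh <- generate_cohort(spec)
  tm <- cohort_tract_metrics(coh)
  avg <- aggregate(tract_strength ~ structure + area, tm, mean)
  get <- function(st, ar) avg$tract_strength[avg$structure == st & avg$area == ar]
  expect_gt(get("STR", "M1"), get("STN", "M1"))
  expect_gt(get("STN", "OFC"), get("STR", "OFC"))
})

test_that("metric-table simulator produces a complete balanced design", {
  tab <- simulate_metric_table(n_subjects = 5, rng_seed = 2)
  expect_identical(nrow(tab), 5L * 2L * 2L * 17L)
  expect_identical(tab, simulate_metric_table(n_subjects = 5, rng_seed = 2))
  counts <- table(tab$subject, tab$hemisphere, tab$structure, tab$area)
  expect_true(all(counts == 1))
})

test_that("a written cohort reads back with identical counts and series", {
  spec <- small_spec(n_subjects = 2, n_timepoints = 30)
  coh <- generate_cohort(spec)
  dir <- file.path(tempdir(), "phantom_rt")
  write_phantom_cohort(coh, dir)
  back <- read_phantom_cohort(dir)
  expect_identical(back$masks$L$STN$voxels, coh$masks$L$STN$voxels)
  expect_identical(back$counts[[1]]$L$STN$M1$fwd$values,
                   coh$counts[[1]]$L$STN$M1$fwd$values)
  expect_identical(back$counts[[2]]$R$STR$OFC$rev$values,
                   coh$counts[[2]]$R$STR$OFC$rev$values)
  expect_equal(back$bold[[1]]$L, coh$bold[[1]]$L, tolerance = 1e-12,
               ignore_attr = TRUE)
  unlink(dir, recursive = TRUE)
})

test_that("ground-truth specs round-trip through YAML config", {
  spec <- ground_truth_spec(n_subjects = 4, subject_sd = 0.05, rng_seed = 99)
  cfg <- list(n_subjects = 4, subject_sd = 0.05, rng_seed = 99,
              truth = spec$truth,
              rs_correlation = list(labels = rownames(spec$rs_correlation),
                                    rows = apply(spec$rs_correlation, 1,
                                                 as.numeric, simplify = FALSE)))
  tf <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, tf)
  spec2 <- read_ground_truth_spec(tf)
  expect_equal(spec2$n_subjects, spec$n_subjects)
  expect_equal(spec2$truth$connected_fraction, spec$truth$connected_fraction)
  expect_equal(unname(spec2$rs_correlation), unname(spec$rs_correlation),
               tolerance = 1e-12)
})
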