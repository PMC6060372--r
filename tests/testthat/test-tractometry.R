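mk_map <- function(counts, n_samples = 5000, label = "STN", hemi = "L") {
  grid <- volume_grid(c(8, 8, 8))
  mask <- roi_mask(grid, seq_along(counts) - 1L, label, hemi)
  list(mask = mask,
       map = sample_count_map(mask, counts, n_samples, "M1"))
}

test_that("thresholding keeps exactly the voxels at or above the cutoff", {
  mm <- mk_map(c(0, 49, 50, 5000))
  surv <- threshold_count_map(mm$map, tractometry_params(50, 5000))
  expect_identical(surv$value, c(50, 5000))

  expect_identical(nrow(threshold_count_map(mk_map(rep(0, 6))$map)), 0L)

  mm2 <- mk_map(c(0, 1, 2))
  expect_identical(threshold_count_map(mm2$map, tractometry_params(0, 5000))$value,
                   c(0, 1, 2))
})

test_that("seed ratio averages survivor counts over the sampling depth", {
  expect_equal(seed_ratio_oneway(mk_map(rep(5000, 4))$map), 1.0)
  expect_equal(seed_ratio_oneway(mk_map(rep(10, 4))$map), 0.0)
  expect_equal(seed_ratio_oneway(mk_map(c(50, 150, 3, 0))$map), 0.02)
  # whole-mask averaging mode counts sub-threshold voxels as zero
  expect_equal(seed_ratio_oneway(mk_map(c(50, 150, 3, 0))$map,
                                 survivors_only = FALSE), 0.01)
  expect_error(seed_ratio_oneway(mk_map(c(50, 150))$map,
                                 tractometry_params(50, 100)), "n_samples")
})

test_that("tract strength is the surviving fraction of the seed mask", {
  counts <- c(rep(100, 25), rep(10, 75))
  mm <- mk_map(counts)
  expect_equal(tract_strength_oneway(mm$map, mm$mask), 0.25)
  mm_all <- mk_map(rep(60, 10))
  expect_equal(tract_strength_oneway(mm_all$map, mm_all$mask), 1.0)
  mm_none <- mk_map(rep(3, 10))
  expect_equal(tract_strength_oneway(mm_none$map, mm_none$mask), 0.0)
})

test_that("bidirectional averaging is a strict two-argument mean", {
  expect_equal(bidirectional_average(0.2, 0.4), 0.3)
  expect_equal(bidirectional_average(0.77, 0.77), 0.77)
  expect_equal(bidirectional_average(0.0, 1.0), 0.5)
  expect_error(bidirectional_average(0.2, NULL), "both")
  expect_error(bidirectional_average(NA, 0.2), "both")
})

test_that("the combined record averages directions, each normalised by its own mask", {
  grid <- volume_grid(c(12, 12, 12))
  seed <- roi_mask(grid, 0:9, "STN", "L")            # 10 voxels
  target <- roi_mask(grid, 100:119, "M1", "L")       # 20 voxels
  fwd <- sample_count_map(seed, rep(100, 10), 5000, "M1")     # all survive
  rev <- sample_count_map(target, c(rep(100, 10), rep(0, 10)), 5000, "STN")
  rec <- compute_tract_metrics(seed, target, fwd, rev)
  expect_equal(rec$tract_strength, (1.0 + 0.5) / 2)
  expect_equal(rec$seed_ratio, (0.02 + 0.02) / 2)
  expect_identical(rec$structure, "STN")
  expect_identical(rec$area, "M1")

  # identical forward/reverse maps collapse to the one-way values
  seed2 <- roi_mask(grid, 200:209, "STN", "L")
  f2 <- sample_count_map(seed2, rep(250, 10), 5000, "M1")
  rec2 <- compute_tract_metrics(seed2, seed2, f2, f2)
  expect_equal(rec2$seed_ratio, 0.05)
  expect_equal(rec2$tract_strength, 1.0)

  expect_error(compute_tract_metrics(seed, target, fwd, fwd), "reverse")
})

test_that("metrics are invariant to voxel permutation and monotone in counts", {
  set.seed(31)
  for (rep in 1:5) {
    counts <- rbinom(200, 5000, runif(1, 0.005, 0.05))
    mm <- mk_map(counts)
    perm <- sample(counts)
    mmp <- mk_map(perm)
    expect_equal(seed_ratio_oneway(mm$map), seed_ratio_oneway(mmp$map))
    expect_equal(tract_strength_oneway(mm$map, mm$mask),
                 tract_strength_oneway(mmp$map, mmp$mask))

    bumped <- pmin(counts + sample(0:30, 200, replace = TRUE), 5000)
    mmb <- mk_map(bumped)
    expect_gte(tract_strength_oneway(mmb$map, mmb$mask),
               tract_strength_oneway(mm$map, mm$mask))
  }
})

test_that("both metrics match a naive voxel-loop re-implementation exactly", {
  set.seed(77)
  for (rep in 1:10) {
    n_vox <- sample(50:1000, 1)
    counts <- rbinom(n_vox, 5000, runif(1, 0.001, 0.1))
    grid <- volume_grid(c(10, 10, 10))
    mask <- roi_mask(grid, seq_len(n_vox) - 1L, "STN", "L")
    map <- sample_count_map(mask, counts, 5000, "M1")
    expect_equal(seed_ratio_oneway(map),
                 naive_seed_ratio(counts, 5000, 50), tolerance = 1e-12)
    expect_equal(seed_ratio_oneway(map, survivors_only = FALSE),
                 naive_seed_ratio(counts, 5000, 50, survivors_only = FALSE),
                 tolerance = 1e-12)
    expect_identical(tract_strength_oneway(map, mask),
                     naive_tract_strength(counts, 50, n_vox))
  }
})

test_that("distance-corrected maps pass through with a warning attribute", {
  grid <- volume_grid(c(8, 8, 8))
  mask <- roi_mask(grid, 0:3, "STN", "L")
  map <- sample_count_map(mask, c(10.5, 80.2, 6000.7, 49.9), 5000, "M1",
                          distance_corrected = TRUE)
  r <- seed_ratio_oneway(map)
  expect_equal(as.numeric(r), mean(c(80.2, 6000.7) / 5000))
  expect_match(attr(r, "warning"), "distance")
})
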