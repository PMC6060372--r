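#' @title Synthetic phantom cohorts with known ground truth
#' @description
#' The generator emulates the *outputs* of the out-of-scope preprocessing
#' chain — co-registered ROI masks, probabilistic-tractography sample-count
#' maps, and ROI-level BOLD series — on a shared voxel grid, with every
#' generative parameter recorded so downstream metric and Bayes-factor
#' recovery can be tested against truth. Counts are drawn per voxel
#' independently: a seed voxel is truly connected with probability `f`, a
#' connected voxel's count is Binomial(`n_samples`, `p`), an unconnected
#' one's Binomial(`n_samples`, `p0`) with `p0 << p`. No spatial
#' autocorrelation, scanner noise or motion is simulated.
#' @name synthetic-data
NULL

# One global seed expands into substreams through a fixed affine counter
# scheme (documented in the methods vignette), so any part of a cohort can
# be regenerated in isolation, bit-exactly.
substream_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(counter) * 7919) %% 2147483647)
}

with_substream <- function(seed, counter, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(substream_seed(seed, counter))
  expr
}

# Substream counter blocks (per component, disjoint)
CTR_SUBJECT_F   <- 1000L
CTR_COUNT_MAPS  <- 10000L
CTR_RS_SERIES   <- 500000L
CTR_RS_JITTER   <- 600000L

# ---- masks ------------------------------------------------------------------

#' Generate the phantom ROI masks
#'
#' Places disjoint rectangular blobs on a cubic grid: 17 cortical boxes, one
#' small STN box and one STR box ten times its volume, per hemisphere
#' (hemispheres occupy the two x-halves of the grid). Placement is
#' deterministic — a fixed cell lattice — so masks depend only on the grid
#' size and the requested voxel counts.
#'
#' @param spec a [ground_truth_spec()]; only `grid_dim` is used here.
#' @param cortical_dims,stn_dims,str_dims integer triples giving each box
#'   shape. Defaults: 6x6x6 cortical, 4x4x4 STN, 8x10x8 STR (STR volume
#'   exactly ten times the STN's, emulating the real volume asymmetry).
#' @return named list `masks[[hemisphere]][[label]]` of [roi_mask()] objects.
#' @export
generate_roi_masks <- function(spec,
                               cortical_dims = c(6L, 6L, 6L),
                               stn_dims = c(4L, 4L, 4L),
                               str_dims = c(8L, 10L, 8L)) {
  stopifnot(inherits(spec, "ground_truth_spec"))
  for (d in list(cortical_dims, stn_dims, str_dims))
    if (length(d) != 3L || any(d < 1L)) stop("ROI box dimensions must be positive triples")
  if (prod(stn_dims) * 10 > prod(str_dims))
    stop("STN volume must be at most one tenth of the STR volume")
  gd <- spec$grid_dim
  grid <- volume_grid(c(gd, gd, gd))
  half <- gd %/% 2L
  cell <- c(max(8L, max(str_dims[1], cortical_dims[1]) + 1L),
            max(12L, str_dims[2] + 1L),
            max(12L, str_dims[3] + 1L))
  n_cells <- (half %/% cell[1]) * (gd %/% cell[2]) * (gd %/% cell[3])
  labels <- c(subcortical_structures(), cortical_areas())
  if (n_cells < length(labels))
    stop("grid too small to place all ROIs disjointly (", n_cells,
         " cells for ", length(labels), " ROIs)")
  box_dims <- c(list(STN = stn_dims, STR = str_dims),
                stats::setNames(rep(list(cortical_dims), 17), cortical_areas()))
  nx <- half %/% cell[1]; ny <- gd %/% cell[2]
  masks <- list()
  for (h in c("L", "R")) {
    hx <- if (h == "L") 0L else half
    masks[[h]] <- list()
    for (li in seq_along(labels)) {
      lab <- labels[li]
      ci <- li - 1L
      corner <- c(hx + (ci %% nx) * cell[1],
                  ((ci %/% nx) %% ny) * cell[2],
                  (ci %/% (nx * ny)) * cell[3])
      bd <- box_dims[[lab]]
      ii <- corner[1] + seq_len(bd[1]) - 1L
      jj <- corner[2] + seq_len(bd[2]) - 1L
      kk <- corner[3] + seq_len(bd[3]) - 1L
      idx <- as.vector(outer(outer(ii, jj * gd, `+`), kk * gd * gd, `+`))
      masks[[h]][[lab]] <- roi_mask(grid, sort(idx), lab, h)
    }
  }
  masks
}

# ---- count maps -------------------------------------------------------------

#' Generate one directed sample-count map
#'
#' Each seed voxel is independently flagged "truly connected" with
#' probability `f`; connected voxels draw their count from
#' Binomial(`n_samples`, `p`), unconnected ones from
#' Binomial(`n_samples`, `p0`).
#'
#' @param seed_mask the [roi_mask()] to seed in.
#' @param f connected-voxel fraction in `[0, 1]`.
#' @param p,p0 per-sample reach probabilities for connected / unconnected
#'   voxels.
#' @param n_samples samples per voxel.
#' @param rng_seed integer seed; the same seed reproduces the map bit-exactly.
#' @param target_label label recorded as the tract's target.
#' @return a [sample_count_map()] with `distance_corrected = FALSE`.
#' @export
generate_count_map <- function(seed_mask, f, p, p0, n_samples, rng_seed,
                               target_label = "target") {
  stopifnot(inherits(seed_mask, "roi_mask"))
  for (prob in c(f, p, p0))
    if (!is.finite(prob) || prob < 0 || prob > 1)
      stop("f, p and p0 must lie in [0, 1]")
  n <- mask_size(seed_mask)
  if (n == 0L) stop("empty seed mask")
  counts <- with_substream(rng_seed, 0L, {
    connected <- stats::runif(n) < f
    k <- integer(n)
    k[connected] <- stats::rbinom(sum(connected), n_samples, p)
    k[!connected] <- stats::rbinom(sum(!connected), n_samples, p0)
    k
  })
  sample_count_map(seed_mask, counts, n_samples, target_label,
                   distance_corrected = FALSE)
}

# ---- resting-state series ---------------------------------------------------

#' Generate correlated Gaussian ROI time series
#'
#' Zero-mean unit-variance Gaussian series whose population correlation is
#' `rho`, obtained by applying the symmetric eigenvalue square root of `rho`
#' to independent noise (so exact rank deficiency, e.g. a duplicated ROI
#' with off-diagonal 1, is handled exactly).
#'
#' @param rho symmetric positive-semidefinite correlation matrix with ROI
#'   labels as dimnames.
#' @param n_timepoints series length T >= 2.
#' @param rng_seed integer seed.
#' @param hemisphere hemisphere tag recorded on each series.
#' @return named list of [roi_timeseries()], one per row of `rho`.
#' @export
generate_rsfmri_series <- function(rho, n_timepoints, rng_seed, hemisphere = "L") {
  check_correlation_matrix(rho)
  if (n_timepoints < 2L) stop("need at least 2 timepoints")
  labels <- rownames(rho)
  if (is.null(labels)) labels <- paste0("ROI", seq_len(nrow(rho)))
  eg <- eigen(rho, symmetric = TRUE)
  root <- eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))
  x <- with_substream(rng_seed, 0L, {
    z <- matrix(stats::rnorm(n_timepoints * nrow(rho)), n_timepoints, nrow(rho))
    z %*% root
  })
  stats::setNames(lapply(seq_along(labels), function(i)
    roi_timeseries(x[, i], labels[i], hemisphere)), labels)
}

# per-subject correlation: Fisher-z jitter of the off-diagonals, repaired to
# the nearest correlation matrix when the perturbation breaks PSD-ness
jitter_correlation <- function(rho, sd, rng_seed) {
  if (sd == 0) return(rho)
  k <- nrow(rho)
  z <- atanh(pmin(pmax(rho, -0.999999), 0.999999))
  noise <- with_substream(rng_seed, 0L, matrix(stats::rnorm(k * k, 0, sd), k, k))
  noise <- (noise + t(noise)) / sqrt(2)
  zj <- z + noise
  rj <- tanh(zj)
  diag(rj) <- 1
  ev <- eigen(rj, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10) {
    rj <- as.matrix(Matrix::nearPD(rj, corr = TRUE)$mat)
    dimnames(rj) <- dimnames(rho)
  }
  rj
}

# ---- cohort -----------------------------------------------------------------

tract_design <- function() {
  expand.grid(hemisphere = c("L", "R"), area = cortical_areas(),
              structure = subcortical_structures(),
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)[, 3:1]
}

#' Generate a full phantom cohort
#'
#' Produces, for each subject: jittered per-(structure, area) connected
#' fractions (clipped to `[0, 1]`), forward (structure -> area) and reverse
#' (area -> structure) sample-count maps per hemisphere, and per-hemisphere
#' ROI time-series matrices drawn from the subject's jittered correlation
#' matrix. Masks are shared across subjects (one co-registered phantom
#' geometry). Regenerating with the same `rng_seed` reproduces the cohort
#' bit-exactly.
#'
#' @param spec a [ground_truth_spec()].
#' @return an object of class `phantom_cohort`: list with `spec`, `masks`,
#'   `subject_f` (data.frame subject x structure x area -> f), `counts`
#'   (`counts[[subject]][[hemi]][[structure]][[area]]` = list(fwd, rev)),
#'   and `bold` (`bold[[subject]][[hemi]]` = T x 19 matrix).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "ground_truth_spec"))
  masks <- generate_roi_masks(spec)
  design <- tract_design()
  truth <- spec$truth
  key <- paste(truth$structure, truth$area)
  n_sub <- spec$n_subjects

  subject_f <- do.call(rbind, lapply(seq_len(n_sub), function(s) {
    jit <- with_substream(spec$rng_seed, CTR_SUBJECT_F + s,
                          stats::rnorm(nrow(truth), 0, spec$subject_sd))
    data.frame(subject = s, structure = truth$structure, area = truth$area,
               f = pmin(pmax(truth$connected_fraction + jit, 0), 1),
               p = truth$reach_probability)
  }))

  counts <- vector("list", n_sub)
  ctr <- CTR_COUNT_MAPS
  for (s in seq_len(n_sub)) {
    counts[[s]] <- list(L = list(STN = list(), STR = list()),
                        R = list(STN = list(), STR = list()))
    fs <- subject_f[subject_f$subject == s, ]
    for (r in seq_len(nrow(design))) {
      st <- design$structure[r]; ar <- design$area[r]; h <- design$hemisphere[r]
      row <- fs[fs$structure == st & fs$area == ar, ]
      fwd <- generate_count_map(masks[[h]][[st]], row$f, row$p,
                                spec$background_probability, spec$n_samples,
                                substream_seed(spec$rng_seed, ctr),
                                target_label = ar)
      rev <- generate_count_map(masks[[h]][[ar]], row$f, row$p,
                                spec$background_probability, spec$n_samples,
                                substream_seed(spec$rng_seed, ctr + 1L),
                                target_label = st)
      counts[[s]][[h]][[st]][[ar]] <- list(fwd = fwd, rev = rev)
      ctr <- ctr + 2L
    }
  }

  bold <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    rho_s <- jitter_correlation(spec$rs_correlation, spec$subject_sd,
                                substream_seed(spec$rng_seed, CTR_RS_JITTER + s))
    bold[[s]] <- list()
    for (h in c("L", "R")) {
      series <- generate_rsfmri_series(rho_s, spec$n_timepoints,
                                       substream_seed(spec$rng_seed,
                                                      CTR_RS_SERIES + 2L * s +
                                                        (h == "R")),
                                       hemisphere = h)
      bold[[s]][[h]] <- sapply(series, function(ts) ts$samples)
    }
  }

  structure(list(spec = spec, masks = masks, subject_f = subject_f,
                 counts = counts, bold = bold),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("<phantom_cohort> %d subjects, %d ROI labels/hemisphere, T=%d\n",
              x$spec$n_subjects, length(x$masks$L), x$spec$n_timepoints))
  invisible(x)
}

# ---- metric-level simulator -------------------------------------------------

#' Simulate a fingerprint metric table directly at the record level
#'
#' A lightweight companion to [generate_cohort()] for statistical tests:
#' draws one value per (subject, hemisphere, structure, area) cell from an
#' additive linear model with optional structure x area interaction, Gaussian
#' subject and hemisphere effects, and residual noise. Useful for checking
#' the mixed-model Bayes factor under known additive or interaction-bearing
#' truth without simulating any volumes.
#'
#' @param n_subjects number of subjects.
#' @param mu grand mean.
#' @param structure_effect half-difference between STR and STN (STR gets
#'   `+structure_effect`, STN `-structure_effect`).
#' @param area_effects named numeric vector over areas (recycled as 0 when
#'   missing); centred internally.
#' @param interaction optional matrix/data.frame of per-(structure, area)
#'   deviations, or `NULL` for a purely additive table.
#' @param subject_sd,hemisphere_sd,noise_sd standard deviations of the
#'   random subject effect, random hemisphere effect and residual.
#' @param rng_seed integer seed.
#' @return long data.frame: subject, hemisphere, structure, area, value.
#' @export
simulate_metric_table <- function(n_subjects = 16L, mu = 0.6,
                                  structure_effect = 0, area_effects = NULL,
                                  interaction = NULL, subject_sd = 0.03,
                                  hemisphere_sd = 0.01, noise_sd = 0.05,
                                  rng_seed = 1L) {
  areas <- cortical_areas()
  tab <- expand.grid(subject = seq_len(n_subjects), hemisphere = c("L", "R"),
                     structure = subcortical_structures(), area = areas,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ae <- stats::setNames(rep(0, length(areas)), areas)
  if (!is.null(area_effects)) ae[names(area_effects)] <- area_effects
  ae <- ae - mean(ae)
  inter <- matrix(0, 2, length(areas),
                  dimnames = list(subcortical_structures(), areas))
  if (!is.null(interaction)) {
    interaction <- as.matrix(interaction)
    inter[rownames(interaction), colnames(interaction)] <- interaction
    inter <- inter - mean(inter)
  }
  with_substream(rng_seed, 0L, {
    subj_eff <- stats::rnorm(n_subjects, 0, subject_sd)
    hemi_eff <- stats::rnorm(2, 0, hemisphere_sd)
    tab$value <- mu +
      ifelse(tab$structure == "STR", structure_effect, -structure_effect) +
      ae[tab$area] + inter[cbind(tab$structure, tab$area)] +
      subj_eff[tab$subject] + hemi_eff[(tab$hemisphere == "R") + 1L] +
      stats::rnorm(nrow(tab), 0, noise_sd)
  })
  rownames(tab) <- NULL
  tab
}

# ---- disk round-trip --------------------------------------------------------

#' Write a phantom cohort to a directory tree
#'
#' Masks and count maps are written as compressed NIfTI-1 volumes with a
#' sidecar CSV (`filename,label,hemisphere,role,subject,target`); ROI time
#' series are written as one CSV per subject and hemisphere (column `t` plus
#' one column per ROI label). Intended for exercising the disk-based analyze
#' path on small cohorts; the in-memory cohort is the default pipeline input.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  grid <- cohort$masks$L[[1]]$grid
  rows <- list()
  ns <- cohort$counts[[1]]$L$STN[[1]]$fwd$n_samples
  add <- function(fn, label, hemi, role, subject = NA, target = NA)
    rows[[length(rows) + 1L]] <<- data.frame(filename = fn, label = label,
                                             hemisphere = hemi, role = role,
                                             subject = subject, target = target,
                                             n_samples = ns)
  for (h in c("L", "R")) for (lab in names(cohort$masks[[h]])) {
    fn <- sprintf("mask_%s_%s.nii.gz", lab, h)
    write_volume(mask_array(cohort$masks[[h]][[lab]]), grid,
                 file.path(dir, fn), datatype = "uint8")
    add(fn, lab, h, "mask")
  }
  for (s in seq_along(cohort$counts)) for (h in c("L", "R"))
    for (st in subcortical_structures())
      for (ar in names(cohort$counts[[s]][[h]][[st]])) {
        pair <- cohort$counts[[s]][[h]][[st]][[ar]]
        fn_f <- sprintf("counts_s%02d_%s_%s_to_%s.nii.gz", s, h, st, ar)
        fn_r <- sprintf("counts_s%02d_%s_%s_to_%s.nii.gz", s, h, ar, st)
        write_volume(count_map_array(pair$fwd), grid, file.path(dir, fn_f),
                     datatype = "int32")
        write_volume(count_map_array(pair$rev), grid, file.path(dir, fn_r),
                     datatype = "int32")
        add(fn_f, st, h, "count_map_fwd", s, ar)
        add(fn_r, ar, h, "count_map_rev", s, st)
      }
  for (s in seq_along(cohort$bold)) for (h in c("L", "R")) {
    fn <- sprintf("bold_s%02d_%s.csv", s, h)
    m <- cohort$bold[[s]][[h]]
    utils::write.csv(cbind(t = seq_len(nrow(m)), as.data.frame(m)),
                     file.path(dir, fn), row.names = FALSE)
    add(fn, "all", h, "bold", s)
  }
  utils::write.csv(do.call(rbind, rows), file.path(dir, "sidecar.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a phantom cohort back from a directory tree
#'
#' Inverse of [write_phantom_cohort()]; reconstructs masks, sparse count
#' maps and BOLD matrices from the sidecar CSV.
#'
#' @param dir directory written by [write_phantom_cohort()].
#' @return a `phantom_cohort` (without the generator `spec` and `subject_f`,
#'   which are generator-side knowledge).
#' @export
read_phantom_cohort <- function(dir) {
  sc <- utils::read.csv(file.path(dir, "sidecar.csv"), stringsAsFactors = FALSE)
  masks <- list(L = list(), R = list())
  grid <- NULL
  for (r in which(sc$role == "mask")) {
    v <- read_volume(file.path(dir, sc$filename[r]))
    if (is.null(grid)) grid <- v$grid
    masks[[sc$hemisphere[r]]][[sc$label[r]]] <-
      roi_mask(grid, v$values > 0, sc$label[r], sc$hemisphere[r])
  }
  subjects <- sort(unique(sc$subject[!is.na(sc$subject)]))
  counts <- vector("list", length(subjects))
  for (s in subjects) {
    counts[[s]] <- list(L = list(STN = list(), STR = list()),
                        R = list(STN = list(), STR = list()))
    for (r in which(sc$role == "count_map_fwd" & sc$subject == s)) {
      h <- sc$hemisphere[r]; st <- sc$label[r]; ar <- sc$target[r]
      vf <- read_volume(file.path(dir, sc$filename[r]))$values
      rr <- which(sc$role == "count_map_rev" & sc$subject == s &
                    sc$hemisphere == h & sc$label == ar & sc$target == st)
      vr <- read_volume(file.path(dir, sc$filename[rr]))$values
      ns <- sc$n_samples[r]
      counts[[s]][[h]][[st]][[ar]] <- list(
        fwd = sample_count_map(masks[[h]][[st]],
                               restrict_to_mask(vf, masks[[h]][[st]])$value,
                               ns, ar),
        rev = sample_count_map(masks[[h]][[ar]],
                               restrict_to_mask(vr, masks[[h]][[ar]])$value,
                               ns, st))
    }
  }
  bold <- vector("list", length(subjects))
  for (s in subjects) {
    bold[[s]] <- list()
    for (r in which(sc$role == "bold" & sc$subject == s)) {
      m <- utils::read.csv(file.path(dir, sc$filename[r]))
      bold[[s]][[sc$hemisphere[r]]] <- as.matrix(m[, -1, drop = FALSE])
    }
  }
  structure(list(spec = NULL, masks = masks, subject_f = NULL,
                 counts = counts, bold = bold),
            class = "phantom_cohort")
}
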