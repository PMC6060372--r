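#' The 17 cortical areas of the fingerprint design
#'
#' Abbreviations for the cortical areas with established non-human-primate
#' tracer evidence of projections to both the subthalamic nucleus (STN) and
#' the striatum (STR): primary motor cortex (M1), pre-motor cortex (preM1),
#' supplementary and pre-supplementary motor areas (SMA, preSMA), frontal
#' eye fields (FEF), dorsolateral prefrontal cortex (DLPFC), frontopolar
#' area (FPA), ventromedial/lateral prefrontal cortex (VMPFC),
#' orbitofrontal cortex (OFC), inferior frontal sulcus and junction (IFS,
#' IFJ), inferior frontal gyrus pars opercularis and triangularis (POP,
#' PTR), cingulate cortex (CIN), cingulate motor area (CMA), perigenual and
#' subgenual areas (PGA, SGA).
#'
#' @return character vector of length 17.
#' @export
cortical_areas <- function() {
  c("M1", "preM1", "SMA", "preSMA", "FEF", "DLPFC", "FPA", "VMPFC", "OFC",
    "IFS", "IFJ", "POP", "PTR", "CIN", "CMA", "PGA", "SGA")
}

#' Subcortical structure labels
#' @return `c("STN", "STR")`.
#' @export
subcortical_structures <- function() c("STN", "STR")

# Default per-(structure, area) ground truth. Connected fractions f encode
# the qualitative pattern of the study: the striatum is the more densely
# connected structure for 15 of the 17 areas, while the orbitofrontal and
# ventromedial prefrontal cortices connect more densely to the STN. Gaps are
# kept >= 0.10 so the encoded sign is decisively recoverable from 16
# subjects (expected paired t ~ 7 at the default subject_sd). Reach
# probabilities p are the per-structure mean seed ratios of the study design.
default_truth_table <- function() {
  areas <- cortical_areas()
  f_stn <- c(0.71, 0.62, 0.74, 0.64, 0.43, 0.66, 0.69, 0.57, 0.45,
             0.66, 0.61, 0.48, 0.61, 0.64, 0.74, 0.68, 0.22)
  f_str <- c(0.84, 0.72, 0.84, 0.74, 0.65, 0.76, 0.79, 0.39, 0.30,
             0.76, 0.73, 0.70, 0.71, 0.78, 0.84, 0.78, 0.32)
  p_stn <- c(0.21, 0.18, 0.19, 0.18, 0.19, 0.18, 0.18, 0.15, 0.15,
             0.19, 0.20, 0.17, 0.17, 0.19, 0.17, 0.17, 0.13)
  p_str <- c(0.18, 0.16, 0.16, 0.16, 0.17, 0.16, 0.15, 0.14, 0.15,
             0.17, 0.17, 0.17, 0.17, 0.17, 0.16, 0.16, 0.14)
  rbind(
    data.frame(structure = "STN", area = areas, connected_fraction = f_stn,
               reach_probability = p_stn),
    data.frame(structure = "STR", area = areas, connected_fraction = f_str,
               reach_probability = p_str)
  )
}

# Default population correlation over the 19 ROI labels of one hemisphere:
# moderate cortico-cortical coupling, stronger striatal than subthalamic
# functional connectivity to cortex.
default_rs_correlation <- function() {
  labels <- c(subcortical_structures(), cortical_areas())
  k <- length(labels)
  rho <- matrix(0.25, k, k, dimnames = list(labels, labels))
  rho["STN", ] <- rho[, "STN"] <- 0.10
  rho["STR", ] <- rho[, "STR"] <- 0.50
  rho["STN", "STR"] <- rho["STR", "STN"] <- 0.20
  diag(rho) <- 1
  rho
}

#' Ground-truth specification for the phantom cohort generator
#'
#' Bundles every knob the synthetic-data generator needs: per-(structure,
#' area) connected seed-voxel fractions and per-sample reach probabilities,
#' the background reach probability of unconnected voxels, the tractography
#' sampling depth, the cohort size, the between-subject variability, and the
#' population ROI correlation matrix for the resting-state series.
#'
#' @param truth data.frame with columns `structure`, `area`,
#'   `connected_fraction`, `reach_probability`; defaults to the packaged
#'   pattern (see Details in the methods vignette).
#' @param background_probability per-sample reach probability of an
#'   unconnected seed voxel (spurious streamlines); default 1e-4.
#' @param n_samples streamline samples per seed voxel; study value 5000.
#' @param n_subjects cohort size; study value 16.
#' @param subject_sd between-subject SD applied to the connected fractions
#'   and to the Fisher-transformed correlations; default 0.03.
#' @param rs_correlation symmetric positive-semidefinite correlation matrix
#'   over the 19 ROI labels (applied per hemisphere).
#' @param n_timepoints resting-state series length; default 500.
#' @param grid_dim edge length of the cubic phantom grid; default 48.
#' @param rng_seed global seed expanded into per-(subject, tract, direction)
#'   substreams.
#' @return an object of class `ground_truth_spec`.
#' @export
ground_truth_spec <- function(truth = default_truth_table(),
                              background_probability = 1e-4,
                              n_samples = 5000L,
                              n_subjects = 16L,
                              subject_sd = 0.03,
                              rs_correlation = default_rs_correlation(),
                              n_timepoints = 500L,
                              grid_dim = 48L,
                              rng_seed = 20260925L) {
  need <- c("structure", "area", "connected_fraction", "reach_probability")
  if (!all(need %in% names(truth))) stop("'truth' must have columns: ",
                                         paste(need, collapse = ", "))
  if (any(truth$connected_fraction < 0 | truth$connected_fraction > 1) ||
      any(truth$reach_probability < 0 | truth$reach_probability > 1))
    stop("fractions and probabilities must lie in [0, 1]")
  if (background_probability < 0 || background_probability > 1)
    stop("'background_probability' must lie in [0, 1]")
  if (n_subjects < 2L) stop("'n_subjects' must be at least 2")
  if (n_samples < 1L) stop("'n_samples' must be positive")
  if (subject_sd < 0) stop("'subject_sd' must be nonnegative")
  check_correlation_matrix(rs_correlation)
  structure(list(truth = truth,
                 background_probability = background_probability,
                 n_samples = as.integer(n_samples),
                 n_subjects = as.integer(n_subjects),
                 subject_sd = subject_sd,
                 rs_correlation = rs_correlation,
                 n_timepoints = as.integer(n_timepoints),
                 grid_dim = as.integer(grid_dim),
                 rng_seed = as.integer(rng_seed)),
            class = "ground_truth_spec")
}

check_correlation_matrix <- function(rho, tol = 1e-8) {
  if (!is.matrix(rho) || nrow(rho) != ncol(rho))
    stop("correlation matrix must be square")
  if (max(abs(rho - t(rho))) > tol) stop("correlation matrix must be symmetric")
  if (max(abs(diag(rho) - 1)) > tol) stop("correlation matrix must have unit diagonal")
  ev <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(abs(ev)))
    stop("correlation matrix must be positive semidefinite")
  invisible(TRUE)
}

#' Read a ground-truth spec from a YAML or JSON config
#'
#' Keys mirror the [ground_truth_spec()] arguments; `truth` is a list of
#' records and `rs_correlation` a nested list of rows with a `labels` key.
#' Missing keys fall back to the packaged defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a `ground_truth_spec`.
#' @export
read_ground_truth_spec <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  args <- list()
  if (!is.null(cfg$truth)) args$truth <- as.data.frame(cfg$truth)
  if (!is.null(cfg$rs_correlation)) {
    m <- do.call(rbind, lapply(cfg$rs_correlation$rows, as.numeric))
    dimnames(m) <- list(cfg$rs_correlation$labels, cfg$rs_correlation$labels)
    args$rs_correlation <- m
  }
  for (k in c("background_probability", "n_samples", "n_subjects", "subject_sd",
              "n_timepoints", "grid_dim", "rng_seed"))
    if (!is.null(cfg[[k]])) args[[k]] <- cfg[[k]]
  do.call(ground_truth_spec, args)
}
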