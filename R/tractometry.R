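#' Tractometry parameters
#'
#' @param min_samples survivor threshold: a seed voxel is kept when its
#'   sample count is at least this value (inclusive). Study value 50.
#' @param n_samples total streamline samples launched per voxel. Study
#'   value 5000.
#' @return an object of class `tractometry_params`.
#' @export
tractometry_params <- function(min_samples = 50, n_samples = 5000L) {
  if (n_samples <= 0) stop("'n_samples' must be positive")
  if (min_samples < 0 || min_samples > n_samples)
    stop("'min_samples' must lie in [0, n_samples]")
  structure(list(min_samples = min_samples, n_samples = as.integer(n_samples)),
            class = "tractometry_params")
}

#' Threshold a sample-count map
#'
#' Removes spurious connections: only seed voxels whose count is at least
#' `min_samples` survive. An empty survivor set is a valid result.
#'
#' @param map a [sample_count_map()].
#' @param params a [tractometry_params()].
#' @return data.frame with columns `voxel` (0-based index) and `value` for
#'   the surviving voxels, in lexicographic voxel order.
#' @export
threshold_count_map <- function(map, params = tractometry_params()) {
  stopifnot(inherits(map, "sample_count_map"), inherits(params, "tractometry_params"))
  keep <- map$values >= params$min_samples
  data.frame(voxel = map$seed_voxels[keep], value = map$values[keep])
}

#' One-way tract seed ratio
#'
#' Each surviving voxel's count is divided by the number of samples launched
#' per voxel, and the resulting per-voxel ratios are averaged — the mean
#' fraction of samples that reached the target, among voxels that cleared
#' the spurious-connection threshold. Returns 0 when no voxel survives (an
#' unconnected tract has zero measured connectivity). With
#' `survivors_only = FALSE` the mean is instead taken over all seed voxels,
#' with sub-threshold voxels contributing 0.
#'
#' @param map a [sample_count_map()].
#' @param params a [tractometry_params()]; `params$n_samples` must match the
#'   map's.
#' @param survivors_only average over surviving voxels (default) or over the
#'   whole seed mask.
#' @return ratio in `[0, 1]` for uncorrected maps. For distance-corrected
#'   maps the value may exceed 1 and a warning is attached
#'   (attribute `"warning"`).
#' @export
seed_ratio_oneway <- function(map, params = tractometry_params(),
                              survivors_only = TRUE) {
  stopifnot(inherits(map, "sample_count_map"))
  if (params$n_samples != map$n_samples)
    stop("params$n_samples (", params$n_samples, ") does not match the map's (",
         map$n_samples, ")")
  surv <- threshold_count_map(map, params)
  ratio <- if (survivors_only) {
    if (nrow(surv) == 0L) 0 else mean(surv$value / map$n_samples)
  } else {
    sum(surv$value / map$n_samples) / length(map$seed_voxels)
  }
  if (map$distance_corrected)
    attr(ratio, "warning") <- "map is distance-corrected; ratio is not bounded by 1"
  ratio
}

#' One-way tract strength
#'
#' The fraction of seed-mask voxels whose sample count clears the threshold:
#' a volume-normalised index of how much of the seed region is
#' probabilistically connected to the target.
#'
#' @inheritParams seed_ratio_oneway
#' @param seed_mask the [roi_mask()] the map was seeded in; the map's
#'   support must lie within it.
#' @return ratio in `[0, 1]`.
#' @export
tract_strength_oneway <- function(map, seed_mask, params = tractometry_params()) {
  stopifnot(inherits(map, "sample_count_map"), inherits(seed_mask, "roi_mask"))
  if (mask_size(seed_mask) == 0L) stop("empty seed mask")
  if (!all(map$seed_voxels[map$values > 0] %in% seed_mask$voxels))
    stop("count map has nonzero support outside the seed mask")
  nrow(threshold_count_map(map, params)) / mask_size(seed_mask)
}

#' Average a metric over the two tracking directions
#'
#' Both directed tractography runs (seed-to-target and target-to-seed)
#' contribute equally; a missing direction is an error, never a silent
#' one-way fallback.
#'
#' @param forward_value,reverse_value the two one-way ratios.
#' @return their arithmetic mean.
#' @export
bidirectional_average <- function(forward_value, reverse_value) {
  if (is.null(forward_value) || is.null(reverse_value) ||
      length(forward_value) != 1L || length(reverse_value) != 1L ||
      is.na(forward_value) || is.na(reverse_value))
    stop("both tracking directions must be present")
  (as.numeric(forward_value) + as.numeric(reverse_value)) / 2
}

#' Compute both tract metrics for one tract
#'
#' Seed ratio and tract strength are each computed one-way in both tracking
#' directions and averaged. Each direction's strength is normalised by its
#' own seed mask's voxel count (the forward map is seeded in `seed_mask`,
#' the reverse map in `target_mask`).
#'
#' @param seed_mask,target_mask the two [roi_mask()]s.
#' @param map_fwd,map_rev the directed [sample_count_map()]s (forward seeded
#'   in `seed_mask`, reverse in `target_mask`).
#' @param params a [tractometry_params()]; `NULL` uses the study threshold
#'   of 50 with the maps' own `n_samples`.
#' @param subject subject identifier carried into the record.
#' @param survivors_only passed to [seed_ratio_oneway()].
#' @return one-row data.frame: subject, hemisphere, structure, area,
#'   seed_ratio, tract_strength, n_samples, min_samples.
#' @export
compute_tract_metrics <- function(seed_mask, target_mask, map_fwd, map_rev,
                                  params = NULL, subject = NA,
                                  survivors_only = TRUE) {
  if (is.null(params)) params <- tractometry_params(50, map_fwd$n_samples)
  if (!identical(map_fwd$seed_voxels, seed_mask$voxels))
    stop("forward map is not seeded in 'seed_mask'")
  if (!identical(map_rev$seed_voxels, target_mask$voxels))
    stop("reverse map is not seeded in 'target_mask'")
  sr <- bidirectional_average(
    seed_ratio_oneway(map_fwd, params, survivors_only),
    seed_ratio_oneway(map_rev, params, survivors_only))
  ts <- bidirectional_average(
    tract_strength_oneway(map_fwd, seed_mask, params),
    tract_strength_oneway(map_rev, target_mask, params))
  data.frame(subject = subject, hemisphere = seed_mask$hemisphere,
             structure = seed_mask$label, area = target_mask$label,
             seed_ratio = sr, tract_strength = ts,
             n_samples = params$n_samples, min_samples = params$min_samples)
}

#' Tract metrics for a whole phantom cohort
#'
#' Runs [compute_tract_metrics()] over every (subject, hemisphere,
#' structure, area) tract of a cohort.
#'
#' @param cohort a [generate_cohort()] or [read_phantom_cohort()] result.
#' @param params a [tractometry_params()], or `NULL` for the study threshold
#'   of 50 with the cohort's own `n_samples`.
#' @param survivors_only passed to [seed_ratio_oneway()].
#' @return long data.frame, one row per tract (subjects x 2 hemispheres x 2
#'   structures x 17 areas).
#' @export
cohort_tract_metrics <- function(cohort, params = NULL,
                                 survivors_only = TRUE) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  out <- vector("list", 0L)
  for (s in seq_along(cohort$counts)) for (h in c("L", "R"))
    for (st in subcortical_structures())
      for (ar in names(cohort$counts[[s]][[h]][[st]])) {
        pair <- cohort$counts[[s]][[h]][[st]][[ar]]
        out[[length(out) + 1L]] <- compute_tract_metrics(
          cohort$masks[[h]][[st]], cohort$masks[[h]][[ar]],
          pair$fwd, pair$rev, params, subject = s,
          survivors_only = survivors_only)
      }
  do.call(rbind, out)
}
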