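#' Extract an ROI's mean time series from a 4-D volume
#'
#' Per-timepoint arithmetic mean of the BOLD signal over the mask's
#' occupied voxels. No detrending, filtering or nuisance regression is
#' applied: the input is assumed already preprocessed (or synthetic).
#'
#' @param series_4d 4-D array on the mask's grid, time as the last axis.
#' @param mask an [roi_mask()].
#' @return an [roi_timeseries()] carrying the mask's label and hemisphere.
#' @export
extract_mean_timeseries <- function(series_4d, mask) {
  stopifnot(inherits(mask, "roi_mask"))
  d <- dim(series_4d)
  if (is.null(d) || length(d) != 4L)
    stop("'series_4d' must be a 4-D array with time as the last axis")
  if (!identical(as.integer(d[1:3]), mask$grid$dims))
    stop("4-D volume and mask are on different grids")
  if (d[4] < 2L) stop("need at least 2 timepoints")
  nv <- prod(d[1:3])
  m <- matrix(series_4d, nrow = nv, ncol = d[4])
  roi_timeseries(colMeans(m[mask$voxels + 1L, , drop = FALSE]),
                 mask$label, mask$hemisphere)
}

#' Pearson correlation of two ROI time series
#'
#' Standard product-moment coefficient. A constant series has no defined
#' correlation and raises an error rather than returning `NA`.
#'
#' @param a,b [roi_timeseries()] objects (or bare numeric vectors) of equal
#'   length T >= 3.
#' @return correlation coefficient in `[-1, 1]`.
#' @export
pearson_correlation <- function(a, b) {
  x <- if (inherits(a, "roi_timeseries")) a$samples else as.numeric(a)
  y <- if (inherits(b, "roi_timeseries")) b$samples else as.numeric(b)
  if (length(x) != length(y)) stop("series lengths differ")
  if (length(x) < 3L) stop("need at least 3 timepoints")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation is undefined for a constant series")
  stats::cor(x, y)
}

#' Functional connectivity fingerprint of a cohort
#'
#' For every subject and hemisphere, correlates each subcortical structure's
#' mean series with each of the 17 cortical areas' series: 34 records per
#' subject per hemisphere.
#'
#' @param cohort a [generate_cohort()] or [read_phantom_cohort()] result
#'   (uses the `bold` matrices, columns named by ROI label).
#' @return long data.frame: subject, hemisphere, structure, area, r.
#' @export
functional_fingerprint <- function(cohort) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  areas <- cortical_areas()
  out <- vector("list", 0L)
  for (s in seq_along(cohort$bold)) for (h in names(cohort$bold[[s]])) {
    m <- cohort$bold[[s]][[h]]
    missing <- setdiff(c(subcortical_structures(), areas), colnames(m))
    if (length(missing))
      stop("subject ", s, " hemisphere ", h, " is missing ROI series: ",
           paste(missing, collapse = ", "))
    for (st in subcortical_structures())
      out[[length(out) + 1L]] <- data.frame(
        subject = s, hemisphere = h, structure = st, area = areas,
        r = apply(m[, areas, drop = FALSE], 2, function(col)
          pearson_correlation(m[, st], col)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
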