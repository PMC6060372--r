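#' Interquartile-range outlier screen
#'
#' Flags values lying strictly outside the fences
#' `[Q1 - k*IQR, Q3 + k*IQR]`, with quartiles by linear interpolation
#' (type-7) and the study multiplier `k = 3`. A zero IQR (near-constant
#' vector) flags nothing.
#'
#' @param values numeric vector, at least 4 values.
#' @param k fence multiplier; study value 3.
#' @return an object of class `outlier_report`: list with `flagged`
#'   (indices into `values`), `lower`, `upper`, `k`.
#' @export
iqr_outliers <- function(values, k = 3) {
  values <- as.numeric(values)
  if (length(values) < 4L) stop("need at least 4 values for quartile fences")
  if (any(!is.finite(values))) stop("values must be finite")
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  lower <- q[1] - k * iqr
  upper <- q[2] + k * iqr
  flagged <- if (iqr == 0) integer(0) else which(values < lower | values > upper)
  structure(list(flagged = flagged, lower = lower, upper = upper, k = k),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("<outlier_report> %d flagged; fences [%.4g, %.4g] (k=%g)\n",
              length(x$flagged), x$lower, x$upper, x$k))
  invisible(x)
}

#' Screen a fingerprint table for outliers, per tract
#'
#' Applies [iqr_outliers()] separately to each (structure, area) vector of
#' hemisphere-specific values across subjects — the per-tract screen of the
#' study design. Flagged rows are removed listwise from that tract only.
#'
#' @param table long data.frame with columns subject, hemisphere, structure,
#'   area and the metric column `value_col`.
#' @param value_col name of the metric column.
#' @param k fence multiplier.
#' @return list with `clean` (the table minus flagged rows) and `outliers`
#'   (data.frame of removed rows with the fences that removed them).
#' @export
screen_outliers <- function(table, value_col, k = 3) {
  stopifnot(value_col %in% names(table))
  drop <- logical(nrow(table))
  removed <- vector("list", 0L)
  for (st in unique(table$structure)) for (ar in unique(table$area)) {
    idx <- which(table$structure == st & table$area == ar)
    if (length(idx) < 4L) next
    rep <- iqr_outliers(table[[value_col]][idx], k = k)
    if (length(rep$flagged)) {
      bad <- idx[rep$flagged]
      drop[bad] <- TRUE
      removed[[length(removed) + 1L]] <- cbind(
        table[bad, c("subject", "hemisphere", "structure", "area")],
        value = table[[value_col]][bad], lower = rep$lower, upper = rep$upper)
    }
  }
  outliers <- if (length(removed)) do.call(rbind, removed) else
    data.frame(subject = integer(0), hemisphere = character(0),
               structure = character(0), area = character(0),
               value = numeric(0), lower = numeric(0), upper = numeric(0))
  rownames(outliers) <- NULL
  list(clean = table[!drop, , drop = FALSE], outliers = outliers)
}
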