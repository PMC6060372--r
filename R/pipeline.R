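#' Assemble the long fingerprint table
#'
#' Stacks the tract metrics and the functional correlations into one
#' long-format table with a `metric` column taking values `seed_ratio`,
#' `tract_strength` and `rs_corr` — one value per (subject, hemisphere,
#' structure, area, metric).
#'
#' @param tract_metrics output of [cohort_tract_metrics()].
#' @param rs_fingerprint output of [functional_fingerprint()] (optional).
#' @return long data.frame: subject, hemisphere, structure, area, metric,
#'   value.
#' @export
fingerprint_table <- function(tract_metrics, rs_fingerprint = NULL) {
  key <- c("subject", "hemisphere", "structure", "area")
  out <- rbind(
    cbind(tract_metrics[key], metric = "seed_ratio",
          value = tract_metrics$seed_ratio),
    cbind(tract_metrics[key], metric = "tract_strength",
          value = tract_metrics$tract_strength))
  if (!is.null(rs_fingerprint))
    out <- rbind(out, cbind(rs_fingerprint[key], metric = "rs_corr",
                            value = rs_fingerprint$r))
  if (anyDuplicated(out[c(key, "metric")]))
    stop("duplicate (subject, hemisphere, structure, area, metric) records")
  rownames(out) <- NULL
  out
}

#' Summarise a fingerprint metric per structure and area
#'
#' Hemisphere-averaged per-subject values, summarised by mean and sample SD
#' across subjects — the "Mean (SD)" layout of the study's summary tables.
#'
#' @param fingerprint long table from [fingerprint_table()].
#' @param metric one of `"seed_ratio"`, `"tract_strength"`, `"rs_corr"`.
#' @return data.frame: structure, area, mean, sd, n.
#' @export
summarize_table <- function(fingerprint, metric) {
  sel <- fingerprint[fingerprint$metric == metric, ]
  if (nrow(sel) == 0L) stop("no records for metric '", metric, "'")
  avg <- average_hemispheres(sel, "value")
  agg <- stats::aggregate(avg$value,
                          by = list(structure = avg$structure, area = avg$area),
                          FUN = function(v) c(mean(v), stats::sd(v), length(v)))
  data.frame(structure = agg$structure, area = agg$area,
             mean = agg$x[, 1], sd = agg$x[, 2], n = as.integer(agg$x[, 3]))
}

# fixed 6-decimal formatting for diff-stable outputs; values too large for
# fixed notation (giant Bayes factors) switch to scientific, deterministically
format_csv_cols <- function(df, digits = 6) {
  for (nm in names(df))
    if (is.numeric(df[[nm]]) && !is.integer(df[[nm]])) {
      x <- df[[nm]]
      out <- formatC(x, digits = digits, format = "f")
      big <- is.finite(x) & abs(x) >= 1e6
      out[big] <- formatC(x[big], digits = digits, format = "e")
      df[[nm]] <- trimws(out)
    }
  df
}

write_pipeline_csv <- function(df, path, digits = 6) {
  utils::write.csv(format_csv_cols(df, digits), path, row.names = FALSE,
                   quote = FALSE)
}

#' Run the full fingerprint pipeline
#'
#' Orchestrates simulate (or load) -> tractometry -> rs-fMRI fingerprint ->
#' outlier screen -> Bayesian statistics, and writes the study-style output
#' tables plus a run manifest to `out_dir`. Deterministic: rerunning with
#' the same `seed` yields byte-identical CSVs.
#'
#' @param spec a [ground_truth_spec()] (simulate mode). Ignored when
#'   `input_dir` is given.
#' @param input_dir optional directory written by [write_phantom_cohort()]
#'   (analyze mode).
#' @param out_dir output directory, created if needed.
#' @param seed global seed; overrides the seeds in `spec` and `prior` so a
#'   single integer pins the whole run.
#' @param params a [tractometry_params()] or `NULL` (threshold 50, the
#'   cohort's `n_samples`).
#' @param prior a [bayes_prior_spec()].
#' @param iqr_k outlier fence multiplier; study value 3.
#' @param survivors_only seed-ratio averaging mode (see
#'   [seed_ratio_oneway()]).
#' @param run_anova compute the mixed-model interaction Bayes factor per
#'   metric (the slowest stage); default `TRUE`.
#' @param pairwise_metrics metrics for which the 17 x 17 within-structure
#'   pairwise matrices are written.
#' @return invisibly, a list with every table and the manifest.
#' @export
run_pipeline <- function(spec = ground_truth_spec(), input_dir = NULL,
                         out_dir, seed = NULL, params = NULL,
                         prior = bayes_prior_spec(), iqr_k = 3,
                         survivors_only = TRUE, run_anova = TRUE,
                         pairwise_metrics = c("tract_strength", "rs_corr")) {
  t0 <- Sys.time()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    spec <- utils::modifyList(spec, list(rng_seed = seed))
    class(spec) <- "ground_truth_spec"
    prior$rng_seed <- substream_seed(seed, 777L)
  }

  cohort <- if (is.null(input_dir)) generate_cohort(spec)
            else read_phantom_cohort(input_dir)
  timings <- c(simulate = as.numeric(Sys.time() - t0, units = "secs"))

  t1 <- Sys.time()
  tract <- cohort_tract_metrics(cohort, params, survivors_only)
  timings["tractometry"] <- as.numeric(Sys.time() - t1, units = "secs")

  t1 <- Sys.time()
  rsfp <- functional_fingerprint(cohort)
  timings["rsfmri"] <- as.numeric(Sys.time() - t1, units = "secs")

  fingerprint <- fingerprint_table(tract, rsfp)

  t1 <- Sys.time()
  metrics <- unique(fingerprint$metric)
  clean_list <- list(); outlier_list <- list()
  for (m in metrics) {
    scr <- screen_outliers(fingerprint[fingerprint$metric == m, ], "value",
                           k = iqr_k)
    clean_list[[m]] <- scr$clean
    if (nrow(scr$outliers)) outlier_list[[m]] <- cbind(metric = m, scr$outliers)
  }
  outliers <- if (length(outlier_list)) do.call(rbind, outlier_list) else
    data.frame(metric = character(0), subject = integer(0),
               hemisphere = character(0), structure = character(0),
               area = character(0), value = numeric(0), lower = numeric(0),
               upper = numeric(0))
  rownames(outliers) <- NULL

  summaries <- do.call(rbind, lapply(metrics, function(m)
    cbind(metric = m, summarize_table(fingerprint, m))))

  bf_structure <- do.call(rbind, lapply(metrics, function(m)
    cbind(metric = m, structure_contrast_bf(clean_list[[m]], "value", prior))))

  anova_rows <- list()
  if (run_anova) for (m in metrics) {
    bf <- jzs_mixed_anova_bf(clean_list[[m]], "value", prior,
                             allow_incomplete = TRUE)
    anova_rows[[m]] <- data.frame(metric = m, bf10 = bf$bf10,
                                  log_bf10 = bf$log_bf10, display = bf$display,
                                  category = bf$category, mc_error = bf$mc_error)
  }
  bf_anova <- if (length(anova_rows)) do.call(rbind, anova_rows) else NULL

  pairwise <- list()
  for (m in intersect(pairwise_metrics, metrics))
    for (st in subcortical_structures())
      pairwise[[paste(st, m, sep = "_")]] <-
        pairwise_bf_matrix(clean_list[[m]], "value", st, prior)
  timings["stats"] <- as.numeric(Sys.time() - t1, units = "secs")

  write_pipeline_csv(tract, file.path(out_dir, "tract_metrics.csv"))
  write_pipeline_csv(rsfp, file.path(out_dir, "rsfmri_fingerprint.csv"))
  write_pipeline_csv(summaries, file.path(out_dir, "summary.csv"))
  write_pipeline_csv(bf_structure, file.path(out_dir, "bf_vs_structure.csv"))
  if (!is.null(bf_anova))
    write_pipeline_csv(bf_anova, file.path(out_dir, "bf_anova.csv"))
  write_pipeline_csv(outliers, file.path(out_dir, "outliers.csv"))
  for (nm in names(pairwise)) {
    df <- cbind(area = rownames(pairwise[[nm]]),
                as.data.frame(pairwise[[nm]]))
    write_pipeline_csv(df, file.path(out_dir,
                                     sprintf("bf_pairwise_%s.csv", nm)))
  }

  manifest <- list(
    package = "subcortfp",
    version = as.character(utils::packageVersion("subcortfp")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = if (is.null(seed)) spec$rng_seed else seed,
    mode = if (is.null(input_dir)) "simulate" else "analyze",
    n_subjects = length(cohort$counts),
    iqr_k = iqr_k,
    survivors_only = survivors_only,
    prior = prior[c("t_rscale", "fixed_rscale", "random_rscale",
                    "mc_iterations", "rng_seed")],
    n_outliers_removed = nrow(outliers),
    outliers = if (nrow(outliers)) outliers[c("metric", "subject",
                                              "hemisphere", "structure",
                                              "area")] else list(),
    timings_sec = as.list(round(timings, 3)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(fingerprint = fingerprint, tract_metrics = tract,
                 rs_fingerprint = rsfp, summaries = summaries,
                 bf_vs_structure = bf_structure, bf_anova = bf_anova,
                 pairwise = pairwise, outliers = outliers,
                 manifest = manifest))
}
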