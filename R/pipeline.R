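#' Run the end-to-end multi-site comparison pipeline
#'
#' Executes simulate (optional) -> preprocess -> decompose -> indices ->
#' quality -> statistics and writes the tidy result tables plus a run
#' manifest to `out_dir`. In `simulate` mode a cohort is generated from
#' `scfg`; in `analyze` mode recordings are read from `recording_paths`
#' (CSV, see [read_recording()]) with a shared annotation file.
#'
#' The summary table ranks sites along the three comparison axes: mean raw
#' correlation with the reference site, number of significant
#' baseline-vs-stress indices, and median walking-stage noise-band power
#' fraction.
#'
#' @param out_dir Output directory (created if missing).
#' @param mode `"simulate"` or `"analyze"`.
#' @param scfg Simulation configuration (simulate mode).
#' @param pcfg,dcfg Pipeline and decomposition configurations.
#' @param recording_paths Character vector of recording CSV paths (analyze
#'   mode).
#' @param annotations_path Annotation CSV path (analyze mode); in simulate
#'   mode annotations derive from the stage plan.
#' @param fs Acquisition sampling rate of the recordings (analyze mode).
#' @param site_columns Site columns to read (analyze mode).
#' @param write_recordings Also write the simulated recordings as CSV
#'   (simulate mode; large files).
#' @return The run manifest (list), invisibly written to
#'   `out_dir/manifest.json`: config snapshot, inputs, output paths.
#' @export
run_pipeline <- function(out_dir, mode = c("simulate", "analyze"),
                         scfg = simulation_config(),
                         pcfg = pipeline_config(),
                         dcfg = decomposition_config(),
                         recording_paths = NULL, annotations_path = NULL,
                         fs = 100, site_columns = NULL,
                         write_recordings = FALSE) {
  mode <- match.arg(mode)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (mode == "simulate") {
    cohort <- simulate_cohort(scfg)
    ann <- annotations_from_plan(scfg$stage_plan)
    inputs <- list(seed = scfg$seed, n_subjects = scfg$n_subjects)
    if (write_recordings) {
      rec_dir <- file.path(out_dir, "recordings")
      dir.create(rec_dir, showWarnings = FALSE)
      for (el in cohort)
        write_recording(el$recording,
                        file.path(rec_dir, paste0(el$recording$subject_id, ".csv")))
      inputs$recordings_dir <- rec_dir
    }
  } else {
    if (is.null(recording_paths) || is.null(annotations_path))
      stop("analyze mode requires recording_paths and annotations_path",
           call. = FALSE)
    if (is.null(site_columns))
      stop("analyze mode requires site_columns", call. = FALSE)
    missing_files <- recording_paths[!file.exists(recording_paths)]
    if (length(missing_files) > 0)
      stop("recording file(s) not found: ",
           paste(missing_files, collapse = ", "), call. = FALSE)
    if (!file.exists(annotations_path))
      stop("annotation file not found: ", annotations_path, call. = FALSE)
    cohort <- lapply(seq_along(recording_paths), function(i) {
      read_recording(recording_paths[i], fs = fs, site_columns = site_columns,
                     subject_id = sprintf("s%02d", i), allow_negative = TRUE)
    })
    ann <- read_annotations(annotations_path)
    inputs <- list(recordings = recording_paths,
                   annotations = annotations_path)
  }

  report <- cohort_report(cohort, ann, pcfg, dcfg)

  paths <- list(
    correlations = file.path(out_dir, "correlations.csv"),
    correlation_summary = file.path(out_dir, "correlation_summary.csv"),
    indices = file.path(out_dir, "indices.csv"),
    tests = file.path(out_dir, "tests.csv"),
    roc_auc = file.path(out_dir, "roc_auc.csv"),
    quality = file.path(out_dir, "quality.csv"),
    quality_summary = file.path(out_dir, "quality_summary.csv"),
    site_ranking = file.path(out_dir, "site_ranking.csv")
  )
  utils::write.csv(report$correlations, paths$correlations, row.names = FALSE)
  utils::write.csv(report$correlation_summary, paths$correlation_summary,
                   row.names = FALSE)
  utils::write.csv(indices_long(report$indices), paths$indices,
                   row.names = FALSE)
  utils::write.csv(report$tests, paths$tests, row.names = FALSE)
  utils::write.csv(report$roc, paths$roc_auc, row.names = FALSE)
  utils::write.csv(report$quality, paths$quality, row.names = FALSE)
  utils::write.csv(report$quality_summary, paths$quality_summary,
                   row.names = FALSE)
  utils::write.csv(site_ranking(report, pcfg), paths$site_ranking,
                   row.names = FALSE)

  manifest <- list(version = as.character(utils::packageVersion("edasite")),
                   mode = mode,
                   timestamp = format(Sys.time(), tz = "UTC"),
                   config = list(pipeline = unclass(pcfg),
                                 decomposition = unclass(dcfg),
                                 simulation = if (mode == "simulate") {
                                   s <- unclass(scfg)
                                   s$site_profiles <- lapply(s$site_profiles, unclass)
                                   s$stage_plan <- NULL
                                   s
                                 }),
                   inputs = inputs,
                   outputs = unlist(paths, use.names = TRUE))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  missing_out <- paths[!vapply(paths, file.exists, logical(1))]
  if (length(missing_out) > 0)
    stop("pipeline failed to write: ",
         paste(unlist(missing_out), collapse = ", "), call. = FALSE)
  invisible(manifest)
}

#' Rank sites along the three comparison axes
#'
#' @param report An `eda_site_report`.
#' @param pcfg The pipeline configuration (names the reference site).
#' @return A data.frame: per non-reference site, mean raw correlation with
#'   the reference, number of significant indices, and median walking-stage
#'   noise-band power fraction (when the walking stage was analysed).
#' @export
site_ranking <- function(report, pcfg = pipeline_config()) {
  cs <- report$correlation_summary
  raw <- cs[cs$component == "raw", c("site", "mean_r")]
  sig <- significant_index_counts(report)
  qs <- report$quality_summary
  walk <- qs[qs$stage == "walking", c("site", "median_pn_raw")]
  out <- raw
  out$n_significant <- as.integer(sig[out$site])
  out$walking_pn <- if (nrow(walk) > 0) {
    walk$median_pn_raw[match(out$site, walk$site)]
  } else NA_real_
  out <- out[order(-out$mean_r), ]
  rownames(out) <- NULL
  out
}
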