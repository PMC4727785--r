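#' Run the full simulate - preprocess - score - correlate pipeline
#'
#' Generates a synthetic cohort, simulates raw paired-click EEG and
#' behavioural trial logs per subject, runs the preprocessing chain and the
#' P50 gating scorer, computes the task indices, joins everything into a
#' score table and runs the correlation battery. Per-subject failures and
#' exclusions (no identifiable S1 P50) are logged and skipped, never abort
#' the cohort. All stage outputs plus a manifest (seed, configuration,
#' exclusions) are written to `out_dir` as CSV/JSON when it is non-`NULL`.
#'
#' @param spec a [cohort_spec()].
#' @param out_dir output directory, or `NULL` to skip writing.
#' @param config pipeline configuration, see [default_config()].
#' @param n_paired_trials,n_click_trials,iti,rate forwarded to
#'   [generate_raw_eeg()].
#' @param write_eeg also write each raw recording in BrainVision format
#'   (off by default; recordings are large).
#' @return List with `gating` (per-subject gating table), `scores` (score
#'   matrix incl. gating ratio and covariates), `report` (a
#'   `correlation_report`), `paired_t_s1_s2` (group gating effect test) and
#'   `manifest`.
#' @export
run_pipeline <- function(spec = cohort_spec(), out_dir = NULL,
                         config = default_config(),
                         n_paired_trials = 135, n_click_trials = 15,
                         iti = 1, rate = 2000, write_eeg = FALSE) {
  cohort <- generate_cohort(spec)
  n <- length(cohort$profiles)

  gating_results <- list()
  score_rows <- list()
  exclusions <- list()
  for (i in seq_len(n)) {
    prof <- cohort$profiles[[i]]
    id <- prof$subject_id
    sub_seed <- spec$seed + 1000L + i
    res <- tryCatch({
      rec <- generate_raw_eeg(prof, n_paired_trials = n_paired_trials,
                              n_click_trials = n_click_trials,
                              rate = rate, iti = iti, snr = spec$snr,
                              seed = sub_seed, config = config)
      if (isTRUE(write_eeg) && !is.null(out_dir)) {
        dir.create(file.path(out_dir, "eeg"), recursive = TRUE,
                   showWarnings = FALSE)
        write_brainvision(rec, file.path(out_dir, "eeg", id))
      }
      ev <- preprocess_recording(rec, config = config)
      score_gating(ev$S1, ev$S2, config = config)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      exclusions[[id]] <- paste("processing failed:", conditionMessage(res))
      next
    }
    if (res$excluded)
      exclusions[[id]] <- "no identifiable S1 P50"
    gating_results[[id]] <- res

    logs <- lapply(setdiff(task_names(), "ospan"), function(task)
      generate_trial_log(prof, task, seed = sub_seed + 17L))
    names(logs) <- setdiff(task_names(), "ospan")
    items <- generate_ospan_items(prof, seed = sub_seed + 31L)
    score_rows[[id]] <- score_task_battery(logs, ospan_items = items,
                                           iq_raw = prof$iq_raw,
                                           config = config)
  }

  gating <- gating_table(gating_results)
  task_scores <- do.call(rbind, score_rows)
  scores <- merge(gating[!gating$excluded, c("subject_id", "ratio")],
                  task_scores, by = "subject_id")
  names(scores)[names(scores) == "ratio"] <- "gating_ratio"

  if (nrow(scores) < 4)
    stop("no usable subjects: ", nrow(scores),
         " non-excluded subject(s) is too few for the battery")

  report <- correlation_battery(scores, config = config)
  usable <- gating[!gating$excluded, ]
  s1s2 <- paired_t(usable$s1_amp, usable$s2_amp)

  manifest <- list(
    package_version = as.character(utils::packageVersion("p50gate")),
    seed = spec$seed,
    n_subjects = n,
    n_excluded = length(exclusions),
    exclusions = exclusions,
    snr = spec$snr,
    n_paired_trials = n_paired_trials,
    rate = rate,
    iti = iti,
    config = config)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(gating, file.path(out_dir, "gating.csv"),
                     row.names = FALSE)
    utils::write.csv(task_scores, file.path(out_dir, "task_scores.csv"),
                     row.names = FALSE)
    utils::write.csv(scores, file.path(out_dir, "score_matrix.csv"),
                     row.names = FALSE)
    utils::write.csv(report$bivariate,
                     file.path(out_dir, "bivariate_correlations.csv"),
                     row.names = FALSE)
    if (!is.null(report$partial))
      utils::write.csv(report$partial,
                       file.path(out_dir, "partial_correlations.csv"),
                       row.names = FALSE)
    jsonlite::write_json(
      list(bivariate = report$bivariate, partial = report$partial,
           williams = report$williams,
           paired_t_s1_s2 = s1s2),
      file.path(out_dir, "correlation_report.json"),
      auto_unbox = TRUE, digits = NA, null = "null")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }

  list(gating = gating, scores = scores, report = report,
       paired_t_s1_s2 = s1s2, manifest = manifest, cohort = cohort)
}
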