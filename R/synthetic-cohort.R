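#' Measures simulated for each subject
#'
#' The gating ratio, the behavioural inhibition indices, continuous
#' performance accuracy and speed, and the two psychometric covariates.
#' This fixed ordering defines rows/columns of the target correlation
#' matrix.
#'
#' @return Character vector of measure names.
#' @export
measure_names <- function() {
  c("gating_ratio", "stroop", "simon", "flanker", "alerting", "orienting",
    "latent_inhibition", "novel_popout", "negative_priming",
    "gonogo_errors", "switch_cost", "antisaccade",
    "cpt_accuracy", "cpt_rt", "iq", "ospan")
}

#' Default marginal means and SDs per measure
#'
#' Group means, and between-subject SDs recovered from the group means and
#' paired t statistics (SD = mean * sqrt(n) / t), of the published
#' descriptive table for each index; covariate moments are taken directly.
#' RT indices are in ms, counts in events, accuracy as a proportion.
#'
#' @return Data frame with columns `measure`, `mean`, `sd`.
#' @export
default_margins <- function() {
  data.frame(
    measure = measure_names(),
    mean = c(73, 75, 28, 92.35, 50, 73, 257, 80, 84,
             1.8, 59, 867, 0.97, 523, 35.12, 39.06),
    sd = c(35, 98.7, 42.2, 65.38, 38.6, 73.5, 313.3, 160, 107.3,
           2.16, 66.0, 1334.7, 0.06, 14, 5.80, 18.66),
    stringsAsFactors = FALSE)
}

#' Default target correlation matrix
#'
#' The gating-ratio column reproduces the published bivariate correlations
#' between the gating ratio and each task index / covariate. Task-covariate
#' entries for latent inhibition, novel pop-out, attentional orienting and
#' CPT accuracy are solved from the published partial correlations (the
#' value of r(task, covariate) that maps the bivariate r to the reported
#' partial r given r(gating, covariate)). Remaining cross-measure entries
#' are weak within-family couplings chosen so the matrix is positive
#' definite; they are simulation defaults, not published values.
#'
#' @return A 16 x 16 symmetric positive-definite correlation matrix.
#' @export
default_target_correlations <- function() {
  m <- measure_names()
  R <- diag(length(m))
  dimnames(R) <- list(m, m)
  set_r <- function(a, b, v) {
    R[a, b] <<- v
    R[b, a] <<- v
  }
  gate <- c(stroop = .06, simon = .07, flanker = .04, alerting = .03,
            orienting = -.38, latent_inhibition = -.63,
            novel_popout = -.47, negative_priming = .18,
            gonogo_errors = -.16, switch_cost = .16, antisaccade = -.15,
            cpt_accuracy = -.38, cpt_rt = 0, iq = -.42, ospan = -.23)
  for (nm in names(gate)) set_r("gating_ratio", nm, gate[[nm]])
  # implied by the published partial-correlation table
  set_r("latent_inhibition", "iq", .18)
  set_r("novel_popout", "iq", .09)
  set_r("orienting", "iq", .09)
  set_r("cpt_accuracy", "iq", -.29)
  set_r("latent_inhibition", "ospan", .08)
  set_r("novel_popout", "ospan", .32)
  set_r("orienting", "ospan", -.11)
  set_r("cpt_accuracy", "ospan", -.47)
  set_r("iq", "ospan", .35)
  # invented weak within-family couplings (keep the matrix positive definite)
  set_r("stroop", "simon", .20)
  set_r("stroop", "flanker", .20)
  set_r("simon", "flanker", .20)
  set_r("latent_inhibition", "novel_popout", .35)
  set_r("latent_inhibition", "orienting", .25)
  set_r("novel_popout", "orienting", .20)
  set_r("latent_inhibition", "cpt_accuracy", .25)
  set_r("novel_popout", "cpt_accuracy", .15)
  set_r("orienting", "cpt_accuracy", .15)
  set_r("gonogo_errors", "switch_cost", .20)
  set_r("cpt_rt", "cpt_accuracy", -.20)
  R
}

#' Specify a synthetic cohort
#'
#' @param n_subjects number of subjects (at least 4, the minimum usable by
#'   the downstream partial correlations).
#' @param target_correlations symmetric positive semi-definite correlation
#'   matrix over the measures in [measure_names()] (any subset, named).
#' @param margins data frame with columns `measure`, `mean`, `sd` giving the
#'   marginal moments; defaults to [default_margins()].
#' @param snr ratio of the S1 P50 peak-to-trough amplitude to the SD of the
#'   broadband background noise in the simulated raw EEG.
#' @param empirical if `TRUE`, plant the target correlation matrix exactly
#'   (the latent draws are rescaled so their sample correlation equals the
#'   target; requires `n_subjects` greater than the number of measures).
#'   The default `FALSE` samples randomly, so the empirical correlations
#'   converge to the target as the cohort grows.
#' @param seed integer seed; the same spec and seed give identical cohorts.
#' @return A `cohort_spec` list, validated.
#' @export
cohort_spec <- function(n_subjects = 60,
                        target_correlations = default_target_correlations(),
                        margins = default_margins(),
                        snr = 0.75,
                        empirical = FALSE,
                        seed = 1L) {
  if (n_subjects < 4)
    stop("n_subjects must be at least 4")
  if (empirical && n_subjects <= nrow(as.matrix(target_correlations)))
    stop("empirical planting requires n_subjects > number of measures")
  R <- as.matrix(target_correlations)
  if (!isTRUE(all.equal(R, t(R), tolerance = 1e-8)))
    stop("target_correlations must be symmetric")
  if (any(abs(diag(R) - 1) > 1e-8))
    stop("target_correlations must have unit diagonal")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("target_correlations is not positive semi-definite ",
         "(min eigenvalue ", format(min(ev)), "); a valid correlation ",
         "matrix over the planted measures is required")
  if (is.null(rownames(R)))
    stop("target_correlations must carry measure names")
  unknown <- setdiff(rownames(R), measure_names())
  if (length(unknown))
    stop("unknown measure(s): ", paste(unknown, collapse = ", "))
  structure(list(n_subjects = as.integer(n_subjects),
                 target_correlations = R,
                 margins = margins,
                 snr = snr,
                 empirical = isTRUE(empirical),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a cohort of subject profiles with planted correlations
#'
#' Draws a latent multivariate normal vector per subject with the target
#' correlation matrix (Gaussian copula with normal margins: a location-scale
#' transform to the stated means and SDs preserves the correlations
#' exactly), then derives each subject's ground-truth profile: S1/S2 P50
#' amplitudes consistent with the planted gating ratio, component latencies,
#' planted task effects, and integer psychometric scores. The continuous
#' planted measures are kept in a `measures` table on the latent
#' (untruncated) scale; derived quantities used for waveform or trial
#' simulation are clipped to their physical ranges.
#'
#' @param spec a [cohort_spec()].
#' @return A `cohort`: list with `profiles` (list of `subject_profile`),
#'   `measures` (data frame of planted per-subject measure values),
#'   `target` (the correlation matrix actually planted), and `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  R <- spec$target_correlations
  vars <- rownames(R)
  n <- spec$n_subjects
  Z <- MASS::mvrnorm(n, mu = rep(0, length(vars)), Sigma = R,
                     empirical = spec$empirical)
  if (n == 1) Z <- matrix(Z, nrow = 1)
  colnames(Z) <- vars

  mg <- spec$margins
  measures <- as.data.frame(Z)
  for (v in vars) {
    row <- mg[mg$measure == v, ]
    if (nrow(row) != 1) stop("no margin stated for measure: ", v)
    measures[[v]] <- row$mean + row$sd * Z[, v]
  }
  measures <- cbind(subject_id = sprintf("S%03d", seq_len(n)), measures,
                    stringsAsFactors = FALSE)

  amp_row <- mg[mg$measure == "gating_ratio", ]
  profiles <- vector("list", n)
  for (i in seq_len(n)) {
    gv <- function(v, default = NA_real_)
      if (v %in% vars) measures[[v]][i] else default
    ratio <- gv("gating_ratio", 73)
    ratio_clipped <- min(200, max(2, ratio))
    s1 <- max(0.3, stats::rnorm(1, 1.33, 0.99))
    s2 <- ratio_clipped / 100 * s1
    n40 <- -max(0.1, stats::rnorm(1, 0.35 * s1, 0.1))
    p50_lat <- min(78, max(45, stats::rnorm(1, 55, 5)))
    n40_lat <- min(48, p50_lat - 8, max(25, stats::rnorm(1, 38, 3)))
    effects <- list(
      stroop = gv("stroop", 75),
      simon = gv("simon", 28),
      flanker = gv("flanker", 92.35),
      alerting = gv("alerting", 50),
      orienting = gv("orienting", 73),
      latent_inhibition = gv("latent_inhibition", 257),
      novel_popout = gv("novel_popout", 80),
      negative_priming = gv("negative_priming", 84),
      gonogo_errors = max(0, min(12, gv("gonogo_errors", 1.8))),
      switch_cost = gv("switch_cost", 59),
      antisaccade = gv("antisaccade", 867),
      cpt_accuracy = max(0, min(1, gv("cpt_accuracy", 0.97))),
      cpt_rt = max(150, gv("cpt_rt", 523)))
    profiles[[i]] <- subject_profile(
      subject_id = measures$subject_id[i],
      s1_p50_amp = s1,
      s2_p50_amp = s2,
      n40_amp = n40,
      p50_latency = p50_lat,
      n40_latency = n40_lat,
      task_effects = effects,
      iq_raw = as.integer(max(0, min(46, round(gv("iq", 35.12))))),
      ospan_abs = as.integer(max(0, min(75, round(gv("ospan", 39.06))))),
      gating_ratio = ratio_clipped)
  }
  structure(list(profiles = profiles, measures = measures,
                 target = R, spec = spec),
            class = "cohort")
}

#' Ground-truth profile of one simulated subject
#'
#' @param subject_id identifier string.
#' @param s1_p50_amp,s2_p50_amp planted peak-to-trough P50 amplitudes
#'   (microvolts) for the conditioning and testing stimulus; S1 must be
#'   positive, S2 non-negative.
#' @param n40_amp planted N40 trough value (microvolts, negative).
#' @param p50_latency,n40_latency planted component latencies in ms; N40
#'   must precede P50, within the scoring windows.
#' @param task_effects named list of planted true task effects.
#' @param iq_raw raw fluid-intelligence score, 0--46 (scale maximum 46).
#' @param ospan_abs absolute operation-span score, non-negative.
#' @param gating_ratio planted S2/S1 ratio in percent.
#' @return A `subject_profile`.
#' @export
subject_profile <- function(subject_id, s1_p50_amp, s2_p50_amp, n40_amp,
                            p50_latency, n40_latency, task_effects,
                            iq_raw, ospan_abs,
                            gating_ratio = 100 * s2_p50_amp / s1_p50_amp) {
  stopifnot(s1_p50_amp > 0, s2_p50_amp >= 0,
            n40_latency >= 20, n40_latency <= 50,
            p50_latency >= 40, p50_latency <= 80,
            n40_latency < p50_latency,
            iq_raw >= 0, iq_raw <= 46, ospan_abs >= 0)
  structure(list(subject_id = subject_id,
                 s1_p50_amp = s1_p50_amp, s2_p50_amp = s2_p50_amp,
                 n40_amp = n40_amp,
                 p50_latency = p50_latency, n40_latency = n40_latency,
                 task_effects = task_effects,
                 iq_raw = iq_raw, ospan_abs = ospan_abs,
                 gating_ratio = gating_ratio),
            class = "subject_profile")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects, %d planted measures, seed %d\n",
              length(x$profiles), ncol(x$target), x$spec$seed))
  invisible(x)
}
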