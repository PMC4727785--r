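#' Mean-RT difference index between two conditions
#'
#' The workhorse for the congruency-type indices: mean correct-trial RT in
#' condition `cond_a` minus mean correct-trial RT in condition `cond_b`
#' (e.g. incongruent minus congruent). Incorrect and withheld trials are
#' excluded; only reaction times from trials with correct responses enter.
#'
#' @param log a trial-log data frame (see [generate_trial_log()]).
#' @param cond_a,cond_b condition labels; the index is `mean(a) - mean(b)`.
#' @return Difference in ms, or `NA` if either condition has no correct
#'   responded trial (a missing value, not zero).
#' @export
score_difference_index <- function(log, cond_a, cond_b) {
  mean_rt <- function(cond) {
    sel <- log$condition == cond & log$correct & !is.na(log$rt)
    if (!any(sel)) return(NA_real_)
    mean(log$rt[sel])
  }
  mean_rt(cond_a) - mean_rt(cond_b)
}

#' Count commission errors on no-go trials
#'
#' @param log a trial-log data frame containing `no_go` trials.
#' @return Number of no-go trials on which a response was made.
#' @export
score_gonogo <- function(log) {
  nogo <- log$condition == "no_go"
  if (!any(nogo)) stop("log contains no no-go trials")
  sum(nogo & !log$correct)
}

#' Score the continuous performance task
#'
#' @param log a trial-log data frame with `target` trials.
#' @return List with `accuracy` (hits / targets; false alarms are not
#'   folded in) and `mean_rt` (ms over correct target responses, `NA` if no
#'   hits).
#' @export
score_cpt <- function(log) {
  targ <- log$condition == "target"
  if (!any(targ)) stop("log contains no target trials")
  hits <- targ & log$correct
  acc <- sum(hits) / sum(targ)
  rt <- if (any(hits & !is.na(log$rt))) mean(log$rt[hits], na.rm = TRUE)
        else NA_real_
  list(accuracy = acc, mean_rt = rt)
}

#' Absolute operation-span score
#'
#' Sum of letter-set sizes over the sets in which every letter was recalled
#' in the correct order; sets with any recall or order error contribute
#' zero.
#'
#' @param items data frame with columns `set_size`, `letters_presented`,
#'   `letters_recalled` (strings in presentation/recall order).
#' @return Integer absolute span score.
#' @export
score_ospan <- function(items) {
  perfect <- items$letters_recalled == items$letters_presented
  as.integer(sum(items$set_size[perfect]))
}

#' Score the three attentional-network indices
#'
#' Condition labels are `cue.flanker` compounds. The executive (flanker)
#' index is incongruent minus congruent across all cue conditions. Two cue
#' conventions are supported: `"paper_text"` scores alerting as no cue
#' minus centre cue and orienting as no cue minus spatial cue; `"fan2002"`
#' scores alerting as no cue minus double cue and orienting as centre cue
#' minus spatial cue.
#'
#' @param log an ANT trial-log data frame.
#' @param convention `"paper_text"` or `"fan2002"`.
#' @return List with `flanker`, `alerting`, `orienting` (ms).
#' @export
score_ant <- function(log, convention = c("paper_text", "fan2002")) {
  convention <- match.arg(convention)
  parts <- strsplit(log$condition, ".", fixed = TRUE)
  cue <- vapply(parts, `[`, "", 1)
  flank <- vapply(parts, `[`, "", 2)
  m <- function(sel) {
    sel <- sel & log$correct & !is.na(log$rt)
    if (!any(sel)) return(NA_real_)
    mean(log$rt[sel])
  }
  flanker <- m(flank == "incongruent") - m(flank == "congruent")
  if (convention == "paper_text") {
    alerting <- m(cue == "no_cue") - m(cue == "center_cue")
    orienting <- m(cue == "no_cue") - m(cue == "spatial_cue")
  } else {
    alerting <- m(cue == "no_cue") - m(cue == "double_cue")
    orienting <- m(cue == "center_cue") - m(cue == "spatial_cue")
  }
  list(flanker = flanker, alerting = alerting, orienting = orienting)
}

#' Score all task indices for one subject
#'
#' Applies the per-task operationalizations to a set of trial logs and
#' returns one row of the score table: nine inhibition indices, CPT
#' accuracy and RT, plus covariates if supplied.
#'
#' @param logs named list of trial-log data frames (names are task names);
#'   tasks may be missing, yielding `NA` indices.
#' @param ospan_items optional operation-span item table for
#'   [score_ospan()].
#' @param iq_raw optional raw fluid-intelligence score (a paper-and-pencil
#'   test; arrives as a score, not a log).
#' @param config pipeline configuration (ANT convention).
#' @return One-row data frame of task scores.
#' @export
score_task_battery <- function(logs, ospan_items = NULL, iq_raw = NA,
                               config = default_config()) {
  g <- function(task) logs[[task]]
  has <- function(task) !is.null(logs[[task]])
  sdi <- function(task, a, b)
    if (has(task)) score_difference_index(g(task), a, b) else NA_real_
  ant <- if (has("ant"))
    score_ant(g("ant"), convention = config$stats$ant_convention)
  else list(flanker = NA_real_, alerting = NA_real_, orienting = NA_real_)
  cpt <- if (has("cpt")) score_cpt(g("cpt"))
         else list(accuracy = NA_real_, mean_rt = NA_real_)
  subject_id <- NA_character_
  for (l in logs) if (!is.null(l) && nrow(l)) {
    subject_id <- l$subject_id[1]
    break
  }
  data.frame(
    subject_id = subject_id,
    stroop = sdi("stroop", "incongruent", "congruent"),
    simon = sdi("simon", "incongruent", "congruent"),
    flanker = ant$flanker,
    alerting = ant$alerting,
    orienting = ant$orienting,
    latent_inhibition = sdi("latent_inhibition", "PE", "NPE"),
    novel_popout = sdi("latent_inhibition", "NPE", "NOV"),
    negative_priming = sdi("negative_priming", "ignored_repetition",
                           "control"),
    gonogo_errors = if (has("gonogo")) score_gonogo(g("gonogo")) else NA,
    switch_cost = sdi("switch", "switch", "repetition"),
    antisaccade = sdi("antisaccade", "anti", "pro"),
    cpt_accuracy = cpt$accuracy,
    cpt_rt = cpt$mean_rt,
    iq = iq_raw,
    ospan = if (!is.null(ospan_items)) score_ospan(ospan_items) else NA,
    stringsAsFactors = FALSE)
}
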