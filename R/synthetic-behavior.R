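#' Ex-Gaussian random reaction times
#'
#' Sum of a normal and an independent exponential component, the standard
#' descriptive model for response-time distributions. Condition effects are
#' planted on the Gaussian location `mu` only.
#'
#' @param n number of draws.
#' @param mu Gaussian location (ms).
#' @param sigma Gaussian SD (ms).
#' @param tau exponential mean (ms).
#' @return Numeric vector of RTs in ms; mean is `mu + tau`.
#' @export
rexgauss <- function(n, mu, sigma, tau) {
  stats::rnorm(n, mu, sigma) + stats::rexp(n, rate = 1 / tau)
}

#' Trial-structure declarations for the simulated tasks
#'
#' For each task: the condition set, trials per condition, the ex-Gaussian
#' noise parameters, the per-condition response accuracy, and the reference
#' condition mean RT (the planted subject effect shifts the other
#' condition(s)). Trial counts follow the acquisition protocols: 30 Stroop
#' trials, 150 Simon trials, 290 ANT trials, 45 test-phase search trials
#' (15 per condition), 75 priming trials, 60 go/no-go trials with an 80/20
#' go/no-go split, 100 switch trials, 180 saccade trials, and 273 CPT
#' trials of which 30% are targets.
#'
#' @return Named list of task design lists.
#' @export
task_designs <- function() {
  list(
    stroop = list(conditions = c("congruent", "incongruent"),
                  counts = c(15, 15), base = 934,
                  sigma = 100, tau = 150, accuracy = 0.95),
    simon = list(conditions = c("congruent", "incongruent"),
                 counts = c(75, 75), base = 458,
                 sigma = 50, tau = 70, accuracy = 0.95),
    ant = list(cues = c("no_cue", "center_cue", "double_cue", "spatial_cue"),
               flankers = c("congruent", "incongruent"),
               n_trials = 290, base = 560,
               sigma = 55, tau = 80, accuracy = 0.95),
    latent_inhibition = list(conditions = c("PE", "NPE", "NOV"),
                             counts = c(15, 15, 15), base = 1074,
                             sigma = 250, tau = 350, accuracy = 0.90),
    negative_priming = list(conditions = c("control", "ignored_repetition",
                                           "neutral"),
                            counts = c(25, 25, 25), base = 500,
                            sigma = 90, tau = 120, accuracy = 0.95),
    gonogo = list(conditions = c("go", "no_go"),
                  counts = c(48, 12), base = 450,
                  sigma = 60, tau = 80, accuracy = 0.98),
    switch = list(conditions = c("repetition", "switch"),
                  counts = c(50, 50), base = 454,
                  sigma = 60, tau = 80, accuracy = 0.95),
    antisaccade = list(conditions = c("pro", "anti"),
                       counts = c(90, 90), base = 871,
                       sigma = 350, tau = 500, accuracy = 0.92),
    cpt = list(conditions = c("target", "nontarget"),
               counts = c(82, 191), base = 523,
               sigma = 50, tau = 60, accuracy = NA),
    ospan = list())
}

#' Names of the simulated tasks
#' @return Character vector of the task enum.
#' @export
task_names <- function() names(task_designs())

#' Simulate a trial log for one subject and task
#'
#' RTs are ex-Gaussian with the condition-wise location shift equal to the
#' subject's planted effect; accuracy is drawn per condition. Correctly
#' withheld no-go / non-target trials carry no RT. Incorrect responded
#' trials keep their RTs (scoring must ignore them).
#'
#' @param profile a [subject_profile()].
#' @param task one of [task_names()] (except `"ospan"`, which has its own
#'   item generator, [generate_ospan_items()]).
#' @param seed integer seed.
#' @return A data frame with columns `subject_id`, `task`, `trial_index`,
#'   `condition`, `rt`, `correct`, `response`.
#' @export
generate_trial_log <- function(profile, task, seed = 1L) {
  stopifnot(inherits(profile, "subject_profile"))
  designs <- task_designs()
  if (!task %in% names(designs))
    stop("unknown task: ", task, " (expected one of ",
         paste(task_names(), collapse = ", "), ")")
  if (task == "ospan")
    stop("use generate_ospan_items() for the operation-span task")
  set.seed(seed)
  d <- designs[[task]]
  eff <- profile$task_effects

  if (task == "ant") {
    cells <- expand.grid(cue = d$cues, flank = d$flankers,
                         stringsAsFactors = FALSE)
    cell_idx <- rep(seq_len(nrow(cells)), length.out = d$n_trials)
    cue <- cells$cue[cell_idx]
    flank <- cells$flank[cell_idx]
    # text-formula generative model: alerting = no cue - centre cue,
    # orienting = no cue - spatial cue
    mu <- d$base -
      eff$alerting * (cue == "center_cue") -
      eff$orienting * (cue == "spatial_cue") -
      (eff$alerting + 5) * (cue == "double_cue") +
      eff$flanker * (flank == "incongruent")
    condition <- paste(cue, flank, sep = ".")
    rt <- rexgauss(length(mu), mu - d$tau, d$sigma, d$tau)
    correct <- stats::runif(length(mu)) < d$accuracy
    log <- data.frame(condition = condition, rt = rt, correct = correct,
                      response = ifelse(correct, "correct", "error"),
                      stringsAsFactors = FALSE)
  } else if (task == "gonogo") {
    condition <- rep(d$conditions, d$counts)
    n <- length(condition)
    go <- condition == "go"
    p_err_nogo <- min(1, max(0, eff$gonogo_errors / d$counts[2]))
    responded <- ifelse(go, stats::runif(n) < d$accuracy,
                        stats::runif(n) < p_err_nogo)
    rt <- ifelse(responded, rexgauss(n, d$base - d$tau, d$sigma, d$tau),
                 NA_real_)
    correct <- (go & responded) | (!go & !responded)
    log <- data.frame(condition = condition, rt = rt, correct = correct,
                      response = ifelse(responded, "press", ""),
                      stringsAsFactors = FALSE)
  } else if (task == "cpt") {
    condition <- rep(d$conditions, d$counts)
    n <- length(condition)
    target <- condition == "target"
    hit_p <- min(1, max(0, eff$cpt_accuracy))
    responded <- ifelse(target, stats::runif(n) < hit_p,
                        stats::runif(n) < 0.02)
    mu <- eff$cpt_rt
    rt <- ifelse(responded, rexgauss(n, mu - d$tau, d$sigma, d$tau),
                 NA_real_)
    correct <- (target & responded) | (!target & !responded)
    log <- data.frame(condition = condition, rt = rt, correct = correct,
                      response = ifelse(responded, "press", ""),
                      stringsAsFactors = FALSE)
  } else {
    shift <- switch(task,
      stroop = c(congruent = 0, incongruent = eff$stroop),
      simon = c(congruent = 0, incongruent = eff$simon),
      latent_inhibition = c(PE = eff$latent_inhibition, NPE = 0,
                            NOV = -eff$novel_popout),
      negative_priming = c(control = 0,
                           ignored_repetition = eff$negative_priming,
                           neutral = -10),
      switch = c(repetition = 0, switch = eff$switch_cost),
      antisaccade = c(pro = 0, anti = eff$antisaccade))
    condition <- rep(d$conditions, d$counts)
    n <- length(condition)
    mu <- d$base + unname(shift[condition])
    rt <- pmax(80, rexgauss(n, mu - d$tau, d$sigma, d$tau))
    correct <- stats::runif(n) < d$accuracy
    log <- data.frame(condition = condition, rt = rt, correct = correct,
                      response = ifelse(correct, "correct", "error"),
                      stringsAsFactors = FALSE)
  }

  perm <- sample.int(nrow(log))
  log <- log[perm, , drop = FALSE]
  data.frame(subject_id = profile$subject_id,
             task = task,
             trial_index = seq_len(nrow(log)),
             log,
             row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Simulate operation-span item-level results for one subject
#'
#' Letter sets of sizes 2 through 7 are presented in three blocks. Each set
#' is recalled perfectly with a probability matched to the subject's
#' planted absolute span score; imperfect recall corrupts the order or one
#' letter, so the set contributes nothing to the absolute score.
#'
#' @param profile a [subject_profile()].
#' @param seed integer seed.
#' @return A data frame with columns `set_size`, `letters_presented`,
#'   `letters_recalled`, `math_correct`.
#' @export
generate_ospan_items <- function(profile, seed = 1L) {
  set.seed(seed)
  sizes <- rep(2:7, times = 3)
  sizes <- sample(sizes)
  max_score <- sum(sizes)
  p_perfect <- min(1, max(0, profile$ospan_abs / max_score))
  consonants <- setdiff(LETTERS, c("A", "E", "I", "O", "U"))
  rows <- lapply(seq_along(sizes), function(i) {
    k <- sizes[i]
    letters_p <- paste(sample(consonants, k), collapse = "")
    if (stats::runif(1) < p_perfect) {
      letters_r <- letters_p
    } else if (k >= 2 && stats::runif(1) < 0.5) {
      # order error: swap two adjacent letters
      v <- strsplit(letters_p, "")[[1]]
      j <- sample(k - 1, 1)
      v[c(j, j + 1)] <- v[c(j + 1, j)]
      letters_r <- paste(v, collapse = "")
    } else {
      # item error: drop the last letter
      letters_r <- substr(letters_p, 1, k - 1)
    }
    data.frame(set_size = k, letters_presented = letters_p,
               letters_recalled = letters_r,
               math_correct = stats::runif(1) < 0.9,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
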