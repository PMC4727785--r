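test_that("cohort generation is deterministic and validates its spec", {
  spec <- cohort_spec(n_subjects = 10, seed = 42)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1$measures, c2$measures)
  expect_identical(c1$profiles, c2$profiles)
  expect_length(c1$profiles, 10)

  bad <- matrix(c(1, 0.9, 0.9, 0.9, 1, -0.9, 0.9, -0.9, 1), 3,
                dimnames = list(c("gating_ratio", "stroop", "simon"),
                                c("gating_ratio", "stroop", "simon")))
  expect_error(cohort_spec(target_correlations = bad),
               "positive semi-definite")
  expect_error(cohort_spec(n_subjects = 3), "at least 4")
})

test_that("independent measures stay uncorrelated at large n", {
  vars <- c("gating_ratio", "stroop", "latent_inhibition", "iq")
  R <- diag(4)
  dimnames(R) <- list(vars, vars)
  co <- generate_cohort(cohort_spec(n_subjects = 2000,
                                    target_correlations = R, seed = 7))
  emp <- cor(co$measures[, vars])
  expect_true(all(abs(emp[upper.tri(emp)]) < 0.08))
})

test_that("a planted gating-latent inhibition correlation is recovered", {
  vars <- c("gating_ratio", "latent_inhibition")
  R <- matrix(c(1, -0.63, -0.63, 1), 2, dimnames = list(vars, vars))
  co <- generate_cohort(cohort_spec(n_subjects = 5000,
                                    target_correlations = R, seed = 11))
  r <- cor(co$measures$gating_ratio, co$measures$latent_inhibition)
  expect_lt(abs(r - (-0.63)), 0.03)
})

test_that("the default target matrix is a valid correlation matrix", {
  R <- default_target_correlations()
  expect_equal(R, t(R))
  expect_equal(unname(diag(R)), rep(1, 16))
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  # the gating column carries the planted study structure
  expect_equal(R["gating_ratio", "latent_inhibition"], -0.63)
  expect_equal(R["gating_ratio", "iq"], -0.42)
})

test_that("profiles respect their physiological invariants", {
  co <- generate_cohort(cohort_spec(n_subjects = 50, seed = 3))
  for (p in co$profiles) {
    expect_gt(p$s1_p50_amp, 0)
    expect_gte(p$s2_p50_amp, 0)
    expect_true(p$n40_latency >= 20 && p$n40_latency <= 50)
    expect_true(p$p50_latency >= 40 && p$p50_latency <= 80)
    expect_lt(p$n40_latency, p$p50_latency)
    expect_lte(p$iq_raw, 46)
    expect_gte(p$ospan_abs, 0)
  }
})

test_that("raw EEG carries paired S1/S2 markers 500 ms apart", {
  rec <- generate_raw_eeg(canonical_profile(), n_paired_trials = 12,
                          n_click_trials = 3, seed = 5)
  s1 <- rec$markers$sample[rec$markers$label == "S1"]
  s2 <- rec$markers$sample[rec$markers$label == "S2"]
  expect_length(s1, 12)
  expect_length(s2, 12)
  expect_equal(sum(rec$markers$label == "click"), 3)
  # every S1 is followed by exactly one S2 at the ISI (within one sample)
  expect_true(all(abs((s2 - s1) - 0.5 * rec$rate) <= 1))
  # determinism
  rec2 <- generate_raw_eeg(canonical_profile(), n_paired_trials = 12,
                           n_click_trials = 3, seed = 5)
  expect_identical(rec$data, rec2$data)
  expect_identical(rec$markers, rec2$markers)
})

test_that("a recording without paired trials yields no epochs downstream", {
  rec <- generate_raw_eeg(canonical_profile(), n_paired_trials = 0,
                          n_click_trials = 4, seed = 2)
  expect_false(any(rec$markers$label %in% c("S1", "S2")))
  expect_error(segment(rec, "S1"), "no 'S1' markers")
})

test_that("noise-free scoring recovers the planted S1 amplitude within 2%", {
  prof <- canonical_profile()
  rec <- generate_raw_eeg(prof, n_paired_trials = 8, snr = Inf,
                          line_amp = 0, blink_rate = 0, seed = 1)
  ev <- suppressWarnings(preprocess_recording(rec))
  g <- score_gating(ev$S1, ev$S2)
  expect_false(g$excluded)
  expect_lt(abs(g$s1$amplitude - prof$s1_p50_amp) / prof$s1_p50_amp, 0.02)
  expect_lt(abs(g$ratio - 100 * prof$s2_p50_amp / prof$s1_p50_amp), 2)
})

test_that("background noise has an approximately 1/f spectrum", {
  set.seed(8)
  x <- pink_noise(2^17, rate = 2000)
  sp <- spec.pgram(ts(x, frequency = 2000), plot = FALSE, taper = 0)
  sel <- sp$freq > 1 & sp$freq < 200
  fit <- lm(log(sp$spec[sel]) ~ log(sp$freq[sel]))
  expect_lt(abs(coef(fit)[2] - (-1)), 0.25)
})

test_that("trial logs have the declared structure", {
  prof <- canonical_profile()
  gng <- generate_trial_log(prof, "gonogo", seed = 1)
  expect_equal(mean(gng$condition == "no_go"), 0.20)
  expect_equal(nrow(gng), 60)
  cpt <- generate_trial_log(prof, "cpt", seed = 1)
  expect_equal(nrow(cpt), 273)
  expect_equal(sum(cpt$condition == "target"), 82)
  expect_equal(nrow(generate_trial_log(prof, "stroop", seed = 1)), 30)
  expect_equal(nrow(generate_trial_log(prof, "simon", seed = 1)), 150)
  expect_equal(nrow(generate_trial_log(prof, "ant", seed = 1)), 290)
  expect_error(generate_trial_log(prof, "towers_of_hanoi"), "unknown task")
  # withheld no-go trials carry no RT; responded trials have positive RTs
  expect_true(all(is.na(gng$rt[gng$condition == "no_go" & gng$correct])))
  expect_true(all(gng$rt[!is.na(gng$rt)] > 0))
  # determinism
  expect_identical(generate_trial_log(prof, "stroop", seed = 9),
                   generate_trial_log(prof, "stroop", seed = 9))
})

test_that("scored task effects are unbiased for the planted effects", {
  prof <- canonical_profile()
  n_seeds <- 400
  eff <- vapply(seq_len(n_seeds), function(s)
    score_difference_index(generate_trial_log(prof, "stroop", seed = s),
                           "incongruent", "congruent"), 0)
  # planted 75 ms; MC error of the mean ~ sd/sqrt(n_seeds)
  expect_lt(abs(mean(eff) - 75), 4 * sd(eff) / sqrt(n_seeds))

  # a null planted effect scores around zero
  prof0 <- canonical_profile()
  prof0$task_effects$stroop <- 0
  eff0 <- vapply(seq_len(200), function(s)
    score_difference_index(generate_trial_log(prof0, "stroop", seed = s),
                           "incongruent", "congruent"), 0)
  expect_lt(abs(mean(eff0)), 4 * sd(eff0) / sqrt(200))
})

test_that("scored-effect dispersion matches an ex-Gaussian brute-force run", {
  # oracle: simulate the scored Stroop effect directly from the ex-Gaussian
  # trial model (15 trials/condition, accuracy 0.95), independent of the
  # trial-log generator's code path
  d <- task_designs()$stroop
  set.seed(123)
  oracle <- replicate(4000, {
    n_inc <- rbinom(1, 15, d$accuracy)
    n_con <- rbinom(1, 15, d$accuracy)
    if (n_inc == 0 || n_con == 0) return(NA_real_)
    mean(rexgauss(n_inc, d$base + 75 - d$tau, d$sigma, d$tau)) -
      mean(rexgauss(n_con, d$base - d$tau, d$sigma, d$tau))
  })
  prof <- canonical_profile()
  scored <- vapply(seq_len(1000), function(s)
    score_difference_index(generate_trial_log(prof, "stroop", seed = s),
                           "incongruent", "congruent"), 0)
  expect_lt(abs(sd(scored) / sd(oracle, na.rm = TRUE) - 1), 0.15)
})

test_that("operation-span items reflect the planted span", {
  prof <- canonical_profile()
  items <- generate_ospan_items(prof, seed = 4)
  expect_equal(sort(unique(items$set_size)), 2:7)
  expect_equal(nrow(items), 18)
  scores <- vapply(1:300, function(s)
    score_ospan(generate_ospan_items(prof, seed = s)), 0L)
  expect_lt(abs(mean(scores) - prof$ospan_abs), 5)
})

test_that("recordings round-trip through BrainVision files", {
  rec <- generate_raw_eeg(canonical_profile(), n_paired_trials = 3,
                          n_click_trials = 1, seed = 6)
  base <- file.path(tempdir(), "bv_roundtrip")
  write_brainvision(rec, base)
  back <- read_brainvision(paste0(base, ".vhdr"))
  expect_equal(back$channel_labels, rec$channel_labels)
  expect_equal(back$rate, rec$rate)
  expect_equal(back$markers$sample, rec$markers$sample)
  expect_equal(back$markers$label, rec$markers$label)
  # float32 storage: relative error bounded
  expect_lt(max(abs(back$data - rec$data)), 1e-3 * max(1, max(abs(rec$data))))
  unlink(paste0(base, c(".vhdr", ".vmrk", ".eeg")))
})
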