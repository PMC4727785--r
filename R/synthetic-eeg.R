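#' Gabor atom (Gaussian-windowed cosine)
#'
#' Building block for simulated ERP components: a single-cycle windowed
#' sinusoid peaking (value 1) at its centre. Its energy is concentrated
#' around `f0`, so an atom placed inside the 10--50 Hz analysis band
#' survives the filter chain with little shape distortion.
#'
#' @param t time axis in seconds.
#' @param center centre of the atom in seconds.
#' @param sigma Gaussian envelope SD in seconds.
#' @param f0 carrier frequency in Hz.
#' @return Numeric vector, same length as `t`.
#' @export
gabor_atom <- function(t, center, sigma = 0.008, f0 = 35) {
  exp(-(t - center)^2 / (2 * sigma^2)) * cos(2 * pi * f0 * (t - center))
}

# Raw (unfiltered) N40+P50 complex for one stimulus, sampled on t (seconds
# relative to stimulus onset). Amplitudes are pre-calibration.
erp_complex <- function(t, p50_amp, n40_amp, p50_latency_ms, n40_latency_ms) {
  p50_peak <- p50_amp + n40_amp   # n40_amp is negative
  p50_peak * gabor_atom(t, p50_latency_ms / 1000) +
    n40_amp * gabor_atom(t, n40_latency_ms / 1000)
}

# Scale factor such that the planted peak-to-trough amplitude is recovered
# exactly by the scoring rule applied after the filter chain and baseline
# correction (the filters attenuate the atoms slightly; the scale
# compensates, exploiting linearity of every stage involved).
calibrate_template_scale <- function(profile, rate, config = default_config()) {
  pc <- config$preprocessing
  pad <- 0.6
  n <- round((2 * pad + 0.4) * rate)
  t <- (seq_len(n) - 1) / rate - pad    # onset at t = 0
  u <- erp_complex(t, profile$s1_p50_amp, profile$n40_amp,
                   profile$p50_latency, profile$n40_latency)
  nyq <- rate / 2
  nt <- notch_coefficients(pc$notch, rate, pc$notch_q)
  hp <- signal::butter(pc$filter_order, pc$band[1] / nyq, type = "high")
  lp <- signal::butter(pc$filter_order, pc$band[2] / nyq, type = "low")
  y <- zero_phase(lp$b, lp$a, zero_phase(hp$b, hp$a, zero_phase(nt$b, nt$a, u)))
  sel <- t >= pc$epoch_window[1] / 1000 & t <= pc$epoch_window[2] / 1000
  times <- t[sel] * 1000
  yw <- y[sel] - mean(y[sel][times >= pc$baseline[1] & times < pc$baseline[2]])
  ev <- structure(list(data = matrix(yw, nrow = 1,
                                     dimnames = list("Cz", NULL)),
                       times = times, channel_labels = "Cz", rate = rate,
                       condition = "cal", n_epochs_retained = 1),
                  class = "evoked")
  sc <- score_p50(ev, channel = "Cz",
                  p50_window = config$scoring$p50_window,
                  n40_window = config$scoring$n40_window,
                  amp_floor = 0)
  if (!isTRUE(sc$found) || sc$amplitude <= 0)
    stop("template calibration failed: no scorable P50 in filtered template")
  profile$s1_p50_amp / sc$amplitude
}

#' 1/f ("pink") background noise
#'
#' Spectrally shaped Gaussian noise whose power spectral density falls as
#' 1/f above a low-frequency floor, the canonical first-order model of
#' background EEG. Generated by filtering white noise in the frequency
#' domain; the result is scaled to unit SD.
#'
#' @param n number of samples.
#' @param rate sampling rate in Hz.
#' @param f_floor frequency floor in Hz below which the spectrum is flat
#'   (avoids unbounded DC power).
#' @return Numeric vector of length `n`, SD 1.
#' @export
pink_noise <- function(n, rate, f_floor = 0.5) {
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  f <- seq(0, rate, length.out = n + 1)[seq_len(n)]
  f <- pmin(f, rate - f)            # two-sided frequency axis
  scale <- 1 / sqrt(pmax(f, f_floor))
  x <- Re(stats::fft(spec * scale, inverse = TRUE)) / n
  x / stats::sd(x)
}

# Half-period raised-cosine pulse (blink-like), duration in seconds.
blink_pulse <- function(rate, duration = 0.25) {
  n <- round(duration * rate)
  0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))
}

#' Simulate a raw paired-click EEG recording for one subject
#'
#' Generates a continuous multichannel recording containing, per paired
#' trial, a conditioning stimulus (S1) and a testing stimulus (S2) 500 ms
#' later, each evoking a deterministic N40 trough + P50 peak complex at Cz
#' with the profile's planted latencies and amplitudes; interleaved click
#' trials carry their own marker. The evoked complexes are calibrated so
#' that the preprocessing chain followed by the scoring rule recovers the
#' planted peak-to-trough amplitudes exactly in the noise-free limit. The
#' background is 1/f noise on every electrode, with optional 50 Hz line
#' noise, Poisson-timed blink artifacts on the vertical EOG pair (and their
#' scaled propagation onto the scalp), and occasional horizontal saccade
#' steps on the HEOG pair.
#'
#' @param profile a [subject_profile()].
#' @param n_paired_trials number of S1--S2 paired trials.
#' @param n_click_trials number of click trials interleaved at random.
#' @param rate sampling rate in Hz.
#' @param isi S1-to-S2 interval in seconds.
#' @param iti inter-trial interval in seconds (the acquisition protocol used
#'   10 s to let activity return to baseline; the simulation default is 1 s,
#'   which does not affect scoring and keeps recordings short).
#' @param snr planted S1 amplitude divided by background-noise SD;
#'   `Inf` gives a noise-free recording.
#' @param line_amp amplitude (microvolts) of 50 Hz line contamination.
#' @param blink_rate blink rate in events per second on VEOG.
#' @param blink_propagation fraction of the bipolar VEOG blink reaching Cz.
#' @param seed integer seed.
#' @param config pipeline configuration (filters used for amplitude
#'   calibration must match those used in preprocessing).
#' @return An [eeg_recording()] with S1/S2/click markers and the ground
#'   truth attached as attribute `"ground_truth"`.
#' @export
generate_raw_eeg <- function(profile, n_paired_trials = 135,
                             n_click_trials = 15, rate = 2000,
                             isi = 0.5, iti = 1, snr = 0.75,
                             line_amp = 1, blink_rate = 0.15,
                             blink_propagation = 0.1, seed = 1L,
                             config = default_config()) {
  stopifnot(inherits(profile, "subject_profile"))
  set.seed(seed)
  channels <- c("Cz", "TP9", "TP10", "VEOG+", "VEOG-", "HEOG+", "HEOG-")

  # trial schedule: paired and click slots in random order
  slot_type <- sample(c(rep("paired", n_paired_trials),
                        rep("click", n_click_trials)))
  t_cursor <- 1.0
  s1_t <- s2_t <- click_t <- numeric(0)
  for (st in slot_type) {
    if (st == "paired") {
      s1_t <- c(s1_t, t_cursor)
      s2_t <- c(s2_t, t_cursor + isi)
      t_cursor <- t_cursor + isi + iti
    } else {
      click_t <- c(click_t, t_cursor)
      t_cursor <- t_cursor + iti
    }
  }
  n <- ceiling((t_cursor + 1.0) * rate)
  duration <- n / rate

  noise_sd <- if (is.finite(snr)) profile$s1_p50_amp / snr else 0
  data <- matrix(0, nrow = length(channels), ncol = n,
                 dimnames = list(channels, NULL))
  if (noise_sd > 0)
    for (i in seq_along(channels))
      data[i, ] <- noise_sd * pink_noise(n, rate)
  if (line_amp > 0) {
    tt <- (seq_len(n) - 1) / rate
    for (i in seq_along(channels))
      data[i, ] <- data[i, ] + line_amp * sin(2 * pi * 50 * tt +
                                              stats::runif(1, 0, 2 * pi))
  }

  # evoked complexes at Cz, calibrated against the filter chain
  scale <- calibrate_template_scale(profile, rate, config)
  tmpl_span <- round(c(-0.15, 0.25) * rate)
  tmpl_t <- (tmpl_span[1]:tmpl_span[2]) / rate
  s1_tmpl <- scale * erp_complex(tmpl_t, profile$s1_p50_amp, profile$n40_amp,
                                 profile$p50_latency, profile$n40_latency)
  s2_scale <- if (profile$s1_p50_amp > 0)
    profile$s2_p50_amp / profile$s1_p50_amp else 0
  s2_tmpl <- s1_tmpl * s2_scale
  click_tmpl <- s1_tmpl * 0.8
  add_at <- function(times, tmpl) {
    for (t0 in times) {
      at <- round(t0 * rate) + 1L
      idx <- at + tmpl_span[1]:tmpl_span[2]
      ok <- idx >= 1 & idx <= n
      data["Cz", idx[ok]] <<- data["Cz", idx[ok]] + tmpl[ok]
    }
  }
  add_at(s1_t, s1_tmpl)
  add_at(s2_t, s2_tmpl)
  add_at(click_t, click_tmpl)

  # ocular activity: blinks on the vertical pair, saccade steps horizontal
  add_pulses <- function(sig, times, pulse, amps) {
    for (k in seq_along(times)) {
      at <- round(times[k] * rate) + 1L
      idx <- at:(at + length(pulse) - 1L)
      ok <- idx >= 1 & idx <= n
      sig[idx[ok]] <- sig[idx[ok]] + amps[k] * pulse[ok]
    }
    sig
  }
  n_blinks <- stats::rpois(1, blink_rate * duration)
  if (n_blinks > 0) {
    bt <- stats::runif(n_blinks, 0, duration - 0.3)
    ba <- stats::rnorm(n_blinks, 150, 25)
    pulse <- blink_pulse(rate)
    blink_sig <- add_pulses(numeric(n), bt, pulse, ba)
    data["VEOG+", ] <- data["VEOG+", ] + blink_sig
    data["VEOG-", ] <- data["VEOG-", ] - 0.1 * blink_sig
    v_bipolar <- 1.1 * blink_sig
    data["Cz", ] <- data["Cz", ] + blink_propagation * v_bipolar
  }
  n_sacc <- stats::rpois(1, 0.1 * duration)
  if (n_sacc > 0) {
    st <- stats::runif(n_sacc, 0, duration - 0.3)
    sa <- stats::rnorm(n_sacc, 0, 40)
    step <- rep(1, round(0.2 * rate))
    sacc_sig <- add_pulses(numeric(n), st, step, sa)
    data["HEOG+", ] <- data["HEOG+", ] + sacc_sig
    data["HEOG-", ] <- data["HEOG-", ] - sacc_sig
    data["Cz", ] <- data["Cz", ] + 0.03 * 2 * sacc_sig
  }

  markers <- data.frame(
    sample = c(round(s1_t * rate) + 1L, round(s2_t * rate) + 1L,
               round(click_t * rate) + 1L),
    label = c(rep("S1", length(s1_t)), rep("S2", length(s2_t)),
              rep("click", length(click_t))))
  markers <- markers[order(markers$sample), , drop = FALSE]
  rownames(markers) <- NULL

  rec <- eeg_recording(data, rate, channels, reference_label = "FCz",
                       markers = markers)
  attr(rec, "ground_truth") <- list(
    profile = profile,
    expected_ratio = min(200, 100 * profile$s2_p50_amp / profile$s1_p50_amp),
    noise_sd = noise_sd, seed = seed)
  rec
}
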