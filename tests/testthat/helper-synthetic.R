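# shared fixtures, all built in code

canonical_profile <- function(id = "T01", s1 = 1.33, s2 = 0.97,
                              n40 = -0.45, p50_lat = 55, n40_lat = 38) {
  subject_profile(id, s1_p50_amp = s1, s2_p50_amp = s2, n40_amp = n40,
                  p50_latency = p50_lat, n40_latency = n40_lat,
                  task_effects = list(stroop = 75, simon = 28,
                                      flanker = 92.35, alerting = 50,
                                      orienting = 73,
                                      latent_inhibition = 257,
                                      novel_popout = 80,
                                      negative_priming = 84,
                                      gonogo_errors = 1.8,
                                      switch_cost = 59, antisaccade = 867,
                                      cpt_accuracy = 0.97, cpt_rt = 523),
                  iq_raw = 35L, ospan_abs = 39L)
}

# evoked built directly from a waveform sampled on a [-100, 200] ms grid
make_evoked <- function(x, rate = 2000, channel = "Cz", condition = "S1") {
  pre <- round(0.1 * rate)
  post <- round(0.2 * rate)
  stopifnot(length(x) == pre + post + 1)
  structure(list(data = matrix(x, nrow = 1,
                               dimnames = list(channel, NULL)),
                 times = (-pre:post) / rate * 1000,
                 channel_labels = channel, rate = rate,
                 condition = condition, n_epochs_retained = 1),
            class = "evoked")
}

# multichannel recording from a named list of signals
make_recording <- function(signals, rate = 2000,
                           markers = data.frame(sample = integer(),
                                                label = character())) {
  data <- do.call(rbind, signals)
  eeg_recording(data, rate, names(signals), markers = markers)
}

# brute-force peak scan used as oracle against find_peak
scan_peak <- function(x, times, window, polarity) {
  if (polarity == "negative") x <- -x
  best_i <- NA
  for (i in seq_along(x)) {
    if (i == 1 || i == length(x)) next
    if (times[i] < window[1] || times[i] > window[2]) next
    l <- x[i] - x[i - 1]
    r <- x[i] - x[i + 1]
    if ((l >= 0 && r > 0) || (l > 0 && r >= 0)) {
      if (is.na(best_i) || x[i] > x[best_i]) best_i <- i
    }
  }
  if (is.na(best_i)) return(list(found = FALSE))
  list(latency = times[best_i],
       value = if (polarity == "negative") -x[best_i] else x[best_i],
       found = TRUE)
}
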