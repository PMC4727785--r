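#' Re-reference a recording to the average of the mastoids
#'
#' Subtracts the mean of the two mastoid channels (TP9, TP10 by default) from
#' every channel except the ocular (EOG) channels, which carry bipolar eye
#' activity and are left untouched.
#'
#' @param rec an [eeg_recording()].
#' @param new_ref character vector of mastoid channel labels.
#' @return The re-referenced [eeg_recording()].
#' @export
rereference <- function(rec, new_ref = c("TP9", "TP10")) {
  stopifnot(inherits(rec, "eeg_recording"))
  missing <- setdiff(new_ref, rec$channel_labels)
  if (length(missing))
    stop("mastoid channel(s) not present: ", paste(missing, collapse = ", "))
  ref_sig <- colMeans(rec$data[new_ref, , drop = FALSE])
  scalp <- !is_eog_label(rec$channel_labels)
  rec$data[scalp, ] <- sweep(rec$data[scalp, , drop = FALSE], 2, ref_sig)
  rec$reference_label <- paste(new_ref, collapse = "/")
  rec
}

# RBJ biquad notch; the width is set by the quality factor.
notch_coefficients <- function(freq, rate, q = 35) {
  w0 <- 2 * pi * freq / rate
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

# Zero-phase filtering with odd reflection padding at both ends to suppress
# edge transients (signal::filtfilt pads with zeros, which rings on long
# low-frequency edges).
zero_phase <- function(b, a, x) {
  n <- length(x)
  np <- min(n - 1L, max(3L * (max(length(a), length(b)) - 1L), 600L))
  pre <- 2 * x[1] - x[(np + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - np)]
  y <- c(pre, x, post)
  y <- signal::filter(b, a, y)
  y <- rev(signal::filter(b, a, rev(y)))
  y[(np + 1L):(np + n)]
}

#' Notch and band-pass filter a recording
#'
#' Applies a 50 Hz notch (2nd-order IIR, quality factor 35) followed by a
#' 10--50 Hz Butterworth band-pass, realized as a 4th-order high-pass at the
#' lower edge cascaded with a 4th-order low-pass at the upper edge
#' (24 dB/octave per edge). All stages are applied forward-backward
#' (zero-phase), so component peak latencies are not shifted; this doubles
#' the effective roll-off, which is documented rather than compensated.
#'
#' @param rec an [eeg_recording()].
#' @param band numeric length-2, band-pass edges in Hz.
#' @param notch notch frequency in Hz; `NA` disables the notch.
#' @param order Butterworth order per edge.
#' @param notch_q quality factor of the notch.
#' @return The filtered [eeg_recording()].
#' @export
filter_chain <- function(rec, band = c(10, 50), notch = 50, order = 4,
                         notch_q = 35) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$rate <= 2 * band[2])
    stop("sampling rate must exceed twice the band-pass upper edge")
  nyq <- rec$rate / 2
  hp <- signal::butter(order, band[1] / nyq, type = "high")
  lp <- signal::butter(order, band[2] / nyq, type = "low")
  nt <- if (!is.na(notch)) notch_coefficients(notch, rec$rate, notch_q)
  for (i in seq_len(nrow(rec$data))) {
    x <- rec$data[i, ]
    if (!is.null(nt)) x <- zero_phase(nt$b, nt$a, x)
    x <- zero_phase(hp$b, hp$a, x)
    x <- zero_phase(lp$b, lp$a, x)
    rec$data[i, ] <- x
  }
  rec
}

#' Regression-based ocular artifact correction
#'
#' Gratton--Coles-style correction: propagation coefficients of each scalp
#' channel on the bipolar vertical and horizontal EOG derivations are
#' estimated by least squares after subtracting the per-condition
#' event-related averages (so that genuine evoked activity common to EEG and
#' EOG does not inflate the coefficients), and the raw bipolar EOG scaled by
#' those coefficients is subtracted from each scalp channel. A single
#' combined regression is used for all ocular activity; blink and saccade
#' activity are not distinguished. EOG channels themselves are not modified.
#'
#' @param rec an [eeg_recording()].
#' @param veog,heog length-2 character vectors naming the positive and
#'   negative electrode of each bipolar EOG pair.
#' @param erp_window seconds around each marker used when subtracting
#'   event-related averages prior to coefficient estimation.
#' @return The corrected [eeg_recording()], with the estimated coefficients
#'   attached as attribute `"eog_coefficients"`.
#' @export
ocular_correct <- function(rec, veog = c("VEOG+", "VEOG-"),
                           heog = c("HEOG+", "HEOG-"),
                           erp_window = c(-0.1, 0.3)) {
  stopifnot(inherits(rec, "eeg_recording"))
  need <- c(veog, heog)
  missing <- setdiff(need, rec$channel_labels)
  if (length(missing))
    stop("EOG channel(s) not present: ", paste(missing, collapse = ", "))

  v <- rec$data[veog[1], ] - rec$data[veog[2], ]
  h <- rec$data[heog[1], ] - rec$data[heog[2], ]

  # residualize on event-related averages per marker label
  resid_data <- rec$data
  resid_v <- v
  resid_h <- h
  n <- ncol(rec$data)
  if (nrow(rec$markers) > 0) {
    pre <- round(-erp_window[1] * rec$rate)
    post <- round(erp_window[2] * rec$rate)
    for (lab in unique(rec$markers$label)) {
      at <- rec$markers$sample[rec$markers$label == lab]
      at <- at[at - pre >= 1 & at + post <= n]
      if (!length(at)) next
      idx <- outer(-pre:post, at, `+`)   # samples x events
      for (ch in seq_len(nrow(rec$data))) {
        seg <- matrix(rec$data[ch, idx], nrow = pre + post + 1)
        avg <- rowMeans(seg)
        resid_data[ch, idx] <- rec$data[ch, idx] - rep(avg, length(at))
      }
      segv <- matrix(v[idx], nrow = pre + post + 1)
      resid_v[idx] <- v[idx] - rep(rowMeans(segv), length(at))
      segh <- matrix(h[idx], nrow = pre + post + 1)
      resid_h[idx] <- h[idx] - rep(rowMeans(segh), length(at))
    }
  }

  degen_v <- stats::sd(resid_v) < 1e-8
  degen_h <- stats::sd(resid_h) < 1e-8
  if (degen_v || degen_h)
    warning("degenerate (constant) EOG derivation; coefficient set to 0")

  scalp <- which(!is_eog_label(rec$channel_labels))
  X <- cbind(resid_v, resid_h)
  coefs <- matrix(0, nrow = length(scalp), ncol = 2,
                  dimnames = list(rec$channel_labels[scalp], c("bV", "bH")))
  keep <- c(!degen_v, !degen_h)
  if (any(keep)) {
    fit <- stats::lm.fit(cbind(1, X[, keep, drop = FALSE]),
                         t(resid_data[scalp, , drop = FALSE]))
    b <- t(fit$coefficients)[, -1, drop = FALSE]
    coefs[, keep] <- b
  }
  for (j in seq_along(scalp))
    rec$data[scalp[j], ] <- rec$data[scalp[j], ] -
      coefs[j, 1] * v - coefs[j, 2] * h
  attr(rec, "eog_coefficients") <- coefs
  rec
}

#' Extract fixed-window epochs around stimulus markers
#'
#' Cuts one epoch per marker of the requested condition, spanning 100 ms
#' before to 200 ms after stimulus onset by default (both endpoints
#' included; the marker sample is time zero). Markers whose window exceeds
#' the recording bounds are dropped with a logged reason.
#'
#' @param rec an [eeg_recording()].
#' @param condition marker label to epoch around (`"S1"` or `"S2"`).
#' @param window epoch window in ms relative to stimulus onset.
#' @return An `epoch_set`: list with `epochs` (trials x channels x samples
#'   array), `times` (ms), `condition`, `channel_labels`, `rate`, and a
#'   `rejected` data frame (initially all `FALSE`).
#' @export
segment <- function(rec, condition, window = c(-100, 200)) {
  stopifnot(inherits(rec, "eeg_recording"), window[1] < 0, window[2] > 0)
  at <- rec$markers$sample[rec$markers$label == condition]
  if (!length(at)) stop("no '", condition, "' markers in recording")
  pre <- round(-window[1] / 1000 * rec$rate)
  post <- round(window[2] / 1000 * rec$rate)
  n <- ncol(rec$data)
  ok <- at - pre >= 1 & at + post <= n
  dropped <- at[!ok]
  at <- at[ok]
  if (!length(at)) stop("no extractable '", condition, "' epochs")
  n_samp <- pre + post + 1L
  epochs <- array(NA_real_,
                  dim = c(length(at), nrow(rec$data), n_samp))
  for (k in seq_along(at))
    epochs[k, , ] <- rec$data[, (at[k] - pre):(at[k] + post)]
  out <- structure(list(
    epochs = epochs,
    times = (-pre:post) / rec$rate * 1000,
    condition = condition,
    channel_labels = rec$channel_labels,
    rate = rec$rate,
    onsets = at,
    rejected = data.frame(epoch = seq_along(at),
                          rejected = FALSE,
                          reason = "",
                          stringsAsFactors = FALSE)),
    class = "epoch_set")
  if (length(dropped))
    attr(out, "dropped_markers") <-
      data.frame(sample = dropped, reason = "window outside recording")
  out
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %s: %d epochs x %d channels x %d samples (%d rejected)\n",
              x$condition, dim(x$epochs)[1], dim(x$epochs)[2],
              dim(x$epochs)[3], sum(x$rejected$rejected)))
  invisible(x)
}

#' Flag artifact-contaminated epochs
#'
#' An epoch is rejected if any scalp-channel sample exceeds the amplitude
#' bounds, or if the absolute first difference, scaled to microvolts per
#' millisecond, exceeds the gradient bound on any scalp channel. EOG channels
#' are excluded from screening (their blink deflections are what the ocular
#' regression corrects for, not grounds for rejection). Reasons are recorded
#' per epoch.
#'
#' @param epochs an `epoch_set`.
#' @param amp_limit amplitude bound in microvolts (applied as +/- limit).
#' @param grad_limit gradient bound in microvolts per millisecond.
#' @return The `epoch_set` with its `rejected` table updated.
#' @export
reject_artifacts <- function(epochs, amp_limit = 50, grad_limit = 50) {
  stopifnot(inherits(epochs, "epoch_set"))
  scalp <- which(!is_eog_label(epochs$channel_labels))
  dt_ms <- 1000 / epochs$rate
  for (k in seq_len(dim(epochs$epochs)[1])) {
    seg <- matrix(epochs$epochs[k, scalp, ], nrow = length(scalp))
    reasons <- character()
    if (any(abs(seg) > amp_limit)) reasons <- c(reasons, "amplitude")
    grad <- abs(seg[, -1, drop = FALSE] - seg[, -ncol(seg), drop = FALSE]) /
      dt_ms
    if (any(grad > grad_limit)) reasons <- c(reasons, "gradient")
    if (length(reasons)) {
      epochs$rejected$rejected[k] <- TRUE
      epochs$rejected$reason[k] <- paste(reasons, collapse = "+")
    }
  }
  epochs
}

#' Subtract the pre-stimulus baseline from each epoch
#'
#' Per epoch and channel, subtracts the mean over the baseline interval.
#' The interval is half-open: samples at -100 ms up to but excluding 0 ms,
#' so the stimulus-onset sample belongs to the post-stimulus side.
#'
#' @param epochs an `epoch_set` whose window covers the baseline interval.
#' @param interval baseline interval in ms.
#' @return The baseline-corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs, interval = c(-100, 0)) {
  stopifnot(inherits(epochs, "epoch_set"))
  sel <- epochs$times >= interval[1] & epochs$times < interval[2]
  if (!any(sel)) stop("epoch window does not cover the baseline interval")
  d <- dim(epochs$epochs)
  for (k in seq_len(d[1])) {
    bl <- rowMeans(matrix(epochs$epochs[k, , sel], nrow = d[2]))
    epochs$epochs[k, , ] <- matrix(epochs$epochs[k, , ], nrow = d[2]) - bl
  }
  epochs
}

#' Average retained epochs into an evoked response
#'
#' @param epochs an `epoch_set`.
#' @return An `evoked`: list with `data` (channels x samples), `times`,
#'   `channel_labels`, `rate`, `condition`, `n_epochs_retained`.
#' @export
average_epochs <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  keep <- which(!epochs$rejected$rejected)
  if (!length(keep))
    stop("no epochs retained after artifact rejection")
  data <- apply(epochs$epochs[keep, , , drop = FALSE], c(2, 3), mean)
  rownames(data) <- epochs$channel_labels
  structure(list(data = data,
                 times = epochs$times,
                 channel_labels = epochs$channel_labels,
                 rate = epochs$rate,
                 condition = epochs$condition,
                 n_epochs_retained = length(keep)),
            class = "evoked")
}

#' @export
print.evoked <- function(x, ...) {
  cat(sprintf("<evoked> %s: mean of %d epochs, %d channels, %.0f..%.0f ms\n",
              x$condition, x$n_epochs_retained, nrow(x$data),
              min(x$times), max(x$times)))
  invisible(x)
}

#' Run the full preprocessing chain on one recording
#'
#' Fixed stage order: re-reference to average mastoids, notch + band-pass
#' filtering, ocular correction, segmentation, artifact rejection, baseline
#' correction, averaging — once per condition.
#'
#' @param rec an [eeg_recording()].
#' @param conditions marker labels to produce evokeds for.
#' @param config optional list overriding preprocessing constants; see
#'   [default_config()].
#' @return A list with one `evoked` per condition plus `rejections`, a data
#'   frame logging per-epoch rejection decisions.
#' @export
preprocess_recording <- function(rec, conditions = c("S1", "S2"),
                                 config = default_config()) {
  pc <- config$preprocessing
  rec <- rereference(rec, pc$mastoids)
  rec <- filter_chain(rec, band = pc$band, notch = pc$notch,
                      order = pc$filter_order, notch_q = pc$notch_q)
  rec <- ocular_correct(rec, veog = pc$veog, heog = pc$heog)
  out <- list()
  rej <- list()
  for (cond in conditions) {
    ep <- segment(rec, cond, window = pc$epoch_window)
    ep <- reject_artifacts(ep, amp_limit = pc$amp_limit,
                           grad_limit = pc$grad_limit)
    ep <- baseline_correct(ep, interval = pc$baseline)
    out[[cond]] <- average_epochs(ep)
    r <- ep$rejected
    r$condition <- cond
    rej[[cond]] <- r
  }
  out$rejections <- do.call(rbind, rej)
  rownames(out$rejections) <- NULL
  out
}
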