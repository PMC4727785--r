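#' Find the extremal local peak of an evoked response in a latency window
#'
#' Scans the requested channel for local extrema of the requested polarity
#' whose latency falls inside the window (endpoints included) and returns
#' the most extreme one. A local maximum is a sample at least as large as
#' both neighbours and strictly larger than one of them (mirrored for
#' minima), so a monotone ramp through the window yields no peak. Ties are
#' broken by the earliest latency. Latencies are reported on the sample
#' grid; no sub-sample interpolation is attempted.
#'
#' @param evoked an `evoked` object.
#' @param channel channel label, typically `"Cz"`.
#' @param polarity `"positive"` or `"negative"`.
#' @param window latency window in ms.
#' @return List with `latency` (ms), `value` (microvolts) and `found`.
#' @export
find_peak <- function(evoked, channel = "Cz",
                      polarity = c("positive", "negative"),
                      window) {
  polarity <- match.arg(polarity)
  stopifnot(inherits(evoked, "evoked"), length(window) == 2)
  if (!channel %in% evoked$channel_labels)
    stop("channel not present: ", channel)
  x <- evoked$data[channel, ]
  if (polarity == "negative") x <- -x
  t <- evoked$times
  n <- length(x)
  idx <- which(t >= window[1] & t <= window[2])
  idx <- idx[idx > 1 & idx < n]   # a peak needs both neighbours
  if (!length(idx)) return(list(latency = NA_real_, value = NA_real_,
                                found = FALSE))
  left <- x[idx] - x[idx - 1]
  right <- x[idx] - x[idx + 1]
  is_peak <- (left >= 0 & right > 0) | (left > 0 & right >= 0)
  cand <- idx[is_peak]
  if (!length(cand)) return(list(latency = NA_real_, value = NA_real_,
                                 found = FALSE))
  best <- cand[which.max(x[cand])]   # which.max returns the first on ties
  value <- if (polarity == "negative") -x[best] else x[best]
  list(latency = t[best], value = value, found = TRUE)
}

#' Score the P50 component of an evoked response
#'
#' P50 is the most positive local peak at Cz between 40 and 80 ms
#' post-stimulus; N40 is the most negative local trough between 20 and
#' 50 ms, constrained to precede the P50. If no local trough precedes the
#' P50 within that range, the minimum value over the pre-P50 part of the
#' N40 window is used as trough fallback (the amplitude definition requires
#' a preceding trough value). The component amplitude is the P50 peak value
#' minus the N40 trough value. A P50 is deemed absent (`found = FALSE`) when
#' no positive local maximum exists in the window or when the resulting
#' amplitude does not exceed a small configurable floor.
#'
#' @param evoked an `evoked` object covering at least 0--80 ms.
#' @param channel channel scored (default `"Cz"`).
#' @param p50_window,n40_window latency windows in ms.
#' @param amp_floor smallest amplitude (microvolts) accepted as a real P50.
#' @return A `peak_score`: list with `n40_latency`, `n40_value`,
#'   `p50_latency`, `p50_value`, `amplitude` and `found`.
#' @export
score_p50 <- function(evoked, channel = "Cz", p50_window = c(40, 80),
                      n40_window = c(20, 50), amp_floor = 0.05) {
  p50 <- find_peak(evoked, channel, "positive", p50_window)
  if (!p50$found)
    return(structure(list(n40_latency = NA_real_, n40_value = NA_real_,
                          p50_latency = NA_real_, p50_value = NA_real_,
                          amplitude = NA_real_, found = FALSE),
                     class = "peak_score"))
  half_ms <- 1000 / evoked$rate / 2
  n40_win <- c(n40_window[1], min(n40_window[2], p50$latency - half_ms))
  n40 <- find_peak(evoked, channel, "negative", n40_win)
  if (!n40$found) {
    # trough fallback: minimum over the pre-P50 part of the N40 window
    sel <- evoked$times >= n40_win[1] & evoked$times <= n40_win[2]
    if (any(sel)) {
      x <- evoked$data[channel, sel]
      t <- evoked$times[sel]
      i <- which.min(x)
      n40 <- list(latency = t[i], value = x[i], found = TRUE)
    }
  }
  amplitude <- if (n40$found) p50$value - n40$value else NA_real_
  found <- n40$found && !is.na(amplitude) && amplitude > amp_floor
  structure(list(n40_latency = n40$latency, n40_value = n40$value,
                 p50_latency = p50$latency, p50_value = p50$value,
                 amplitude = amplitude, found = found),
            class = "peak_score")
}

#' Construct a peak score directly from amplitudes
#'
#' Convenience constructor for feeding [compute_gating()] with known
#' amplitudes (e.g. worked examples or externally scored data).
#'
#' @param amplitude peak-to-trough amplitude in microvolts.
#' @param found whether a P50 was identified.
#' @param p50_latency,n40_latency optional latencies in ms.
#' @return A `peak_score`.
#' @export
peak_score <- function(amplitude, found = TRUE, p50_latency = NA_real_,
                       n40_latency = NA_real_) {
  structure(list(n40_latency = n40_latency, n40_value = NA_real_,
                 p50_latency = p50_latency, p50_value = NA_real_,
                 amplitude = amplitude, found = found),
            class = "peak_score")
}

#' Compute the S2/S1 sensory-gating ratio
#'
#' The gating ratio is 100 times the S2 P50 amplitude divided by the S1 P50
#' amplitude; a smaller ratio indicates stronger gating. Subjects without an
#' identifiable S1 P50 are excluded. An absent S2 P50 is treated as full
#' suppression and scored with a placeholder amplitude of 0.01 microvolts.
#' Ratios above 200 are truncated to 200 so extreme values cannot dominate
#' group statistics; truncation is applied to the per-subject ratio only,
#' after imputation.
#'
#' @param s1,s2 `peak_score` objects for the conditioning (S1) and testing
#'   (S2) stimulus.
#' @param impute_value amplitude substituted for an absent S2 P50.
#' @param ceiling truncation ceiling for the ratio.
#' @return A `gating_result`: list with `s1`, `s2`, `s2_amplitude_used`,
#'   `s2_imputed`, `ratio`, `excluded`.
#' @export
compute_gating <- function(s1, s2, impute_value = 0.01, ceiling = 200) {
  excluded <- !isTRUE(s1$found)
  if (!excluded && (is.na(s1$amplitude) || s1$amplitude <= 0)) {
    warning("S1 scored as found but has non-positive amplitude; ",
            "treating as not found (subject excluded)")
    excluded <- TRUE
  }
  if (excluded) {
    return(structure(list(s1 = s1, s2 = s2,
                          s2_amplitude_used = NA_real_,
                          s2_imputed = FALSE,
                          ratio = NA_real_, excluded = TRUE),
                     class = "gating_result"))
  }
  s2_imputed <- !isTRUE(s2$found)
  s2_amp <- if (s2_imputed) impute_value else s2$amplitude
  ratio <- min(ceiling, 100 * s2_amp / s1$amplitude)
  structure(list(s1 = s1, s2 = s2,
                 s2_amplitude_used = s2_amp,
                 s2_imputed = s2_imputed,
                 ratio = ratio, excluded = FALSE),
            class = "gating_result")
}

#' @export
print.gating_result <- function(x, ...) {
  if (x$excluded) {
    cat("<gating_result> excluded (no identifiable S1 P50)\n")
  } else {
    cat(sprintf(
      "<gating_result> S1 %.3f uV, S2 %.3f uV%s -> ratio %.2f\n",
      x$s1$amplitude, x$s2_amplitude_used,
      if (x$s2_imputed) " (imputed, full suppression)" else "",
      x$ratio))
  }
  invisible(x)
}

#' Score gating for one subject from S1/S2 evoked responses
#'
#' @param s1_evoked,s2_evoked `evoked` objects.
#' @param config optional configuration list; see [default_config()].
#' @return A `gating_result` with the two `peak_score`s attached.
#' @export
score_gating <- function(s1_evoked, s2_evoked, config = default_config()) {
  sc <- config$scoring
  s1 <- score_p50(s1_evoked, channel = sc$channel,
                  p50_window = sc$p50_window, n40_window = sc$n40_window,
                  amp_floor = sc$amp_floor)
  s2 <- score_p50(s2_evoked, channel = sc$channel,
                  p50_window = sc$p50_window, n40_window = sc$n40_window,
                  amp_floor = sc$amp_floor)
  compute_gating(s1, s2, impute_value = sc$impute_value,
                 ceiling = sc$ratio_ceiling)
}

#' Tabulate gating results across subjects
#'
#' @param results named list of `gating_result` objects (names are subject
#'   ids).
#' @return Data frame with one row per subject: amplitudes, latencies,
#'   imputation/exclusion flags and the truncated ratio.
#' @export
gating_table <- function(results) {
  rows <- lapply(names(results), function(id) {
    g <- results[[id]]
    data.frame(subject_id = id,
               s1_amp = g$s1$amplitude %||% NA_real_,
               s2_amp = g$s2_amplitude_used %||% NA_real_,
               s1_lat = g$s1$p50_latency %||% NA_real_,
               s2_lat = g$s2$p50_latency %||% NA_real_,
               imputed = isTRUE(g$s2_imputed),
               excluded = isTRUE(g$excluded),
               ratio = g$ratio %||% NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
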