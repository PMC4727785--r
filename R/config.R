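#' Default pipeline configuration
#'
#' All numeric constants used by the preprocessing chain, the P50 scorer and
#' the statistical battery, collected in one nested list so a whole run is
#' reproducible from a single object. Any subset can be overridden by
#' passing a partial list to `default_config()`; unnamed fields keep their
#' defaults.
#'
#' @param ... named overrides, e.g.
#'   `default_config(scoring = list(amp_floor = 0.1))`.
#' @return Nested list with elements `preprocessing`, `scoring`, `stats`.
#' @export
default_config <- function(...) {
  cfg <- list(
    preprocessing = list(
      mastoids = c("TP9", "TP10"),
      band = c(10, 50),          # Hz band-pass edges
      notch = 50,                # Hz
      filter_order = 4,          # Butterworth order per edge (24 dB/octave)
      notch_q = 35,
      veog = c("VEOG+", "VEOG-"),
      heog = c("HEOG+", "HEOG-"),
      epoch_window = c(-100, 200),  # ms around stimulus onset
      baseline = c(-100, 0),        # ms, half-open on the right
      amp_limit = 50,               # microvolts
      grad_limit = 50               # microvolts per millisecond
    ),
    scoring = list(
      channel = "Cz",
      p50_window = c(40, 80),    # ms
      n40_window = c(20, 50),    # ms
      amp_floor = 0.05,          # microvolts; below this no P50 is accepted
      impute_value = 0.01,       # microvolts, full-suppression placeholder
      ratio_ceiling = 200
    ),
    stats = list(
      ant_convention = "paper_text",  # or "fan2002"
      alpha = 0.05,
      p_adjust = "none"               # "holm" available, off by default
    )
  )
  dots <- list(...)
  for (top in names(dots)) {
    if (!top %in% names(cfg)) stop("unknown config section: ", top)
    for (key in names(dots[[top]])) {
      if (!key %in% names(cfg[[top]]))
        stop("unknown config field: ", top, "$", key)
      cfg[[top]][[key]] <- dots[[top]][[key]]
    }
  }
  cfg
}
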