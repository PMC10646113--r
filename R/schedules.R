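#' Stimulus event
#'
#' A single stimulus application: an instantaneous kick (`duration_h = 0`)
#' or a constant drive spread over `duration_h` with total impulse equal to
#' the calibrated kick for `dose`.
#'
#' @param t_h onset time (hours, >= 0).
#' @param dose stimulus dose (MPa or mOsm depending on `kind`).
#' @param kind `"compression_MPa"` or `"osmotic_mOsm"`.
#' @param duration_h duration in hours (0 = instantaneous).
#' @return one-row data.frame.
#' @export
stimulus_event <- function(t_h, dose, kind = "osmotic_mOsm", duration_h = 0) {
  if (t_h < 0) stop("t_h must be >= 0")
  if (duration_h < 0) stop("duration_h must be >= 0")
  if (dose < 0) stop("dose must be >= 0")
  kind <- match.arg(kind, c("osmotic_mOsm", "compression_MPa"))
  data.frame(t_h = t_h, duration_h = duration_h, dose = dose, kind = kind,
             stringsAsFactors = FALSE)
}

#' Stimulus schedule
#'
#' @param events data.frame of [stimulus_event()] rows (may be empty/NULL).
#' @param square_wave optional list `(period_h, on_fraction, dose, kind,
#'   phase_offset_h, stop_h)` describing sustained square-wave forcing such as
#'   12 h on / 12 h off loading; `stop_h` ends the forcing (default `Inf`).
#' @return object of class `stimulus_schedule`.
#' @export
stimulus_schedule <- function(events = NULL, square_wave = NULL) {
  if (is.null(events)) {
    events <- data.frame(t_h = numeric(0), duration_h = numeric(0),
                         dose = numeric(0), kind = character(0),
                         stringsAsFactors = FALSE)
  }
  if (nrow(events) > 1 && is.unsorted(events$t_h)) {
    o <- order(events$t_h)
    cells <- attr(events, "cells")
    events <- events[o, , drop = FALSE]
    if (!is.null(cells)) attr(events, "cells") <- cells[o]
  }
  if (!is.null(square_wave)) {
    need <- c("period_h", "on_fraction", "dose", "kind")
    if (!all(need %in% names(square_wave)))
      stop("square_wave needs fields: ", paste(need, collapse = ", "))
    if (square_wave$on_fraction <= 0 || square_wave$on_fraction >= 1)
      stop("square_wave on_fraction must be in (0, 1)")
    if (is.null(square_wave$phase_offset_h)) square_wave$phase_offset_h <- 0
    if (is.null(square_wave$stop_h)) square_wave$stop_h <- Inf
  }
  structure(list(events = events, square_wave = square_wave),
            class = "stimulus_schedule")
}

# phase categories, hours after the reporter peak
.phase_categories <- c(peak = 0, mid_descending = 6, trough = 12,
                       mid_ascending = 18)

#' Build a stimulus schedule from a named experimental preset
#'
#' Presets mirror the study's stimulation protocols:
#' \describe{
#'   \item{single_pulse}{one stimulus at `t_h` (instantaneous by default, or
#'     `duration_h` such as the 1-h compression bout).}
#'   \item{phase_series}{one schedule per circadian phase category
#'     (`peak`, `mid_descending`, `trough`, `mid_ascending`, mapped to 0, 6,
#'     12, 18 h after the reporter peak at `ref_peak_h`).}
#'   \item{daily_pulses}{`n_days` pulses 24 h apart starting at `t_h`.}
#'   \item{antiphase_12_12}{two square-wave schedules (12 h on / 12 h off
#'     compression for `days` days) offset by 12 h from each other.}
#'   \item{osmotic_cycles}{`n_cycles` daily 12-h hyperosmotic exposures.}
#'   \item{treadmill_in_vivo}{five daily 45-min loading pulses applied at the
#'     trough phase category.}
#' }
#'
#' @param preset preset name (see Details).
#' @param t_h,dose,kind,duration_h event parameters (preset-dependent
#'   defaults).
#' @param ref_peak_h time of the reporter peak used to anchor phase
#'   categories.
#' @param phases phase categories for `phase_series`.
#' @param n_days,n_cycles,days protocol lengths.
#' @param start_h forcing start for `antiphase_12_12` / `osmotic_cycles`.
#' @return a `stimulus_schedule`, or a named list of schedules for
#'   `phase_series` and `antiphase_12_12`.
#' @export
make_schedule <- function(preset, t_h = 72, dose = 200, kind = "osmotic_mOsm",
                          duration_h = 0, ref_peak_h = 72,
                          phases = names(.phase_categories),
                          n_days = 5, n_cycles = 2, days = 3, start_h = 0) {
  presets <- c("single_pulse", "phase_series", "daily_pulses",
               "antiphase_12_12", "osmotic_cycles", "treadmill_in_vivo")
  if (!preset %in% presets)
    stop("unknown preset '", preset, "'; available: ",
         paste(presets, collapse = ", "))
  switch(preset,
    single_pulse = stimulus_schedule(stimulus_event(t_h, dose, kind,
                                                    duration_h)),
    phase_series = {
      phases <- match.arg(phases, names(.phase_categories),
                          several.ok = TRUE)
      out <- lapply(phases, function(p) {
        stimulus_schedule(stimulus_event(ref_peak_h + .phase_categories[[p]],
                                         dose, kind, duration_h))
      })
      names(out) <- phases
      out
    },
    daily_pulses = {
      ev <- do.call(rbind, lapply(seq_len(n_days) - 1L, function(k)
        stimulus_event(t_h + 24 * k, dose, kind, duration_h)))
      stimulus_schedule(ev)
    },
    antiphase_12_12 = {
      if (missing(dose)) dose <- 0.5
      if (missing(kind)) kind <- "compression_MPa"
      sw <- function(off) list(period_h = 24, on_fraction = 0.5, dose = dose,
                               kind = kind, phase_offset_h = start_h + off,
                               stop_h = start_h + 24 * days)
      list(in_phase = stimulus_schedule(square_wave = sw(0)),
           antiphase = stimulus_schedule(square_wave = sw(12)))
    },
    osmotic_cycles = {
      if (missing(duration_h)) duration_h <- 12
      ev <- do.call(rbind, lapply(seq_len(n_cycles) - 1L, function(k)
        stimulus_event(start_h + 24 * k, dose, kind, duration_h)))
      stimulus_schedule(ev)
    },
    treadmill_in_vivo = {
      if (missing(dose)) dose <- 0.5
      if (missing(kind)) kind <- "compression_MPa"
      t0 <- ref_peak_h + .phase_categories[["trough"]]
      ev <- do.call(rbind, lapply(0:4, function(k)
        stimulus_event(t0 + 24 * k, dose, kind, duration_h = 0.75)))
      stimulus_schedule(ev)
    })
}
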