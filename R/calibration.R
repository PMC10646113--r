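#' Pipeline-reported phase shift of one deterministic kick
#'
#' Canonical deterministic protocol used for dose calibration and
#' phase-response geometry: a single noiseless oscillator, synchronised at
#' the reporter peak at t = 0, receives one instantaneous kick of magnitude
#' `eps` along `dir_rad` at circadian phase `phase_h` of the cycle starting
#' at `anchor_peak_h`; the shift is then estimated from the recording with
#' the baseline-extrapolation cosinor method.
#'
#' @param eps kick magnitude (units of the limit radius).
#' @param dir_rad kick direction (radians).
#' @param phase_h stimulus phase, hours after the reporter peak.
#' @param anchor_peak_h reference peak time (multiple of the period).
#' @param t_end_h recording length.
#' @param params deterministic oscillator parameters.
#' @return `phase_shift_estimate` (advance positive, delay negative).
#' @export
deterministic_kick_shift <- function(eps, dir_rad, phase_h,
                                     anchor_peak_h = 96, t_end_h = 216,
                                     params = deterministic_params()) {
  # eps_max = 2*eps at dose = half_dose yields a kick of exactly eps
  calib <- dose_calibration("osmotic_mOsm", eps_max = 2 * eps, half_dose = 1,
                            kick_direction_rad = dir_rad)
  sched <- stimulus_schedule(stimulus_event(anchor_peak_h + phase_h,
                                            dose = 1, kind = "osmotic_mOsm"))
  rec <- simulate_ensemble(params, sched, calib, t_end_h)
  estimate_phase_shift(as_lum_series(rec), anchor_peak_h + phase_h)
}

#' Fit the osmotic dose calibration by root finding on the pipeline
#'
#' Finds the kick magnitude for which the pipeline reports the target
#' maximal phase delay for a +`dose` mOsm instantaneous stimulus at the
#' mid-descending phase of the deterministic oscillator, then converts it to
#' `eps_max` for the saturating dose map with the stated half-dose and
#' direction. A coarse grid brackets the root before `uniroot` refinement.
#'
#' @param target_delay_h printed maximal delay (hours, positive).
#' @param dose dose achieving the maximal delay (mOsm).
#' @param half_dose saturation constant K (mOsm).
#' @param dir_rad kick direction (radians).
#' @param phase_h stimulus phase (mid-descending = 6 h after peak).
#' @return fitted `dose_calibration`; attribute `fit` records the achieved
#'   shift.
#' @export
calibrate_osmotic_kick <- function(target_delay_h = 9.5, dose = 400,
                                   half_dose = 300, dir_rad = 1.4835299,
                                   phase_h = 6) {
  f <- function(eps)
    deterministic_kick_shift(eps, dir_rad, phase_h)$shift_h + target_delay_h
  grid <- seq(0.2, 3, by = 0.2)
  vals <- vapply(grid, f, numeric(1))
  i <- which(diff(sign(vals)) != 0)
  if (!length(i)) stop("target delay not bracketed by the kick grid")
  root <- stats::uniroot(f, c(grid[i[1]], grid[i[1] + 1]), tol = 1e-5)
  eps_max <- root$root * (dose + half_dose) / dose
  out <- dose_calibration("osmotic_mOsm", eps_max, half_dose, dir_rad)
  attr(out, "fit") <- list(eps_at_dose = root$root,
                           achieved_shift_h = f(root$root) - target_delay_h,
                           target_delay_h = target_delay_h, dose = dose)
  out
}

#' Pipeline-reported cumulative shift of the in-vivo loading preset
#'
#' Deterministic oracle for the treadmill protocol: five daily 45-min
#' loading pulses at the trough phase category, shift measured after the
#' last pulse by baseline extrapolation on the deterministic oscillator.
#'
#' @param eps_pulse kick magnitude per pulse.
#' @param dir_rad kick direction.
#' @param t_first_pulse_h first pulse time (trough of the unperturbed
#'   oscillator).
#' @return shift in hours (advance positive).
#' @export
deterministic_treadmill_shift <- function(eps_pulse, dir_rad,
                                          t_first_pulse_h = 60) {
  calib <- dose_calibration("compression_MPa", eps_max = 2 * eps_pulse,
                            half_dose = 1, kick_direction_rad = dir_rad)
  ev <- do.call(rbind, lapply(0:4, function(k)
    stimulus_event(t_first_pulse_h + 24 * k, dose = 1, "compression_MPa",
                   duration_h = 0.75)))
  sched <- stimulus_schedule(ev)
  t_last_end <- t_first_pulse_h + 96 + 0.75
  rec <- simulate_ensemble(deterministic_params(), sched, calib,
                           t_end_h = t_last_end + 72)
  estimate_phase_shift(as_lum_series(rec), t_last_end,
                       pre_end_h = t_first_pulse_h)$shift_h
}

#' Ensemble-level treadmill shift for a candidate loading calibration
#'
#' Runs the full treadmill protocol (five daily 45-min pulses at the trough
#' phase on a default synchronized ensemble, parallel unstimulated control,
#' control-referenced shift after the last pulse) and averages the reported
#' shift over a set of calibration seeds.
#'
#' @param calib candidate loading `dose_calibration`.
#' @param dose pulse dose (MPa).
#' @param seeds calibration seeds averaged over.
#' @return mean shift in hours (advance positive).
#' @export
ensemble_treadmill_shift <- function(calib, dose = 0.5, seeds = 101:106) {
  mean(vapply(seeds, function(s) {
    sched <- make_schedule("treadmill_in_vivo", dose = dose, ref_peak_h = 0)
    t_last_end <- max(sched$events$t_h) + 0.75
    treated <- simulate_ensemble(oscillator_params(seed = s), sched, calib,
                                 t_end_h = t_last_end + 62)
    control <- simulate_ensemble(oscillator_params(seed = s + 1L), NULL,
                                 NULL, t_end_h = t_last_end + 62)
    estimate_phase_shift(as_lum_series(treated), t_last_end,
                         control = as_lum_series(control),
                         method = "control_referenced")$shift_h
  }, numeric(1)))
}

#' Fit the in-vivo loading calibration
#'
#' Two stages: (1) grid search over the kick direction crossed with root
#' finding on the per-pulse magnitude so that the deterministic treadmill
#' oracle accumulates the target printed phase advance; (2) refinement of
#' the magnitude on the full ensemble protocol (mean over fixed calibration
#' seeds), which absorbs the small systematic offset between the
#' deterministic oscillator and the noisy, heterogeneous ensemble.
#'
#' @param target_advance_h printed in-vivo advance (hours, positive).
#' @param dose pulse dose (MPa).
#' @param half_dose saturation constant K (MPa).
#' @param dir_grid_rad candidate kick directions.
#' @param ensemble_refine run stage 2.
#' @return fitted `dose_calibration`; attribute `fit` records the search.
#' @export
calibrate_loading_kick <- function(target_advance_h = 8, dose = 0.5,
                                   half_dose = 0.25,
                                   dir_grid_rad = c(45, 50, 55, 60) *
                                     pi / 180,
                                   ensemble_refine = TRUE) {
  best <- NULL
  for (dir_rad in dir_grid_rad) {
    f <- function(eps)
      deterministic_treadmill_shift(eps, dir_rad) - target_advance_h
    grid <- seq(0.3, 2.4, by = 0.3)
    vals <- vapply(grid, f, numeric(1))
    i <- which(diff(sign(vals)) != 0)
    cand <- if (length(i)) {
      root <- stats::uniroot(f, c(grid[i[1]], grid[i[1] + 1]), tol = 1e-4)
      list(dir_rad = dir_rad, eps = root$root, err = abs(f(root$root)))
    } else {
      j <- which.min(abs(vals))
      list(dir_rad = dir_rad, eps = grid[j], err = abs(vals[j]))
    }
    if (is.null(best) || cand$err < best$err) best <- cand
  }
  to_calib <- function(eps)
    dose_calibration("compression_MPa", eps * (dose + half_dose) / dose,
                     half_dose, best$dir_rad)
  if (ensemble_refine) {
    g <- function(eps)
      ensemble_treadmill_shift(to_calib(eps), dose) - target_advance_h
    lo <- 0.3 * best$eps; hi <- 1.2 * best$eps
    root <- try(stats::uniroot(g, c(lo, hi), tol = 1e-3), silent = TRUE)
    if (!inherits(root, "try-error")) {
      best$eps <- root$root
      best$err <- abs(g(root$root))
    }
  }
  out <- to_calib(best$eps)
  attr(out, "fit") <- c(best, target_advance_h = target_advance_h,
                        dose = dose)
  out
}
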