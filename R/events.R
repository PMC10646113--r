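#' Detect peaks and troughs of a detrended trace
#'
#' Local maxima of the smoothed series, with greedy retention of the higher
#' peak whenever two candidates fall within `min_separation_h`; troughs are
#' detected analogously on the negated signal.
#'
#' @param series a uniformly sampled, detrended `lum_series`.
#' @param min_separation_h minimum separation between retained peaks (hours).
#' @param smooth_window_h centred moving-average smoothing window (hours);
#'   0 disables smoothing.
#' @return `peak_set`: list with `peak_times_h`, `peak_heights`,
#'   `trough_times_h`, `trough_heights`. Empty vectors when nothing is found.
#' @export
detect_peaks <- function(series, min_separation_h = 16, smooth_window_h = 4) {
  stopifnot(inherits(series, "lum_series"))
  if (!.is_uniform(series$time_h))
    stop("detect_peaks expects a uniform grid; resample_uniform() first")
  t <- series$time_h
  dt <- t[2] - t[1]
  y <- series$signal
  if (smooth_window_h > 0) {
    k <- max(1L, round(smooth_window_h / dt))
    if (k %% 2 == 0) k <- k + 1L
    if (k > 1) {
      ys <- as.numeric(stats::filter(y, rep(1 / k, k), sides = 2))
      keep <- !is.na(ys)
      t <- t[keep]; y <- ys[keep]
    }
  }
  find <- function(v) {
    n <- length(v)
    if (n < 3) return(integer(0))
    i <- which(v[2:(n - 1)] >= v[1:(n - 2)] & v[2:(n - 1)] > v[3:n]) + 1L
    if (!length(i)) return(integer(0))
    keep <- integer(0)
    for (j in i[order(v[i], decreasing = TRUE)]) {
      if (!length(keep) || all(abs(t[j] - t[keep]) >= min_separation_h))
        keep <- c(keep, j)
    }
    sort(keep)
  }
  ip <- find(y)
  it <- find(-y)
  structure(list(peak_times_h = t[ip], peak_heights = y[ip],
                 trough_times_h = t[it], trough_heights = y[it]),
            class = "peak_set")
}

#' Amplitude change after a stimulus, as a percentage of a reference peak
#'
#' 100 x (height of the first peak after `event_time_h`) / (height of the
#' reference peak). The reference is either the last peak at or before the
#' event (`pre_event_peak`) or the peak nearest 24 h after the start of the
#' recording (`peak_24h_after_start`). Heights are detrended peak heights
#' (peak-to-midline); set `peak_to_trough = TRUE` for the alternative
#' peak-to-following-trough reading.
#'
#' @param series detrended `lum_series`.
#' @param event_time_h stimulus time (hours).
#' @param reference reference-peak mode.
#' @param peak_to_trough use peak minus following trough as the height.
#' @param ... passed to [detect_peaks()].
#' @return percentage (numeric scalar).
#' @export
amplitude_percent_change <- function(series, event_time_h,
                                     reference = c("pre_event_peak",
                                                   "peak_24h_after_start"),
                                     peak_to_trough = FALSE, ...) {
  reference <- match.arg(reference)
  pk <- detect_peaks(series, ...)
  if (!length(pk$peak_times_h)) stop("no peaks detected")
  height <- function(i) {
    h <- pk$peak_heights[i]
    if (peak_to_trough) {
      nt <- which(pk$trough_times_h > pk$peak_times_h[i])
      if (!length(nt)) stop("no trough after peak for peak_to_trough height")
      h <- h - pk$trough_heights[nt[1]]
    }
    h
  }
  i_post <- which(pk$peak_times_h > event_time_h)
  if (!length(i_post))
    stop("no post-event peak found after t = ", event_time_h, " h")
  i_ref <- if (reference == "pre_event_peak") {
    cand <- which(pk$peak_times_h <= event_time_h)
    if (!length(cand))
      stop("no pre-event reference peak found before t = ", event_time_h,
           " h")
    cand[length(cand)]
  } else {
    tgt <- min(series$time_h) + 24
    which.min(abs(pk$peak_times_h - tgt))
  }
  100 * height(i_post[1]) / height(i_ref)
}

#' Wrap a phase difference into (-12, +12] hours
#' @param x hours.
#' @param period_h cycle length.
#' @return wrapped value; advances positive, delays negative.
#' @export
wrap_phase_h <- function(x, period_h = 24) {
  x - period_h * ceiling((x - period_h / 2) / period_h)
}

#' Estimate the phase shift produced by a stimulus
#'
#' `baseline_extrapolation`: a fixed-period cosinor fitted to the pre-event
#' window predicts where peaks would have fallen; a cosinor fitted to the
#' post-event window (excluding a transient right after the event) gives the
#' observed peaks; shift = wrap(predicted peak - observed peak), so an
#' earlier-than-predicted peak gives a positive shift (advance).
#' `control_referenced`: the same formula with a parallel control trace's
#' fitted peak as the prediction, both fitted on the post window.
#'
#' @param treated treated `lum_series`.
#' @param event_time_h stimulus time (hours).
#' @param control control `lum_series` (required for `control_referenced`).
#' @param method shift estimator.
#' @param period_h cosinor period (hours).
#' @param transient_h post-event window excluded from the post fit.
#' @param pre_end_h end of the baseline window for `baseline_extrapolation`
#'   (defaults to `event_time_h`; for multi-pulse protocols set it to the
#'   first pulse so the baseline is unperturbed).
#' @return `phase_shift_estimate`: list with `shift_h` in (-12, 12]
#'   (advance positive), `se_h`, `method`, and the underlying fits.
#' @export
estimate_phase_shift <- function(treated, event_time_h, control = NULL,
                                 method = c("baseline_extrapolation",
                                            "control_referenced"),
                                 period_h = 24, transient_h = 12,
                                 pre_end_h = NULL) {
  method <- match.arg(method)
  if (is.null(pre_end_h)) pre_end_h <- event_time_h
  stopifnot(inherits(treated, "lum_series"))
  post_window <- function(s) {
    keep <- s$time_h >= event_time_h + transient_h
    if (sum(keep) < 6 || diff(range(s$time_h[keep])) < 1.0 * period_h)
      stop("insufficient post-event window (need >= 1 cycle after the ",
           transient_h, "-h transient)")
    fit_cosinor_fixed_period(s$signal[keep], period_h = period_h,
                             time_h = s$time_h[keep])
  }
  fit_post <- post_window(treated)
  if (method == "baseline_extrapolation") {
    keep <- treated$time_h < pre_end_h
    if (sum(keep) < 6 || diff(range(treated$time_h[keep])) < 2 * period_h)
      stop("insufficient pre-event window (need >= 2 cycles before the event)")
    fit_pre <- fit_cosinor_fixed_period(treated$signal[keep],
                                        period_h = period_h,
                                        time_h = treated$time_h[keep])
    ref_fit <- fit_pre
  } else {
    if (is.null(control))
      stop("control series required for control_referenced method")
    ref_fit <- post_window(control)
  }
  if (ref_fit$p_zero_amplitude > 0.5 && fit_post$p_zero_amplitude > 0.5)
    stop("no phase defined: both series are non-rhythmic (p > 0.5)")
  shift <- wrap_phase_h(ref_fit$acrophase_h - fit_post$acrophase_h, period_h)
  se <- sqrt(ref_fit$acrophase_se_h^2 + fit_post$acrophase_se_h^2)
  structure(list(shift_h = shift, se_h = se, method = method,
                 reference_fit = ref_fit, post_fit = fit_post),
            class = "phase_shift_estimate")
}

#' @export
print.phase_shift_estimate <- function(x, ...) {
  cat(sprintf("phase shift: %+.2f h (%s; advance positive), se %.2f h\n",
              x$shift_h, x$method, x$se_h))
  invisible(x)
}
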