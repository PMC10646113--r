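#' Build a phase response curve from event-aligned experiments
#'
#' Each experiment supplies the circadian phase at which the stimulus was
#' applied (hours after the reporter peak), the treated trace, the event
#' time, and optionally a parallel control. Per phase, the shift is
#' estimated with [estimate_phase_shift()] and the amplitude response with
#' [amplitude_percent_change()]; failures are flagged in the result, never
#' dropped silently.
#'
#' @param experiments list of lists with fields `phase_h`, `treated`,
#'   `event_time_h`, optional `control`, optional `dose`.
#' @param method passed to [estimate_phase_shift()].
#' @param period_h,transient_h passed to [estimate_phase_shift()].
#' @param stimulus list describing the shared stimulus (kind, dose); stored
#'   as metadata.
#' @return `prc_result`: data.frame `old_phase_h`, `shift_h`,
#'   `amplitude_pct`, `ok`, `note`, sorted by phase.
#' @export
build_prc <- function(experiments, method = "baseline_extrapolation",
                      period_h = 24, transient_h = 12, stimulus = NULL) {
  if (length(experiments) < 4) stop("a PRC needs at least 4 phases")
  rows <- lapply(experiments, function(e) {
    out <- data.frame(old_phase_h = e$phase_h %% period_h,
                      shift_h = NA_real_, amplitude_pct = NA_real_,
                      ok = FALSE, note = "", stringsAsFactors = FALSE)
    sh <- try(estimate_phase_shift(e$treated, e$event_time_h,
                                   control = e$control, method = method,
                                   period_h = period_h,
                                   transient_h = transient_h), silent = TRUE)
    if (inherits(sh, "try-error")) {
      out$note <- paste("shift:", attr(sh, "condition")$message)
      return(out)
    }
    out$shift_h <- sh$shift_h
    amp <- try(amplitude_percent_change(e$treated, e$event_time_h),
               silent = TRUE)
    if (inherits(amp, "try-error"))
      out$note <- paste("amplitude:", attr(amp, "condition")$message)
    else out$amplitude_pct <- amp
    out$ok <- TRUE
    out
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$old_phase_h), , drop = FALSE]
  if (anyDuplicated(res$old_phase_h)) stop("stimulus phases must be unique")
  rownames(res) <- NULL
  structure(res, stimulus = stimulus, period_h = period_h,
            class = c("prc_result", "data.frame"))
}

#' Phase transition curve and winding-number resetting type
#'
#' The PTC maps old phase to new phase = (old + shift) mod period. The new
#' phases are unwrapped over the sorted old phases by shortest-path steps
#' (jumps below half a period); the winding number W is the net number of
#' cycles the new phase makes as the old phase traverses one cycle. W = 1 is
#' type 1 (weak) resetting, W = 0 type 0 (strong) resetting; noisy curves
#' with an unwrap jump of half a period or more are classified undetermined.
#'
#' @param prc a `prc_result` with at least 6 usable phases.
#' @return `ptc_result`: list with data.frame `curve` (`old_phase_h`,
#'   `new_phase_h`), `winding_number`, `resetting_type`, `diagnostics`.
#' @export
build_ptc_classify <- function(prc) {
  period_h <- attr(prc, "period_h")
  if (is.null(period_h)) period_h <- 24
  use <- prc[prc$ok & is.finite(prc$shift_h), , drop = FALSE]
  if (nrow(use) < 6)
    stop("winding determination needs at least 6 usable phases")
  new_phase <- (use$old_phase_h + use$shift_h) %% period_h
  d <- diff(new_phase)
  d <- wrap_phase_h(d, period_h)
  # closing increment back to the first phase, one full cycle of old phase on
  d_close <- wrap_phase_h(new_phase[1] + period_h - new_phase[length(new_phase)],
                          period_h)
  steps <- c(d, d_close)
  half <- period_h / 2
  undet <- any(abs(steps) >= half - 1e-9)
  W <- as.integer(round(sum(steps) / period_h))
  type <- if (undet) "undetermined"
          else if (W == 1L) "type1"
          else if (W == 0L) "type0" else "undetermined"
  structure(list(curve = data.frame(old_phase_h = use$old_phase_h,
                                    new_phase_h = new_phase,
                                    shift_h = use$shift_h),
                 winding_number = W, resetting_type = type,
                 diagnostics = list(steps = steps,
                                    max_abs_step = max(abs(steps)))),
            class = "ptc_result")
}

#' @export
print.ptc_result <- function(x, ...) {
  cat("PTC over", nrow(x$curve), "phases: winding number",
      x$winding_number, "->", x$resetting_type, "\n")
  invisible(x)
}

#' Dose-response table of phase shift and amplitude induction
#'
#' @param experiments list of lists with fields `dose`, `treated`,
#'   `event_time_h`, optional `control`.
#' @param method,period_h,transient_h passed to [estimate_phase_shift()].
#' @return `dose_response_table`: data.frame `dose`, `shift_h`,
#'   `amplitude_pct`, `shift_sd_h` (SD over duplicate doses), `n`; attribute
#'   `concordance` holds the Spearman correlation of |shift| with dose.
#' @export
build_dose_response <- function(experiments, method = "baseline_extrapolation",
                                period_h = 24, transient_h = 12) {
  if (length(experiments) < 3) stop("a dose-response needs >= 3 doses")
  doses <- vapply(experiments, `[[`, numeric(1), "dose")
  if (!any(doses == 0))
    stop("a dose-response table must include dose 0")
  raw <- lapply(experiments, function(e) {
    sh <- estimate_phase_shift(e$treated, e$event_time_h,
                               control = e$control, method = method,
                               period_h = period_h,
                               transient_h = transient_h)
    amp <- try(amplitude_percent_change(e$treated, e$event_time_h),
               silent = TRUE)
    data.frame(dose = e$dose, shift_h = sh$shift_h,
               amplitude_pct = if (inherits(amp, "try-error")) NA_real_
                               else amp)
  })
  raw <- do.call(rbind, raw)
  agg <- do.call(rbind, lapply(split(raw, raw$dose), function(g)
    data.frame(dose = g$dose[1], shift_h = mean(g$shift_h),
               amplitude_pct = mean(g$amplitude_pct),
               shift_sd_h = if (nrow(g) > 1) stats::sd(g$shift_h) else 0,
               n = nrow(g))))
  agg <- agg[order(agg$dose), , drop = FALSE]
  rownames(agg) <- NULL
  conc <- if (nrow(agg) >= 3)
    stats::cor(abs(agg$shift_h), agg$dose, method = "spearman") else NA_real_
  structure(agg, concordance = conc,
            class = c("dose_response_table", "data.frame"))
}
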