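#' Poincare oscillator ensemble parameters
#'
#' Parameter container for the amplitude-phase (Poincare) limit-cycle model
#' used to emulate clock-reporter recordings from skeletal tissue explants and
#' cells. Each cell i carries a radius r_i and phase phi_i evolving as
#' dr/dt = lambda * r * (A0 - r), dphi/dt = 2*pi/tau_i (+ phase diffusion),
#' and is observed as obs_baseline + obs_gain * r*cos(phi) + noise.
#'
#' @param n_cells number of cells in the ensemble.
#' @param tau_h intrinsic circadian period in hours.
#' @param tau_sd_h between-cell SD of the intrinsic period (hours). Drives
#'   desynchronization-damping of the population-mean signal.
#' @param relax_rate radial relaxation rate lambda (per hour).
#' @param limit_radius limit-cycle radius A0 (arbitrary units).
#' @param phase_noise phase diffusion intensity (rad per sqrt hour).
#' @param obs_baseline additive offset of the observable (signal units).
#' @param obs_gain scale from oscillator x-coordinate to signal units.
#' @param obs_noise_sd observation noise SD (signal units).
#' @param init_mode `"synchronized"` (all cells at `phase0_h`) or
#'   `"desynchronized"` (uniform random phases).
#' @param phase0_h initial phase for synchronized ensembles, hours after the
#'   reporter peak (phase 0 = peak of the observable).
#' @param init_radius initial radius; defaults to `limit_radius`.
#' @param dt_h integration step (hours); must be <= 0.1.
#' @param seed RNG seed; every stochastic draw in a simulation derives from it.
#' @return object of class `oscillator_params`.
#' @export
oscillator_params <- function(n_cells = 1000L, tau_h = 24, tau_sd_h = 0.5,
                              relax_rate = 0.5, limit_radius = 1,
                              phase_noise = 0.1, obs_baseline = 150,
                              obs_gain = 100, obs_noise_sd = 2,
                              init_mode = c("synchronized", "desynchronized"),
                              phase0_h = 0, init_radius = limit_radius,
                              dt_h = 0.05, seed = 1L) {
  init_mode <- match.arg(init_mode)
  if (n_cells < 1) stop("n_cells must be >= 1")
  if (tau_h <= 0) stop("tau_h must be > 0")
  if (relax_rate <= 0) stop("relax_rate must be > 0")
  if (limit_radius <= 0) stop("limit_radius must be > 0")
  if (dt_h > 0.1) stop("dt_h must be <= 0.1 for the fixed-step integrator")
  if (tau_sd_h < 0 || phase_noise < 0 || obs_noise_sd < 0)
    stop("noise parameters must be >= 0")
  structure(list(n_cells = as.integer(n_cells), tau_h = tau_h,
                 tau_sd_h = tau_sd_h, relax_rate = relax_rate,
                 limit_radius = limit_radius, phase_noise = phase_noise,
                 obs_baseline = obs_baseline, obs_gain = obs_gain,
                 obs_noise_sd = obs_noise_sd, init_mode = init_mode,
                 phase0_h = phase0_h, init_radius = init_radius,
                 dt_h = dt_h, seed = as.integer(seed)),
            class = "oscillator_params")
}

#' Deterministic single-oscillator parameters
#'
#' Convenience constructor: one cell, no period heterogeneity, no phase
#' diffusion, no observation noise. Used for phase-response geometry,
#' dose calibration and the resetting-type classification.
#'
#' @param phase0_h initial phase (hours after reporter peak).
#' @param ... overrides passed to [oscillator_params()].
#' @return `oscillator_params` object.
#' @export
deterministic_params <- function(phase0_h = 0, ...) {
  args <- list(n_cells = 1L, tau_sd_h = 0, phase_noise = 0, obs_noise_sd = 0,
               init_mode = "synchronized", phase0_h = phase0_h)
  override <- list(...)
  args[names(override)] <- override
  do.call(oscillator_params, args)
}

#' Saturating dose-to-kick calibration
#'
#' Maps a stimulus dose (MPa of compression or mOsm of hyperosmotic challenge)
#' to the magnitude of the Cartesian displacement ("kick") applied to the
#' oscillator state, via the saturating form eps_max * d / (d + half_dose).
#' The kick acts along a fixed direction in the oscillator plane.
#'
#' @param stimulus_kind `"compression_MPa"` or `"osmotic_mOsm"`.
#' @param eps_max maximal kick magnitude (units of `limit_radius`).
#' @param half_dose dose giving half-maximal kick (saturation constant K).
#' @param kick_direction_rad fixed kick direction (radians; 0 points along the
#'   reporter-peak axis).
#' @return object of class `dose_calibration`.
#' @export
dose_calibration <- function(stimulus_kind = c("osmotic_mOsm", "compression_MPa"),
                             eps_max, half_dose, kick_direction_rad) {
  stimulus_kind <- match.arg(stimulus_kind)
  if (eps_max < 0) stop("eps_max must be >= 0")
  if (half_dose <= 0) stop("half_dose must be > 0")
  structure(list(stimulus_kind = stimulus_kind, eps_max = eps_max,
                 half_dose = half_dose,
                 kick_direction_rad = kick_direction_rad),
            class = "dose_calibration")
}

# Calibration constants fitted by grid search / root finding on the
# deterministic pipeline (see analysis/01_calibrate_stimuli.R):
#  - osmotic: a +400 mOsm instantaneous kick at the mid-descending phase
#    produces the maximal phase delay of 9.5 h;
#  - loading: five daily 45-min pulses at the trough phase accumulate a
#    phase advance of 8 h.
.calib_defaults <- new.env(parent = emptyenv())
.calib_defaults$osmotic <- list(eps_max = 1.982670, half_dose = 300,
                                kick_direction_rad = 1.4835299)
.calib_defaults$loading <- list(eps_max = 0.739025, half_dose = 0.25,
                                kick_direction_rad = 0.5235988)

#' Default fitted osmotic calibration
#' @return `dose_calibration` for hyperosmotic stimuli (dose in mOsm above
#'   iso-osmotic baseline).
#' @export
default_osmotic_calibration <- function() {
  d <- .calib_defaults$osmotic
  dose_calibration("osmotic_mOsm", d$eps_max, d$half_dose, d$kick_direction_rad)
}

#' Default fitted mechanical-loading calibration
#' @return `dose_calibration` for compressive loading (dose in MPa).
#' @export
default_loading_calibration <- function() {
  d <- .calib_defaults$loading
  dose_calibration("compression_MPa", d$eps_max, d$half_dose,
                   d$kick_direction_rad)
}

#' Kick magnitude for a stimulus dose
#'
#' @param dose stimulus dose (>= 0), in the units of the calibration.
#' @param calib a [dose_calibration()].
#' @return kick magnitude, bounded above by `eps_max`.
#' @export
dose_to_kick <- function(dose, calib) {
  if (any(dose < 0)) stop("dose must be >= 0")
  calib$eps_max * dose / (dose + calib$half_dose)
}

#' New oscillator phase after an instantaneous kick (closed form)
#'
#' For a cell on the limit cycle at phase `old_phase_h` (hours after peak),
#' an instantaneous Cartesian displacement of magnitude `eps` along
#' `dir_rad` moves the state off the cycle; because radial relaxation does
#' not alter phase in the Poincare model, the asymptotic phase equals the
#' polar angle of the displaced point. Phase at the origin singularity is
#' defined as 0.
#'
#' @param old_phase_h phase at the kick, hours in `[0, period)`.
#' @param eps kick magnitude.
#' @param dir_rad kick direction (radians).
#' @param radius radius at the kick (defaults to the limit radius 1).
#' @param period_h oscillator period (hours).
#' @return new phase in hours, in `[0, period_h)`.
#' @export
kick_phase_map <- function(old_phase_h, eps, dir_rad, radius = 1,
                           period_h = 24) {
  omega <- 2 * pi / period_h
  phi <- -omega * old_phase_h   # observable peaks at polar angle 0, x = cos
  x <- radius * cos(phi) + eps * cos(dir_rad)
  y <- radius * sin(phi) + eps * sin(dir_rad)
  new_phi <- ifelse(x == 0 & y == 0, 0, atan2(y, x))
  (-new_phi / omega) %% period_h
}

# Internal: polar angle convention. Phase hour theta (hours after peak)
# corresponds to polar angle phi = -omega * theta, so that x = r*cos(phi)
# peaks at theta = 0 and the angle advances clockwise as time passes.
.theta_to_phi <- function(theta_h, period_h) -2 * pi * theta_h / period_h

#' Simulate a Poincare oscillator ensemble recording
#'
#' Fixed-step (Euler-Maruyama) integration in polar coordinates with stimulus
#' events applied between steps. Instantaneous events (duration 0) displace
#' the Cartesian state by `dose_to_kick(dose)` along the calibration
#' direction; duration events and square-wave "on" halves apply the same
#' total impulse spread uniformly over their duration as a constant drive.
#'
#' @param params [oscillator_params()].
#' @param schedule a [stimulus_schedule()] or `NULL` for free run.
#' @param calib [dose_calibration()] matching the schedule's stimulus kind
#'   (may be a named list of calibrations keyed by stimulus kind).
#' @param t_end_h simulation end time (hours).
#' @param save_dt_h sampling interval of the returned recording; must be a
#'   multiple of `dt_h`. Default 0.25 h.
#' @return `ensemble_recording`: list with `time_h`, `ensemble_signal`,
#'   `per_cell_signals` (cells x time), and `truth` (per-cell phases in hours
#'   at each save point, intrinsic periods, the schedule).
#' @export
simulate_ensemble <- function(params, schedule = NULL, calib = NULL,
                              t_end_h, save_dt_h = 0.25) {
  stopifnot(inherits(params, "oscillator_params"))
  if (t_end_h <= 0) stop("t_end_h must be > 0")
  dt <- params$dt_h
  thin <- round(save_dt_h / dt)
  if (abs(thin * dt - save_dt_h) > 1e-9) stop("save_dt_h must be a multiple of dt_h")
  events <- if (is.null(schedule)) NULL else schedule$events
  if (!is.null(events) && nrow(events) > 0 && any(events$t_h >= t_end_h))
    stop("all event times must be < t_end_h")
  sq <- if (is.null(schedule)) NULL else schedule$square_wave

  .with_seed(params$seed, {
    n <- params$n_cells
    A0 <- params$limit_radius
    tau_i <- params$tau_h + params$tau_sd_h * stats::rnorm(n)
    tau_i <- pmax(tau_i, params$tau_h / 4)
    omega_i <- 2 * pi / tau_i
    phi <- if (params$init_mode == "synchronized")
      rep(.theta_to_phi(params$phase0_h, params$tau_h), n)
    else stats::runif(n, 0, 2 * pi)
    r <- rep(params$init_radius, n)

    n_steps <- ceiling(t_end_h / dt)
    keep <- seq(1L, n_steps + 1L, by = thin)
    time_h <- (keep - 1L) * dt
    X <- matrix(NA_real_, n, length(keep))
    PH <- matrix(NA_real_, n, length(keep))
    k_out <- 1L
    X[, 1L] <- r * cos(phi)
    PH[, 1L] <- (-phi * params$tau_h / (2 * pi)) %% params$tau_h

    get_calib <- function(kind) {
      if (is.null(calib)) stop("a dose_calibration is required for stimuli")
      if (inherits(calib, "dose_calibration")) {
        if (calib$stimulus_kind != kind)
          stop("calibration kind '", calib$stimulus_kind,
               "' does not match stimulus kind '", kind, "'")
        return(calib)
      }
      cc <- calib[[kind]]
      if (is.null(cc)) stop("no calibration supplied for stimulus kind ", kind)
      cc
    }

    # Pre-resolve event impulses: list of (t_on, t_off, rate, dir, cells)
    drives <- list()
    inst <- list()
    if (!is.null(events) && nrow(events) > 0) {
      for (j in seq_len(nrow(events))) {
        ev <- events[j, ]
        cc <- get_calib(ev$kind)
        eps <- dose_to_kick(ev$dose, cc)
        cells <- attr(events, "cells")[[j]]
        if (is.null(cells)) cells <- seq_len(n)
        if (ev$duration_h <= 0) {
          inst[[length(inst) + 1L]] <- list(t = ev$t_h, eps = eps,
                                            dir = cc$kick_direction_rad,
                                            cells = cells)
        } else {
          drives[[length(drives) + 1L]] <- list(on = ev$t_h,
                                                off = ev$t_h + ev$duration_h,
                                                rate = eps / ev$duration_h,
                                                dir = cc$kick_direction_rad,
                                                cells = cells)
        }
      }
    }
    sq_rate <- 0; sq_dir <- 0
    if (!is.null(sq)) {
      cc <- get_calib(sq$kind)
      on_h <- sq$period_h * sq$on_fraction
      sq_rate <- dose_to_kick(sq$dose, cc) / on_h
      sq_dir <- cc$kick_direction_rad
    }
    inst_t <- vapply(inst, `[[`, numeric(1), "t")

    noise_sd <- params$phase_noise * sqrt(dt)
    lam <- params$relax_rate
    for (s in seq_len(n_steps)) {
      t0 <- (s - 1L) * dt; t1 <- s * dt
      # instantaneous kicks occurring in (t0, t1] applied before the step
      if (length(inst)) {
        hit <- which(inst_t > t0 - 1e-12 & inst_t <= t1 - 1e-12 &
                       inst_t >= t0 - 1e-12)
        for (h in hit) {
          k <- inst[[h]]
          cs <- k$cells
          x <- r[cs] * cos(phi[cs]) + k$eps * cos(k$dir)
          y <- r[cs] * sin(phi[cs]) + k$eps * sin(k$dir)
          r[cs] <- sqrt(x^2 + y^2)
          phi[cs] <- ifelse(r[cs] == 0, 0, atan2(y, x))
          inst_t[h] <- Inf   # fire once
        }
      }
      # constant drives active over this step
      dx <- 0; dy <- 0
      drv <- rep(FALSE, n)
      dxv <- rep(0, n); dyv <- rep(0, n)
      if (length(drives)) {
        for (d in drives) {
          ov <- max(t0, d$on); oe <- min(t1, d$off)
          if (oe > ov) {
            amt <- d$rate * (oe - ov)
            dxv[d$cells] <- dxv[d$cells] + amt * cos(d$dir)
            dyv[d$cells] <- dyv[d$cells] + amt * sin(d$dir)
            drv[d$cells] <- TRUE
          }
        }
      }
      if (!is.null(sq)) {
        stop_h <- if (is.null(sq$stop_h)) Inf else sq$stop_h
        if (t0 < stop_h) {
          ph <- (t0 - sq$phase_offset_h) %% sq$period_h
          if (ph < sq$period_h * sq$on_fraction) {
            dxv <- dxv + sq_rate * dt * cos(sq_dir)
            dyv <- dyv + sq_rate * dt * sin(sq_dir)
            drv[] <- TRUE
          }
        }
      }
      # deterministic polar dynamics + phase diffusion
      r <- r + dt * lam * r * (A0 - r)
      phi <- phi - dt * omega_i
      if (noise_sd > 0) phi <- phi + noise_sd * stats::rnorm(n)
      if (any(drv)) {
        x <- r * cos(phi) + dxv
        y <- r * sin(phi) + dyv
        r <- sqrt(x^2 + y^2)
        phi <- ifelse(r == 0, 0, atan2(y, x))
      }
      if ((s %% thin) == 0L) {
        k_out <- k_out + 1L
        X[, k_out] <- r * cos(phi)
        PH[, k_out] <- (-phi * params$tau_h / (2 * pi)) %% params$tau_h
      }
    }
    obs <- params$obs_baseline + params$obs_gain * X
    if (params$obs_noise_sd > 0)
      obs <- obs + matrix(stats::rnorm(length(obs), 0, params$obs_noise_sd),
                          nrow(obs))
    rownames(obs) <- paste0("cell_", seq_len(n))
    structure(list(time_h = time_h,
                   ensemble_signal = colMeans(obs),
                   per_cell_signals = obs,
                   truth = list(phase_h = PH, tau_i = tau_i,
                                schedule = schedule, params = params)),
              class = "ensemble_recording")
  })
}

#' @export
print.ensemble_recording <- function(x, ...) {
  cat("ensemble_recording:", nrow(x$per_cell_signals), "cells x",
      length(x$time_h), "timepoints, 0 -",
      max(x$time_h), "h\n")
  invisible(x)
}

# Evaluate with a private RNG stream; global .Random.seed is untouched.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
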