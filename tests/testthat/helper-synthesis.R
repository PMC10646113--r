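# Synthetic traces used across tests.

make_cosine_series <- function(t_end = 168, dt = 0.25, period = 24,
                               mesor = 0, amp = 1, acro = 0, noise = 0,
                               trend = 0, damping = 0, seed = 1,
                               trace_id = "synthetic") {
  t <- seq(0, t_end, by = dt)
  y <- mesor + amp * exp(-damping * t) * cos(2 * pi * (t - acro) / period) +
    trend * t
  if (noise > 0) {
    set.seed(seed)
    y <- y + rnorm(length(y), 0, noise)
  }
  lum_series(t, y, trace_id = trace_id)
}

# Cosine whose phase jumps by `shift_h` (advance positive) at `event_time_h`.
make_shifted_series <- function(shift_h, event_time_h = 96, t_end = 192,
                                dt = 0.25, period = 24, noise = 0,
                                seed = 1) {
  t <- seq(0, t_end, by = dt)
  ph <- ifelse(t < event_time_h, t, t + shift_h)
  y <- cos(2 * pi * ph / period)
  if (noise > 0) {
    set.seed(seed)
    y <- y + rnorm(length(y), 0, noise)
  }
  lum_series(t, y, trace_id = "shifted")
}

# deterministic single-oscillator recording with one instantaneous kick
det_kick_recording <- function(eps, dir_rad, phase_h, anchor_peak_h = 96,
                               t_end_h = 216) {
  calib <- dose_calibration("osmotic_mOsm", eps_max = 2 * eps,
                            half_dose = 1, kick_direction_rad = dir_rad)
  sched <- stimulus_schedule(stimulus_event(anchor_peak_h + phase_h, 1,
                                            "osmotic_mOsm"))
  simulate_ensemble(deterministic_params(), sched, calib, t_end_h)
}

# brute-force BH step-up oracle (independent of stats::p.adjust)
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[o[i]] * m / i)
    q[o[i]] <- val
    prev <- val
  }
  q
}
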