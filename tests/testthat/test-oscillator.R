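test_that("dose-to-kick map is saturating, monotone and anchored", {
  calib <- default_osmotic_calibration()
  expect_identical(dose_to_kick(0, calib), 0)
  expect_equal(dose_to_kick(calib$half_dose, calib), calib$eps_max / 2)
  kicks <- dose_to_kick(c(50, 100, 200, 300, 400), calib)
  expect_true(all(diff(kicks) > 0))
  expect_true(all(kicks < calib$eps_max))
  expect_error(dose_to_kick(-1, calib), "dose")
})

test_that("schedule presets encode the study protocols", {
  s <- make_schedule("single_pulse", t_h = 72, dose = 200)
  expect_equal(nrow(s$events), 1L)
  expect_equal(s$events$t_h, 72)

  anti <- make_schedule("antiphase_12_12", days = 3)
  expect_named(anti, c("in_phase", "antiphase"))
  sw <- anti$in_phase$square_wave
  expect_equal(sw$period_h, 24)
  expect_equal(sw$on_fraction, 0.5)
  expect_equal(sw$dose, 0.5)
  expect_equal(anti$antiphase$square_wave$phase_offset_h - sw$phase_offset_h,
               12)
  expect_equal(sw$stop_h, 72)

  tm <- make_schedule("treadmill_in_vivo", ref_peak_h = 0)
  expect_equal(nrow(tm$events), 5L)
  expect_equal(tm$events$duration_h, rep(0.75, 5))
  expect_equal(diff(tm$events$t_h), rep(24, 4))
  expect_equal(tm$events$t_h[1], 12)   # trough category = 12 h after peak

  ps <- make_schedule("phase_series", ref_peak_h = 96, dose = 200)
  expect_equal(vapply(ps, function(x) x$events$t_h, numeric(1)),
               c(peak = 96, mid_descending = 102, trough = 108,
                 mid_ascending = 114))

  expect_error(make_schedule("nope"), "available")
})

test_that("homogeneous noiseless ensemble equals a single oscillator with period tau", {
  par <- oscillator_params(n_cells = 20, tau_sd_h = 0, phase_noise = 0,
                           obs_noise_sd = 0, init_mode = "synchronized")
  rec <- simulate_ensemble(par, NULL, NULL, t_end_h = 96)
  one <- simulate_ensemble(deterministic_params(), NULL, NULL, t_end_h = 96)
  expect_equal(rec$ensemble_signal, one$ensemble_signal, tolerance = 1e-12)
  pk <- detect_peaks(detrend_moving_average(as_lum_series(rec)))
  expect_equal(diff(pk$peak_times_h), rep(24, length(pk$peak_times_h) - 1),
               tolerance = 0.02)
})

test_that("radius converges monotonically to the limit cycle from above and below", {
  for (r0 in c(0.2, 1.7)) {
    par <- deterministic_params(init_radius = r0)
    rec <- simulate_ensemble(par, NULL, NULL, t_end_h = 48)
    # reconstruct radius from the observable and the known phase
    phi <- -2 * pi * rec$truth$phase_h[1, ] / 24
    x <- (rec$per_cell_signals[1, ] - par$obs_baseline) / par$obs_gain
    r <- x / cos(phi)
    ok <- abs(cos(phi)) > 0.3   # avoid division blow-up near zero crossings
    rr <- r[ok]
    if (r0 < 1) expect_true(all(diff(rr) > -1e-6))
    else expect_true(all(diff(rr) < 1e-6))
    expect_equal(rr[length(rr)], 1, tolerance = 1e-3)
  }
})

test_that("desynchronized ensemble envelope decays over successive cycles", {
  par <- oscillator_params(n_cells = 400, init_mode = "synchronized",
                           obs_noise_sd = 0, seed = 3)
  rec <- simulate_ensemble(par, NULL, NULL, t_end_h = 144)
  det <- detrend_moving_average(as_lum_series(rec))
  pk <- detect_peaks(det)
  expect_gte(length(pk$peak_times_h), 4)
  expect_true(all(diff(pk$peak_heights) < 0))
  # decay target of the defaults: below half the first cycle by ~5-6 cycles
  expect_lt(pk$peak_heights[length(pk$peak_heights)],
            0.6 * pk$peak_heights[1])
})

test_that("a vanishing kick leaves the phase unchanged (continuity at eps = 0)", {
  for (eps in c(0.05, 0.01)) {
    shifts <- abs(kick_phase_map(c(3, 9, 15, 21), eps, 0.5) -
                    c(3, 9, 15, 21))
    expect_true(all(pmin(shifts, 24 - shifts) < eps * 24 / (2 * pi) * 1.5))
  }
  expect_equal(kick_phase_map(7, 0, 1.2), 7)
})

test_that("a strong pulse resynchronizes a desynchronized ensemble (amplitude increase)", {
  par <- oscillator_params(n_cells = 400, init_mode = "desynchronized",
                           seed = 9)
  sched <- stimulus_schedule(stimulus_event(120, 400, "osmotic_mOsm"))
  rec <- simulate_ensemble(par, sched, default_osmotic_calibration(),
                           t_end_h = 216)
  det <- detrend_moving_average(as_lum_series(rec))
  expect_gt(amplitude_percent_change(det, 120), 100)
})

test_that("simulations are bit-identical for identical seeds and params", {
  par <- oscillator_params(n_cells = 30, seed = 77)
  sched <- stimulus_schedule(stimulus_event(48, 100, "osmotic_mOsm"))
  r1 <- simulate_ensemble(par, sched, default_osmotic_calibration(), 96)
  r2 <- simulate_ensemble(par, sched, default_osmotic_calibration(), 96)
  expect_identical(r1$ensemble_signal, r2$ensemble_signal)
  expect_identical(r1$per_cell_signals, r2$per_cell_signals)
  r3 <- simulate_ensemble(oscillator_params(n_cells = 30, seed = 78),
                          sched, default_osmotic_calibration(), 96)
  expect_false(identical(r1$ensemble_signal, r3$ensemble_signal))
})

test_that("observable stays nonnegative when the baseline dominates the gain", {
  par <- oscillator_params(n_cells = 50, obs_baseline = 160, obs_gain = 100,
                           obs_noise_sd = 2, seed = 5)
  expect_gte(par$obs_baseline, par$obs_gain * par$limit_radius * 1.5)
  rec <- simulate_ensemble(par, NULL, NULL, t_end_h = 120)
  expect_true(all(rec$per_cell_signals >= 0))
})

test_that("parameter domain violations are rejected", {
  expect_error(oscillator_params(n_cells = 0), "n_cells")
  expect_error(oscillator_params(dt_h = 0.2), "dt_h")
  expect_error(oscillator_params(tau_h = -1), "tau_h")
  expect_error(dose_calibration("osmotic_mOsm", -1, 100, 0), "eps_max")
  expect_error(stimulus_event(-1, 100), "t_h")
  par <- deterministic_params()
  sched <- stimulus_schedule(stimulus_event(100, 10, "osmotic_mOsm"))
  expect_error(simulate_ensemble(par, sched,
                                 default_osmotic_calibration(), 50),
               "event times")
})

test_that("cell population generator books responder truth correctly", {
  pop1 <- simulate_cell_population(responder_fraction = 1)
  expect_true(all(pop1$truth$responder))
  pop0 <- simulate_cell_population(responder_fraction = 0)
  expect_false(any(pop0$truth$responder))
  # seeded binomial draw is reproducible
  p1 <- simulate_cell_population(responder_fraction = 0.66)
  p2 <- simulate_cell_population(responder_fraction = 0.66)
  expect_identical(p1$truth$responder, p2$truth$responder)
  expect_equal(nrow(p1$truth), 78)
})

test_that("count generator honours truth labels and design", {
  exp0 <- simulate_count_timeseries(g_genes = 50, frac_rhythmic = 0,
                                    seed = 2)
  expect_false(any(exp0$truth$rhythmic))
  expect_true(all(exp0$counts >= 0))
  expect_true(all(exp0$counts == round(exp0$counts)))
  expect_equal(sort(unique(exp0$samples$time_h)), seq(0, 48, 4))
  # flat gene: expected counts constant across timepoints up to library size
  exp1 <- simulate_count_timeseries(g_genes = 2000, frac_rhythmic = 0,
                                    frac_responsive = 0, n_reps = 2,
                                    nb_dispersion = 0.05, seed = 3)
  norm <- normalize_counts(exp1$counts)
  hi <- exp1$truth$mesor_log2 > 7   # high-count genes: tight CV
  profile <- tapply(colMeans(norm[hi, ]), exp1$samples$time_h, mean)
  expect_lt(max(profile) - min(profile), 0.05)
})
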