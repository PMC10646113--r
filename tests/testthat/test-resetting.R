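test_that("zero-dose PRC is identically zero within estimator noise", {
  exps <- lapply(c(0, 6, 12, 18), function(ph) {
    rec <- simulate_ensemble(deterministic_params(), NULL, NULL, 216)
    list(phase_h = ph, treated = as_lum_series(rec),
         event_time_h = 96 + ph)
  })
  prc <- build_prc(exps)
  expect_true(all(abs(prc$shift_h) < 0.05))
})

test_that("weak-kick PRC matches the closed-form kick geometry", {
  eps <- 0.3; dir <- default_osmotic_calibration()$kick_direction_rad
  exps <- lapply(c(0, 6, 12, 18), function(ph) {
    rec <- det_kick_recording(eps, dir, ph)
    list(phase_h = ph, treated = as_lum_series(rec),
         event_time_h = 96 + ph)
  })
  prc <- build_prc(exps)
  predicted <- vapply(prc$old_phase_h, function(ph)
    wrap_phase_h(kick_phase_map(ph, eps, dir) - ph), numeric(1))
  expect_equal(prc$shift_h, predicted, tolerance = 0.15)
  # opposite-signed shifts flank the trough
  s6 <- prc$shift_h[prc$old_phase_h == 6]
  s18 <- prc$shift_h[prc$old_phase_h == 18]
  expect_lt(s6 * s18, 0)
})

test_that("a moderate kick at the peak phase inflates the limit-cycle radius", {
  # single cell: the kick's outward radial component at the peak enlarges
  # the orbit before relaxation pulls it back
  dir <- default_osmotic_calibration()$kick_direction_rad
  p <- c(cos(0) + 0.8 * cos(dir), sin(0) + 0.8 * sin(dir))
  expect_gt(sqrt(sum(p^2)), 1)
  # ensemble: the same kick resynchronizes a partially damped population,
  # raising the population-mean amplitude above the pre-stimulus cycle
  par <- oscillator_params(init_mode = "desynchronized", seed = 23,
                           n_cells = 400)
  sched <- stimulus_schedule(stimulus_event(120, 200, "osmotic_mOsm"))
  rec <- simulate_ensemble(par, sched, default_osmotic_calibration(), 216)
  det <- detrend_moving_average(as_lum_series(rec))
  expect_gt(amplitude_percent_change(det, 120), 100)
})

test_that("PTC winding distinguishes identity, complete reset, and kick strengths", {
  mk_prc <- function(shifts, phases = seq(0, 22, 2)) {
    df <- data.frame(old_phase_h = phases, shift_h = shifts,
                     amplitude_pct = NA_real_, ok = TRUE, note = "")
    structure(df, period_h = 24, class = c("prc_result", "data.frame"))
  }
  ident <- build_ptc_classify(mk_prc(rep(0, 12)))
  expect_equal(ident$winding_number, 1L)
  expect_equal(ident$resetting_type, "type1")

  complete <- build_ptc_classify(mk_prc(wrap_phase_h(5 - seq(0, 22, 2))))
  expect_equal(complete$winding_number, 0L)
  expect_equal(complete$resetting_type, "type0")

  expect_error(build_ptc_classify(mk_prc(rep(0, 4), phases = c(0, 6, 12,
                                                               18))),
               "6 usable phases")

  # simulated deterministic PRCs on either side of the kick = A0 transition
  dir <- default_osmotic_calibration()$kick_direction_rad
  for (cfg in list(list(eps = 0.5, type = "type1", W = 1L),
                   list(eps = 1.5, type = "type0", W = 0L))) {
    exps <- lapply(seq(0, 22, 2), function(ph) {
      rec <- det_kick_recording(cfg$eps, dir, ph)
      list(phase_h = ph, treated = as_lum_series(rec),
           event_time_h = 96 + ph)
    })
    ptc <- build_ptc_classify(build_prc(exps))
    expect_equal(ptc$winding_number, cfg$W)
    expect_equal(ptc$resetting_type, cfg$type)
  }
})

test_that("PTC of the closed-form map is continuous and start-phase invariant", {
  dir <- default_osmotic_calibration()$kick_direction_rad
  for (eps in c(0.5, 1.5)) {
    grid <- seq(0, 23.5, 0.5)
    new_phase <- kick_phase_map(grid, eps, dir)
    d <- abs(wrap_phase_h(diff(c(new_phase, new_phase[1]))))
    expect_lt(max(d), 3)
    # winding from the unwrapped steps, from two different starting phases
    W1 <- round(sum(wrap_phase_h(diff(c(new_phase, new_phase[1] + 24)))) /
                  24)
    rolled <- c(new_phase[11:48], new_phase[1:10])
    W2 <- round(sum(wrap_phase_h(diff(c(rolled, rolled[1] + 24)))) / 24)
    expect_equal(W1, W2)
    expect_equal(W1, as.integer(eps < 1))
  }
})

test_that("osmotic dose-response magnitude is monotone under the saturating calibration", {
  osm <- default_osmotic_calibration()
  exps <- lapply(c(0, 50, 100, 200, 300, 400), function(d) {
    sched <- stimulus_schedule(stimulus_event(102, d, "osmotic_mOsm"))
    rec <- simulate_ensemble(deterministic_params(), sched, osm, 216)
    list(dose = d, treated = as_lum_series(rec), event_time_h = 102)
  })
  dr <- build_dose_response(exps)
  expect_equal(dr$shift_h[dr$dose == 0], 0, tolerance = 0.05)
  expect_true(all(diff(abs(dr$shift_h)) > -0.05))
  expect_equal(attr(dr, "concordance"), 1, tolerance = 1e-9)
  # printed endpoint of the calibration: ~9.5 h delay at +400
  expect_equal(dr$shift_h[dr$dose == 400], -9.5, tolerance = 0.1)
  expect_error(build_dose_response(exps[2:4]), "dose 0")
})
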