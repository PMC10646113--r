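test_that("fixed-period cosinor recovers a noiseless synthesis at machine precision", {
  s <- make_cosine_series(t_end = 48, dt = 1, mesor = 5, amp = 3, acro = 6)
  fit <- fit_cosinor_fixed_period(s)
  expect_equal(fit$mesor, 5, tolerance = 1e-10)
  expect_equal(fit$amplitude, 3, tolerance = 1e-10)
  expect_equal(fit$acrophase_h, 6, tolerance = 1e-8)
  expect_lt(fit$p_zero_amplitude, 1e-12)
})

test_that("constant input gives zero amplitude and p = 1", {
  s <- lum_series(seq(0, 48, 2), rep(7, 25))
  fit <- fit_cosinor_fixed_period(s)
  expect_equal(fit$amplitude, 0, tolerance = 1e-12)
  expect_equal(fit$F_stat, 0)
  expect_equal(fit$p_zero_amplitude, 1)
})

test_that("noisy cosine estimates fall within 3 SE of truth", {
  s <- make_cosine_series(t_end = 47, dt = 1, mesor = 5, amp = 3, acro = 6,
                          noise = 3 / 5, seed = 42)
  fit <- fit_cosinor_fixed_period(s)
  se_lin <- 3 / 5 / sqrt(length(s$signal) / 2)   # approx SE of amplitude
  expect_lt(abs(fit$amplitude - 3), 3 * se_lin)
  expect_lt(abs(wrap_phase_h(fit$acrophase_h - 6)), 3 * fit$acrophase_se_h)
  expect_lt(fit$p_zero_amplitude, 1e-6)
})

test_that("cosinor design degeneracies raise errors", {
  expect_error(fit_cosinor_fixed_period(c(1, 2, 3), time_h = c(0, 1, 2)),
               "6 samples")
  expect_error(fit_cosinor_fixed_period(rep(1, 8), time_h = seq(0, 14, 2)),
               "at least one period")
  expect_error(fit_cosinor_fixed_period(rnorm(8), time_h = c(0, 24, 48, 72,
                                                             96, 120, 144,
                                                             168)),
               "rank-deficient")
})

test_that("acrophase is equivariant under time shifts and amplitude under scaling", {
  base <- make_cosine_series(t_end = 96, dt = 0.5, amp = 2, acro = 4,
                             noise = 0.2, seed = 7)
  for (dt in c(3, 8.5, 17)) {
    shifted <- lum_series(base$time_h, base$signal)
    fit0 <- fit_cosinor_fixed_period(base)
    fit1 <- fit_cosinor_fixed_period(shifted, t0_ref = -dt)
    expect_equal(wrap_phase_h(fit1$acrophase_h - (fit0$acrophase_h + dt)),
                 0, tolerance = 1e-8)
  }
  sc <- lum_series(base$time_h, 4.5 * base$signal + 11)
  fit0 <- fit_cosinor_fixed_period(base)
  fit1 <- fit_cosinor_fixed_period(sc)
  expect_equal(fit1$amplitude, 4.5 * fit0$amplitude, tolerance = 1e-9)
  expect_equal(fit1$F_stat, fit0$F_stat, tolerance = 1e-9)
  expect_equal(fit1$acrophase_h, fit0$acrophase_h, tolerance = 1e-9)
})

test_that("damped cosinor recovers its own synthesis and beats a brute grid", {
  s <- make_cosine_series(t_end = 120, dt = 0.5, mesor = 20, amp = 100,
                          acro = 5, damping = 0.01)
  fit <- fit_damped_cosinor(s)
  expect_equal(fit$period_h, 24, tolerance = 24 * 5e-4)
  expect_equal(fit$damping_rate, 0.01, tolerance = 0.01 * 5e-3)
  expect_equal(fit$amplitude, 100, tolerance = 0.5)
  expect_equal(fit$acrophase_h, 5, tolerance = 0.01)

  und <- make_cosine_series(t_end = 120, dt = 0.5, amp = 10)
  expect_lt(abs(fit_damped_cosinor(und)$damping_rate), 1e-4)

  noisy <- make_cosine_series(t_end = 120, dt = 0.5, amp = 50,
                              damping = 0.008, noise = 5, seed = 12)
  fit <- fit_damped_cosinor(noisy)
  grid <- expand.grid(period = seq(18, 30, 0.05), d = seq(0, 0.05, 0.005))
  grss <- mapply(function(p, d)
    skeletime:::.damped_rss(noisy$time_h, noisy$signal, p, d)$rss,
    grid$period, grid$d)
  expect_lte(fit$rss, min(grss) + 1e-9)
})

test_that("period estimators agree and recover ensemble periods", {
  s <- make_cosine_series(t_end = 120, dt = 0.25)
  pp <- estimate_period(s, method = "peak_to_peak")
  expect_equal(pp$period_h, 24, tolerance = 1e-6)
  expect_equal(pp$se_h, 0, tolerance = 1e-6)
  dc <- estimate_period(s, method = "damped_cosinor")
  expect_lt(abs(dc$period_h - pp$period_h), 0.2)

  par <- oscillator_params(tau_h = 25.5, seed = 21, n_cells = 400)
  rec <- simulate_ensemble(par, NULL, NULL, t_end_h = 144)
  est <- estimate_period(detrend_moving_average(as_lum_series(rec)),
                         period_bounds = c(18, 30))
  expect_lt(abs(est$period_h - 25.5), 0.5)

  expect_error(estimate_period(make_cosine_series(t_end = 40, dt = 0.5),
                               method = "peak_to_peak"), "3 peaks")
})

test_that("permutation rhythmicity test is anchored and calibrated", {
  s <- make_cosine_series(t_end = 48, dt = 4, amp = 3)
  rt <- rhythmicity_test(s, n_perm = 500, seed = 4)
  expect_equal(rt$p_permutation, 1 / 501)

  # parametric and permutation p agree within a factor of 3 on noisy cosines
  for (sd in c(1, 2)) {
    s <- make_cosine_series(t_end = 48, dt = 2, amp = 1.5, noise = sd,
                            seed = 30 + sd)
    rt <- rhythmicity_test(s, n_perm = 2000, seed = 9)
    if (rt$p_parametric > 5e-4) {
      ratio <- rt$p_permutation / rt$p_parametric
      expect_gt(ratio, 1 / 3)
      expect_lt(ratio, 3)
    }
  }
  expect_error(rhythmicity_test(make_cosine_series(t_end = 12, dt = 2)),
               "8 observations")
})

test_that("null profiles give calibrated parametric p-values", {
  set.seed(11)
  tt <- rep(seq(0, 48, 4), each = 2)
  Y <- matrix(rnorm(length(tt) * 1000), nrow = length(tt))
  Fs <- skeletime:::.cosinor_F_matrix(tt, Y)$F
  p <- stats::pf(Fs, 2, length(tt) - 3, lower.tail = FALSE)
  # binomial 95% envelope around 5% for 1000 null genes
  expect_lte(mean(p < 0.05), 0.07)
  expect_gte(mean(p < 0.05), 0.03)
})
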