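#' Fixed-period cosinor fit
#'
#' Least-squares fit of M + A*cos(2*pi*(t - phi_a)/period) via the linear
#' sine/cosine parameterisation. Rhythmicity is assessed with the
#' zero-amplitude F test against the intercept-only model on (2, n - 3)
#' degrees of freedom.
#'
#' @param series a `lum_series`, or a numeric signal when `time_h` is given.
#' @param period_h fixed period (hours).
#' @param t0_ref reference time; the acrophase is reported as hours after
#'   `t0_ref` at which the fitted curve peaks, in `[0, period_h)`.
#' @param time_h time grid when `series` is a bare numeric vector.
#' @return object of class `cosinor_fit`: `mesor`, `amplitude`,
#'   `acrophase_h`, `period_h`, `rss`, `r2`, `p_zero_amplitude`, `F_stat`,
#'   `n`, `acrophase_se_h`.
#' @export
fit_cosinor_fixed_period <- function(series, period_h = 24, t0_ref = 0,
                                     time_h = NULL) {
  if (inherits(series, "lum_series")) {
    t <- series$time_h; y <- series$signal
  } else {
    t <- time_h; y <- as.numeric(series)
    if (is.null(t)) stop("time_h required when series is a numeric vector")
  }
  n <- length(y)
  if (n < 6) stop("cosinor fit needs at least 6 samples")
  if (diff(range(t)) < period_h)
    stop("samples must span at least one period")
  om <- 2 * pi / period_h
  ts <- t - t0_ref
  X <- cbind(1, cos(om * ts), sin(om * ts))
  qx <- qr(X)
  if (qx$rank < 3)
    stop("rank-deficient cosinor design (all samples at one phase?)")
  cf <- qr.coef(qx, y)
  fitted <- drop(X %*% cf)
  rss <- sum((y - fitted)^2)
  tss <- sum((y - mean(y))^2)
  A <- sqrt(cf[2]^2 + cf[3]^2)
  # peak where cos(om*t - psi) = 1, psi = atan2(b_sin, b_cos)
  acro <- (atan2(cf[3], cf[2]) / om) %% period_h
  F_stat <- if (tss <= 0 || rss <= 0 && tss <= 0) 0
            else ((tss - rss) / 2) / (rss / (n - 3))
  if (!is.finite(F_stat)) F_stat <- if (tss > rss) Inf else 0
  p <- stats::pf(F_stat, 2, n - 3, lower.tail = FALSE)
  sigma2 <- rss / (n - 3)
  XtXinv <- chol2inv(qr.R(qx))
  # delta-method SE of the acrophase (hours)
  g <- c(0, -cf[3], cf[2]) / max(A^2, .Machine$double.eps)
  acro_se <- sqrt(drop(crossprod(g, (sigma2 * XtXinv) %*% g))) / om
  structure(list(mesor = unname(cf[1]), amplitude = unname(A),
                 acrophase_h = unname(acro), period_h = period_h,
                 rss = rss, r2 = if (tss > 0) 1 - rss / tss else 0,
                 p_zero_amplitude = unname(p), F_stat = unname(F_stat),
                 n = n, acrophase_se_h = unname(acro_se),
                 coef = unname(cf), t0_ref = t0_ref),
            class = "cosinor_fit")
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cat(sprintf(
    "cosinor fit (period %.2f h): mesor %.3g, amplitude %.3g, acrophase %.2f h, p(zero amplitude) %.3g\n",
    x$period_h, x$mesor, x$amplitude, x$acrophase_h, x$p_zero_amplitude))
  invisible(x)
}

# Profiled linear least squares for an exponentially damped cosinor at
# fixed (period, damping): y ~ 1 + e^{-d t} cos(om t) + e^{-d t} sin(om t).
.damped_rss <- function(t, y, period_h, d) {
  om <- 2 * pi / period_h
  env <- exp(-d * (t - min(t)))
  X <- cbind(1, env * cos(om * t), env * sin(om * t))
  fit <- stats::lm.fit(X, y)
  list(rss = sum(fit$residuals^2), coef = fit$coefficients, env0 = env)
}

#' Damped cosinor fit
#'
#' Nonlinear least squares of M + A*exp(-d*(t - t_min))*cos(2*pi*(t -
#' phi_a)/period) with multi-start initialisation over a 1-h period grid in
#' `period_bounds` crossed with a damping grid, followed by Nelder-Mead
#' refinement of (period, damping) with the linear parameters profiled out.
#' Ties on equal rss are broken towards smaller damping, then the period
#' closer to 24 h.
#'
#' @param series a `lum_series` covering at least 2 full cycles, or a numeric
#'   signal with `time_h`.
#' @param period_bounds search bounds for the period (hours).
#' @param damping_grid starting values for the damping rate (per hour).
#' @param time_h time grid when `series` is a numeric vector.
#' @return `damped_cosinor_fit`: cosinor fields plus `damping_rate` and
#'   `period_se_h` (asymptotic, from the numerical curvature of the profiled
#'   rss).
#' @export
fit_damped_cosinor <- function(series, period_bounds = c(18, 30),
                               damping_grid = c(0, 0.005, 0.01, 0.02, 0.05),
                               time_h = NULL) {
  if (inherits(series, "lum_series")) {
    t <- series$time_h; y <- series$signal
  } else {
    t <- time_h; y <- as.numeric(series)
  }
  if (diff(range(t)) < 2 * period_bounds[1])
    stop("damped cosinor needs at least 2 full cycles of data")
  starts <- expand.grid(period = seq(period_bounds[1], period_bounds[2], 1),
                        d = damping_grid)
  rss0 <- mapply(function(p, d) .damped_rss(t, y, p, d)$rss,
                 starts$period, starts$d)
  diag <- data.frame(starts, rss = rss0)
  best <- NULL
  ord <- order(rss0)[seq_len(min(3L, length(rss0)))]
  for (i in ord) {
    opt <- try(stats::optim(c(starts$period[i], starts$d[i]), function(par) {
      if (par[1] < period_bounds[1] || par[1] > period_bounds[2]) return(Inf)
      .damped_rss(t, y, par[1], par[2])$rss
    }, method = "Nelder-Mead",
    control = list(reltol = 1e-12, maxit = 2000)), silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) ||
        opt$value < best$value - 1e-12 ||
        (abs(opt$value - best$value) <= 1e-12 &&
           (abs(opt$par[2]) < abs(best$par[2]) - 1e-12 ||
              (abs(opt$par[2] - best$par[2]) <= 1e-12 &&
                 abs(opt$par[1] - 24) < abs(best$par[1] - 24)))))
      best <- opt
  }
  if (is.null(best)) {
    cond <- structure(class = c("skeletime_fit_error", "error", "condition"),
                      list(message = "no damped-cosinor start converged",
                           call = sys.call(), diagnostics = diag))
    stop(cond)
  }
  period <- best$par[1]; d <- best$par[2]
  ls <- .damped_rss(t, y, period, d)
  cf <- ls$coef
  om <- 2 * pi / period
  A <- sqrt(cf[2]^2 + cf[3]^2)
  acro <- (atan2(cf[3], cf[2]) / om) %% period
  n <- length(y)
  sigma2 <- ls$rss / max(n - 5, 1)
  h <- 0.05
  f <- function(p) .damped_rss(t, y, p, d)$rss
  curv <- (f(period + h) - 2 * ls$rss + f(period - h)) / h^2
  period_se <- if (is.finite(curv) && curv > 0) sqrt(2 * sigma2 / curv)
               else NA_real_
  structure(list(mesor = unname(cf[1]), amplitude = unname(A),
                 acrophase_h = unname(acro), period_h = period,
                 damping_rate = d, rss = ls$rss,
                 r2 = 1 - ls$rss / sum((y - mean(y))^2),
                 n = n, period_se_h = period_se,
                 start_diagnostics = diag),
            class = c("damped_cosinor_fit", "cosinor_fit"))
}

#' Estimate the circadian period of a trace
#'
#' @param series a detrended `lum_series`.
#' @param method `"damped_cosinor"` (fitted period and asymptotic SE) or
#'   `"peak_to_peak"` (mean and SD of successive peak intervals; needs >= 3
#'   detectable peaks).
#' @param period_bounds passed to [fit_damped_cosinor()].
#' @param ... passed to [detect_peaks()] for `peak_to_peak`.
#' @return list with `period_h`, `se_h`, `method`.
#' @export
estimate_period <- function(series, method = c("damped_cosinor",
                                               "peak_to_peak"),
                            period_bounds = c(18, 30), ...) {
  method <- match.arg(method)
  if (method == "damped_cosinor") {
    fit <- fit_damped_cosinor(series, period_bounds)
    list(period_h = fit$period_h, se_h = fit$period_se_h,
         method = method, fit = fit)
  } else {
    pk <- detect_peaks(series, ...)
    if (length(pk$peak_times_h) < 3)
      stop("peak_to_peak period estimation needs at least 3 peaks")
    iv <- diff(pk$peak_times_h)
    list(period_h = mean(iv), se_h = stats::sd(iv), method = method,
         intervals = iv)
  }
}

# Vectorised zero-amplitude F statistics for profiles in the columns of Y.
.cosinor_F_matrix <- function(time_h, Y, period_h = 24) {
  om <- 2 * pi / period_h
  X <- cbind(1, cos(om * time_h), sin(om * time_h))
  qx <- qr(X)
  n <- nrow(Y)
  res <- qr.resid(qx, Y)
  rss <- colSums(res^2)
  tss <- colSums(scale(Y, scale = FALSE)^2)
  Fs <- ((tss - rss) / 2) / (rss / (n - 3))
  Fs[!is.finite(Fs)] <- 0
  Fs[tss <= 0] <- 0
  cf <- qr.coef(qx, Y)
  list(F = Fs, rss = rss, tss = tss,
       mesor = cf[1, ], amplitude = sqrt(cf[2, ]^2 + cf[3, ]^2),
       acrophase_h = (atan2(cf[3, ], cf[2, ]) / om) %% period_h)
}

#' Rhythmicity test (parametric and permutation)
#'
#' The zero-amplitude cosinor F test plus a time-label permutation test on
#' the same F statistic, with add-one correction (b + 1)/(n_perm + 1).
#'
#' @param series a `lum_series`, or a numeric profile with `time_h`.
#' @param period_h test period (hours).
#' @param n_perm number of permutations (values below 100 are accepted with
#'   a message; 0 skips the permutation test).
#' @param seed RNG seed for the permutations.
#' @param time_h time grid when `series` is a numeric vector.
#' @return list with `p_parametric`, `p_permutation`, `F_stat`, `fit`.
#' @export
rhythmicity_test <- function(series, period_h = 24, n_perm = 1000, seed = 1L,
                             time_h = NULL) {
  if (inherits(series, "lum_series")) {
    t <- series$time_h; y <- series$signal
  } else {
    t <- time_h; y <- as.numeric(series)
  }
  if (length(y) < 8) stop("rhythmicity test needs at least 8 observations")
  fit <- fit_cosinor_fixed_period(y, period_h = period_h, time_h = t)
  p_perm <- NA_real_
  if (n_perm > 0) {
    if (n_perm < 100)
      message("n_perm = ", n_perm, " is low; permutation p will be coarse")
    Fobs <- fit$F_stat
    Fperm <- .with_seed(seed, {
      P <- vapply(seq_len(n_perm), function(i) sample(y), numeric(length(y)))
      .cosinor_F_matrix(t, P, period_h)$F
    })
    p_perm <- (sum(Fperm >= Fobs) + 1) / (n_perm + 1)
  }
  list(p_parametric = fit$p_zero_amplitude, p_permutation = p_perm,
       F_stat = fit$F_stat, fit = fit)
}
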