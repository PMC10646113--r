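#' Luminescence/fluorescence time series
#'
#' One recorded trace: a strictly increasing time grid in hours plus the
#' signal, with free-form metadata (tissue, condition, dose, ...).
#'
#' @param time_h time grid (hours), strictly increasing, no missing values.
#' @param signal numeric signal of the same length.
#' @param trace_id trace label.
#' @param meta named list of metadata.
#' @return object of class `lum_series`.
#' @export
lum_series <- function(time_h, signal, trace_id = "trace", meta = list()) {
  if (anyNA(time_h)) stop("time_h must not contain missing values")
  if (length(time_h) != length(signal))
    stop("time_h and signal lengths differ")
  if (length(time_h) < 2) stop("a series needs at least 2 samples")
  d <- diff(time_h)
  if (any(d <= 0))
    stop("time_h must be strictly increasing; first offending row: ",
         which(d <= 0)[1] + 1L)
  structure(list(time_h = as.numeric(time_h), signal = as.numeric(signal),
                 trace_id = trace_id, meta = meta), class = "lum_series")
}

#' @export
print.lum_series <- function(x, ...) {
  cat("lum_series '", x$trace_id, "': ", length(x$time_h), " samples, ",
      min(x$time_h), " - ", max(x$time_h), " h\n", sep = "")
  invisible(x)
}

#' Extract the ensemble-mean trace of a recording as a `lum_series`
#' @param rec an `ensemble_recording`.
#' @param trace_id label for the extracted trace.
#' @return `lum_series`.
#' @export
as_lum_series <- function(rec, trace_id = "ensemble") {
  stopifnot(inherits(rec, "ensemble_recording"))
  lum_series(rec$time_h, rec$ensemble_signal, trace_id)
}

.is_uniform <- function(time_h, tol = 1e-6) {
  d <- diff(time_h)
  diff(range(d)) <= tol * stats::median(d)
}

#' Write traces to a wide CSV
#'
#' Column 1 is `time_h`, one column per trace; metadata are written as
#' `# key: value` header lines. UTF-8, "." decimal separator, 12 significant
#' digits.
#'
#' @param series a `lum_series`, a list of them (sharing one grid), an
#'   `ensemble_recording`, or a `cell_trajectory_set`.
#' @param path output file.
#' @param meta named list written as `#` header lines.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path, meta = list()) {
  if (inherits(series, "lum_series")) series <- list(series)
  if (inherits(series, "ensemble_recording")) {
    m <- cbind(time_h = series$time_h, ensemble = series$ensemble_signal,
               t(series$per_cell_signals))
  } else if (inherits(series, "cell_trajectory_set")) {
    m <- cbind(time_h = series$time_h, t(series$signals))
  } else {
    tt <- series[[1]]$time_h
    for (s in series)
      if (!isTRUE(all.equal(s$time_h, tt)))
        stop("all series must share one time grid to be written wide")
    m <- cbind(time_h = tt,
               sapply(series, `[[`, "signal"))
    colnames(m) <- c("time_h", vapply(series, `[[`, character(1), "trace_id"))
  }
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("# %s: %s", k, meta[[k]]), con)
  writeLines(paste(colnames(m), collapse = ","), con)
  writeLines(apply(m, 1, function(r)
    paste(formatC(r, digits = 12, format = "g"), collapse = ",")), con)
  invisible(path)
}

#' Read a wide CSV of traces
#'
#' @param path file whose first column is `time_h`; optional `#`-prefixed
#'   `key: value` header lines become shared metadata.
#' @return list of `lum_series`, one per non-time column.
#' @export
read_series_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  is_meta <- grepl("^#", lines)
  meta <- list()
  for (l in sub("^#\\s*", "", lines[is_meta])) {
    kv <- strsplit(l, ":\\s*")[[1]]
    if (length(kv) >= 2) meta[[kv[1]]] <- paste(kv[-1], collapse = ": ")
  }
  df <- utils::read.csv(text = paste(lines[!is_meta], collapse = "\n"),
                        check.names = FALSE)
  if (names(df)[1] != "time_h") stop("first column must be 'time_h'")
  for (j in seq_along(df)) {
    bad <- which(is.na(suppressWarnings(as.numeric(as.character(df[[j]])))) &
                   !is.na(df[[j]]))
    if (!is.numeric(df[[j]]))
      stop("non-numeric cell in column '", names(df)[j], "', row ",
           if (length(bad)) bad[1] else NA)
  }
  tt <- df[[1]]
  d <- diff(tt)
  if (any(d <= 0))
    stop("time_h not strictly increasing; first offending row: ",
         which(d <= 0)[1] + 1L)
  lapply(names(df)[-1], function(nm)
    lum_series(tt, df[[nm]], trace_id = nm, meta = meta))
}

#' Detrend a series with a centred moving average
#'
#' Removes the slow trend by subtracting (or dividing by) the centred moving
#' average of width `window_h`; the half-window at each edge is trimmed, not
#' padded. With the default 24-h window the output averages ~0 over any full
#' circadian cycle.
#'
#' @param series a `lum_series` with uniform sampling spanning at least
#'   `window_h`.
#' @param window_h moving-average window (hours).
#' @param mode `"subtract"` (default; keeps amplitude in signal units) or
#'   `"divide"`.
#' @return detrended `lum_series` (shorter by one window).
#' @export
detrend_moving_average <- function(series, window_h = 24,
                                   mode = c("subtract", "divide")) {
  mode <- match.arg(mode)
  stopifnot(inherits(series, "lum_series"))
  span <- diff(range(series$time_h))
  if (span < window_h)
    stop("series duration (", span, " h) is shorter than the window (",
         window_h, " h)")
  if (!.is_uniform(series$time_h))
    stop("series must be uniformly sampled; resample_uniform() first")
  dt <- series$time_h[2] - series$time_h[1]
  k <- round(window_h / dt)
  if (abs(k * dt - window_h) < 1e-8 && k %% 2 == 0) {
    # grid divides the window: trapezoidal weights span exactly window_h,
    # so any pure cycle of that period averages to zero (periodic trapezoid
    # rule is exact) and detrending leaves it untouched
    w <- c(0.5, rep(1, k - 1), 0.5) / k
  } else {
    if (k %% 2 == 0) k <- k + 1L
    w <- rep(1 / k, k)
  }
  ma <- as.numeric(stats::filter(series$signal, w, sides = 2))
  keep <- !is.na(ma)
  out <- if (mode == "subtract") series$signal[keep] - ma[keep]
         else series$signal[keep] / ma[keep]
  lum_series(series$time_h[keep], out, trace_id = series$trace_id,
             meta = c(series$meta, list(detrend = mode)))
}

#' Resample a series onto a uniform grid by linear interpolation
#'
#' @param series a `lum_series`.
#' @param dt_h target sampling interval (hours).
#' @return resampled `lum_series` spanning the original range.
#' @export
resample_uniform <- function(series, dt_h) {
  stopifnot(inherits(series, "lum_series"))
  if (dt_h <= 0) stop("dt_h must be > 0")
  span <- diff(range(series$time_h))
  if (dt_h > span / 2) stop("dt_h larger than half the series duration")
  grid <- seq(min(series$time_h), max(series$time_h), by = dt_h)
  y <- stats::approx(series$time_h, series$signal, xout = grid)$y
  lum_series(grid, y, trace_id = series$trace_id, meta = series$meta)
}
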