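#' Normalize single-cell reporter trajectories
#'
#' `auc` mode divides each trajectory by its trapezoidal area under the curve
#' over the first `auc_window_h` hours divided by `auc_window_h` (so a
#' constant trajectory becomes 1); `zscore` mode centres and scales each
#' trajectory to mean 0, SD 1 over its full length. Cells with AUC <= 0 are
#' excluded and reported.
#'
#' @param cells matrix (cells x time) of trajectories.
#' @param time_h time grid (hours) covering `[0, auc_window_h]`.
#' @param auc_window_h normalisation window for `auc` mode (hours).
#' @param mode `"auc"` or `"zscore"`.
#' @return normalised matrix; attribute `excluded` is a data.frame
#'   (`cell_id`, `reason`) of dropped cells.
#' @export
normalize_trajectories <- function(cells, time_h, auc_window_h = 48,
                                   mode = c("auc", "zscore")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(cells), ncol(cells) == length(time_h))
  if (max(time_h) < auc_window_h && mode == "auc")
    stop("trajectories must cover [0, ", auc_window_h, "] h")
  ids <- rownames(cells)
  if (is.null(ids)) ids <- paste0("cell_", seq_len(nrow(cells)))
  if (mode == "zscore") {
    out <- t(scale(t(cells)))
    attr(out, "excluded") <- data.frame(cell_id = character(0),
                                        reason = character(0))
    dimnames(out) <- list(ids, colnames(cells))
    return(out)
  }
  w <- time_h <= auc_window_h + 1e-9
  tw <- time_h[w]
  auc <- apply(cells[, w, drop = FALSE], 1, function(y)
    sum(diff(tw) * (y[-1] + y[-length(y)]) / 2))
  bad <- auc <= 0
  out <- cells[!bad, , drop = FALSE] / (auc[!bad] / auc_window_h)
  rownames(out) <- ids[!bad]
  attr(out, "excluded") <- data.frame(cell_id = ids[bad],
                                      reason = rep("AUC <= 0", sum(bad)),
                                      stringsAsFactors = FALSE)
  out
}

#' Classify one cell as responding to the stimulus
#'
#' Applies the study's rule: a cell responds if the amplitude (detrended
#' height) of the peak following treatment is strictly higher than that of
#' the peak preceding it. The pre-treatment reference is the highest peak in
#' `(treat_time_h - search_window_h, treat_time_h]` (`pre_rule = "highest"`,
#' robust to shoulder artifacts) or the last one (`pre_rule = "last"`); the
#' post peak is the first peak in `(treat_time_h, treat_time_h +
#' search_window_h]`.
#'
#' @param traj detrended `lum_series` for one cell.
#' @param treat_time_h treatment time (hours), inside the recording.
#' @param search_window_h window searched on each side of the treatment.
#' @param pre_rule pre-treatment reference peak rule.
#' @param ... passed to [detect_peaks()].
#' @return `responder_call`: list with `cell_id`, `pre_peak`, `post_peak`,
#'   `responder` (logical, NA when undefined), `reason`.
#' @export
classify_responder <- function(traj, treat_time_h, search_window_h = 30,
                               pre_rule = c("highest", "last"), ...) {
  pre_rule <- match.arg(pre_rule)
  stopifnot(inherits(traj, "lum_series"))
  if (treat_time_h < min(traj$time_h) || treat_time_h > max(traj$time_h))
    stop("treat_time_h outside the recording")
  pk <- detect_peaks(traj, ...)
  pre_i <- which(pk$peak_times_h > treat_time_h - search_window_h &
                   pk$peak_times_h <= treat_time_h)
  post_i <- which(pk$peak_times_h > treat_time_h &
                    pk$peak_times_h <= treat_time_h + search_window_h)
  call <- list(cell_id = traj$trace_id, pre_peak = NULL, post_peak = NULL,
               responder = NA, reason = "")
  if (!length(pre_i)) {
    call$reason <- "no pre-treatment peak in window"
  } else if (!length(post_i)) {
    call$reason <- "no post-treatment peak in window"
  }
  if (length(pre_i)) {
    i <- if (pre_rule == "highest") pre_i[which.max(pk$peak_heights[pre_i])]
         else pre_i[length(pre_i)]
    call$pre_peak <- c(time_h = pk$peak_times_h[i],
                       height = pk$peak_heights[i])
  }
  if (length(post_i)) {
    i <- post_i[1]
    call$post_peak <- c(time_h = pk$peak_times_h[i],
                        height = pk$peak_heights[i])
  }
  if (!is.null(call$pre_peak) && !is.null(call$post_peak))
    call$responder <- unname(call$post_peak["height"] >
                               call$pre_peak["height"])
  structure(call, class = "responder_call")
}

#' Classify every cell of a trajectory set
#'
#' Detrends each trajectory with the 24-h moving average, then applies
#' [classify_responder()].
#'
#' @param cells a `cell_trajectory_set` (or matrix with `time_h`).
#' @param treat_time_h treatment time; defaults to the set's own.
#' @param time_h grid when `cells` is a matrix.
#' @param ... passed to [classify_responder()].
#' @return data.frame of calls: `cell_id`, `pre_time_h`, `pre_height`,
#'   `post_time_h`, `post_height`, `responder`, `reason`.
#' @export
classify_population <- function(cells, treat_time_h = NULL, time_h = NULL,
                                ...) {
  if (inherits(cells, "cell_trajectory_set")) {
    if (is.null(treat_time_h)) treat_time_h <- cells$treat_time_h
    time_h <- cells$time_h
    mat <- cells$signals
  } else mat <- cells
  if (is.null(treat_time_h)) stop("treat_time_h required")
  ids <- rownames(mat)
  rows <- lapply(seq_len(nrow(mat)), function(i) {
    s <- detrend_moving_average(lum_series(time_h, mat[i, ],
                                           trace_id = ids[i]))
    cl <- classify_responder(s, treat_time_h, ...)
    data.frame(cell_id = cl$cell_id,
               pre_time_h = if (is.null(cl$pre_peak)) NA_real_
                            else cl$pre_peak[["time_h"]],
               pre_height = if (is.null(cl$pre_peak)) NA_real_
                            else cl$pre_peak[["height"]],
               post_time_h = if (is.null(cl$post_peak)) NA_real_
                             else cl$post_peak[["time_h"]],
               post_height = if (is.null(cl$post_peak)) NA_real_
                             else cl$post_peak[["height"]],
               responder = cl$responder, reason = cl$reason,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Responder fraction with exact binomial confidence interval
#'
#' @param calls data.frame from [classify_population()] (or any data.frame
#'   with a logical `responder` column; NA = undefined call).
#' @param conf_level confidence level of the Clopper-Pearson interval.
#' @return list with `percent`, `ci_percent` (length 2), `n_responders`,
#'   `n_defined`, `n_undefined`.
#' @export
responder_fraction <- function(calls, conf_level = 0.95) {
  r <- calls$responder
  defined <- !is.na(r)
  if (!any(defined)) stop("no defined responder calls")
  k <- sum(r[defined]); n <- sum(defined)
  bt <- stats::binom.test(k, n, conf.level = conf_level)
  list(percent = 100 * k / n,
       ci_percent = 100 * as.numeric(bt$conf.int),
       n_responders = k, n_defined = n, n_undefined = sum(!defined))
}
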