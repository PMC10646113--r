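#' Simulate single-cell reporter trajectories with responder ground truth
#'
#' Emulates fluorescence imaging of clock-unsynchronized primary cells: cells
#' start desynchronized on a low-amplitude decaying orbit (the residual
#' oscillation of an unsynchronized culture), and a randomly drawn fraction
#' of "responder" cells receives the calibrated stimulus kick at
#' `treat_time_h`, re-inflating their oscillation amplitude. Non-responders
#' continue to damp, so the peak after treatment is lower than the peak
#' before it.
#'
#' @param params [oscillator_params()]; the defaults here override the
#'   explant defaults with a low-amplitude unsynchronized regime
#'   (`limit_radius = 0.15`, `init_radius = 0.35`, `relax_rate = 0.1`,
#'   desynchronized phases, `n_cells = 78`).
#' @param treat_time_h stimulus time (0 < treat_time_h < t_end_h).
#' @param responder_fraction probability that a cell responds (receives the
#'   kick).
#' @param t_end_h recording length (hours).
#' @param dose,calib stimulus dose and calibration (default +200 mOsm under
#'   the fitted osmotic calibration).
#' @return `cell_trajectory_set`: list with `time_h`, `signals` (cells x
#'   time), and `truth` data.frame (`cell_id`, `responder`).
#' @export
simulate_cell_population <- function(params = NULL, treat_time_h = 48,
                                     responder_fraction = 0.66,
                                     t_end_h = 96, dose = 200,
                                     calib = default_osmotic_calibration()) {
  if (is.null(params))
    params <- oscillator_params(n_cells = 78L, limit_radius = 0.15,
                                init_radius = 0.35, relax_rate = 0.1,
                                init_mode = "desynchronized",
                                phase_noise = 0.05, obs_baseline = 60,
                                obs_gain = 100, obs_noise_sd = 1)
  if (treat_time_h <= 0 || treat_time_h >= t_end_h)
    stop("treat_time_h must lie inside (0, t_end_h)")
  if (responder_fraction < 0 || responder_fraction > 1)
    stop("responder_fraction must be in [0, 1]")
  responders <- .with_seed(params$seed + 1000003L,
                           stats::rbinom(params$n_cells, 1L,
                                         responder_fraction) == 1L)
  ev <- stimulus_event(treat_time_h, dose, calib$stimulus_kind, 0)
  attr(ev, "cells") <- list(which(responders))
  sched <- stimulus_schedule(ev)
  rec <- simulate_ensemble(params, sched, calib, t_end_h)
  structure(list(time_h = rec$time_h, signals = rec$per_cell_signals,
                 truth = data.frame(cell_id = rownames(rec$per_cell_signals),
                                    responder = responders,
                                    stringsAsFactors = FALSE),
                 treat_time_h = treat_time_h, params = params),
            class = "cell_trajectory_set")
}

#' Simulate a rhythmic negative-binomial count time series
#'
#' Emulates the study's RNAseq design: samples every 4 h for 48 h
#' (13 timepoints). Rhythmic genes follow a cosine on the log2 scale,
#' log2 mu_g(t) = mesor_g + a_g * cos(2*pi*(t - theta_g)/24); a subset of
#' genes is additionally "responsive", gaining a step of `true_log2fc`
#' from t >= 4 h (the early response to the stimulus). Counts are drawn from
#' a negative binomial with gene-shared dispersion and per-sample library
#' size factors.
#'
#' @param g_genes number of genes.
#' @param frac_rhythmic fraction of genes that are truly rhythmic.
#' @param times sampling times in hours.
#' @param n_reps replicates per timepoint.
#' @param nb_dispersion NB dispersion (var = mu + dispersion * mu^2).
#' @param amplitude_log2 cosine amplitude (log2 units) of rhythmic genes.
#' @param frac_responsive fraction of genes with the T4 step response.
#' @param true_log2fc log2 fold change of responsive genes from t >= 4 h.
#' @param lib_size_range range of multiplicative library-size factors.
#' @param seed RNG seed.
#' @return `rhythmic_count_experiment`: list with integer matrix `counts`
#'   (genes x samples), `samples` data.frame (`sample_id`, `time_h`,
#'   `replicate`), and `truth` data.frame per gene.
#' @export
simulate_count_timeseries <- function(g_genes = 1000, frac_rhythmic = 0.2,
                                      times = seq(0, 48, by = 4),
                                      n_reps = 2, nb_dispersion = 0.1,
                                      amplitude_log2 = 1,
                                      frac_responsive = 0.1,
                                      true_log2fc = 2,
                                      lib_size_range = c(0.7, 1.3),
                                      seed = 1L) {
  if (g_genes < 1) stop("g_genes must be >= 1")
  if (frac_rhythmic < 0 || frac_rhythmic > 1)
    stop("frac_rhythmic must be in [0, 1]")
  .with_seed(seed, {
    n_rh <- round(g_genes * frac_rhythmic)
    rhythmic <- seq_len(g_genes) <= n_rh
    mesor <- stats::runif(g_genes, 3, 9)
    amp <- ifelse(rhythmic, amplitude_log2, 0)
    theta <- stats::runif(g_genes, 0, 24)
    responsive <- stats::runif(g_genes) < frac_responsive
    l2fc <- ifelse(responsive, true_log2fc, 0)
    samples <- expand.grid(replicate = seq_len(n_reps), time_h = times)
    samples <- data.frame(sample_id = sprintf("T%g_R%d", samples$time_h,
                                              samples$replicate),
                          time_h = samples$time_h,
                          replicate = samples$replicate,
                          stringsAsFactors = FALSE)
    lib <- stats::runif(nrow(samples), lib_size_range[1], lib_size_range[2])
    log2mu <- outer(mesor, rep(1, nrow(samples))) +
      outer(amp, rep(1, nrow(samples))) *
        cos(2 * pi * outer(theta, samples$time_h, function(th, t) t - th) / 24) +
      outer(l2fc, as.numeric(samples$time_h >= 4))
    mu <- t(t(2^log2mu) * lib)
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = 1 / nb_dispersion),
                     nrow = g_genes)
    rownames(counts) <- sprintf("gene_%04d", seq_len(g_genes))
    colnames(counts) <- samples$sample_id
    structure(list(counts = counts, samples = samples,
                   truth = data.frame(gene_id = rownames(counts),
                                      rhythmic = rhythmic,
                                      amplitude_log2 = amp,
                                      acrophase_h = theta %% 24,
                                      mesor_log2 = mesor,
                                      responsive_T4 = responsive,
                                      true_log2fc = l2fc,
                                      stringsAsFactors = FALSE),
                   dispersion = nb_dispersion, lib_size = lib),
              class = "rhythmic_count_experiment")
  })
}
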