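.scenario_names <- c("loading_pulse", "phase_series", "dose_series_osmotic",
                     "dose_series_loading", "antiphase_entrainment",
                     "media_swap", "osmotic_cycles_young_aged",
                     "single_cell_osmotic", "rnaseq_osmotic",
                     "treadmill_in_vivo")

.scenario_defaults <- function(scenario) {
  base <- list(scenario = scenario, seed = 1L, out_dir = NULL,
               simulator = list(), analysis = list())
  extra <- switch(scenario,
    loading_pulse = list(dose = 0.5, phase = "peak"),
    phase_series = list(dose = 200, kind = "osmotic_mOsm"),
    dose_series_osmotic = list(doses = c(0, 50, 100, 200, 300, 400),
                               phase = "mid_descending"),
    dose_series_loading = list(doses = c(0, 0.125, 0.25, 0.5, 1),
                               phase = "mid_descending"),
    antiphase_entrainment = list(dose = 0.5, days = 3, free_run_days = 2),
    media_swap = list(dose = 200, swap_time_h = 144),
    osmotic_cycles_young_aged = list(dose = 200, n_cycles = 2),
    single_cell_osmotic = list(dose = 200, responder_fraction = 0.66,
                               n_cells = 78),
    rnaseq_osmotic = list(g_genes = 1000, frac_rhythmic = 0.2,
                          n_reps = 4, nb_dispersion = 0.1),
    treadmill_in_vivo = list(dose = 0.5),
    list())
  c(base, extra)
}

#' Validate and normalise a scenario configuration
#'
#' Accepts a YAML or JSON file path, or a plain list. All problems are
#' collected and reported together rather than fail-fast; on success, all
#' defaults for the scenario are filled in.
#'
#' @param config path to a YAML/JSON config, or a named list with at least a
#'   `scenario` field.
#' @return normalised `scenario_config` list.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  if (is.null(config)) config <- list()
  errors <- character(0)
  if (is.null(config$scenario)) {
    errors <- c(errors, "field 'scenario' is required")
  } else if (!config$scenario %in% .scenario_names) {
    errors <- c(errors, paste0("unknown scenario '", config$scenario,
                               "'; available: ",
                               paste(.scenario_names, collapse = ", ")))
  }
  if (length(errors)) stop(paste(errors, collapse = "; "))
  defaults <- .scenario_defaults(config$scenario)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    errors <- c(errors, paste0("unknown field(s): ",
                               paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(defaults, config[intersect(names(config),
                                                      names(defaults))])
  if (!is.null(cfg$seed) &&
      (!is.numeric(cfg$seed) || cfg$seed != round(cfg$seed)))
    errors <- c(errors, "field 'seed' must be an integer")
  for (fld in c("dose", "doses"))
    if (!is.null(cfg[[fld]]) && any(cfg[[fld]] < 0))
      errors <- c(errors, paste0("field '", fld, "' must be >= 0"))
  if (!is.null(cfg$responder_fraction) &&
      (cfg$responder_fraction < 0 || cfg$responder_fraction > 1))
    errors <- c(errors, "field 'responder_fraction' must be in [0, 1]")
  if (length(errors)) stop(paste(errors, collapse = "; "))
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "scenario_config")
}

.default_ensemble <- function(seed, ...) {
  do.call(oscillator_params, utils::modifyList(list(seed = seed), list(...)))
}

.detrended_ensemble <- function(rec) detrend_moving_average(as_lum_series(rec))

# one stimulated-vs-control deterministic pair for PRC / dose tables
.det_experiment <- function(phase_h, dose, calib, anchor_peak_h = 96,
                            t_end_h = 216) {
  sched <- stimulus_schedule(stimulus_event(anchor_peak_h + phase_h, dose,
                                            calib$stimulus_kind))
  rec <- simulate_ensemble(deterministic_params(), sched, calib, t_end_h)
  list(phase_h = phase_h, dose = dose, treated = as_lum_series(rec),
       event_time_h = anchor_peak_h + phase_h)
}

#' Run a figure-level scenario end to end
#'
#' Simulates the scenario's inputs, runs the relevant pipeline stages,
#' writes intermediate CSV/TSV files plus a machine-readable `summary.json`
#' under the configured output directory, and returns the summary.
#'
#' @param config a `scenario_config` (or anything accepted by
#'   [validate_config()]).
#' @param out_dir output directory; overrides the config's `out_dir`; `NULL`
#'   skips file output.
#' @return summary list (invisibly written as JSON when `out_dir` is set).
#' @export
run_scenario <- function(config, out_dir = NULL) {
  cfg <- if (inherits(config, "scenario_config")) config
         else validate_config(config)
  if (is.null(out_dir)) out_dir <- cfg$out_dir
  seed <- cfg$seed
  osm <- default_osmotic_calibration()
  load <- default_loading_calibration()
  summary <- list(schema_version = 1L, scenario = cfg$scenario, seed = seed)
  files <- list()

  res <- switch(cfg$scenario,
    loading_pulse = {
      # synchronized explant left to damp for 5 days before the bout
      par <- .default_ensemble(seed)
      ev_t <- 120 + .phase_categories[[cfg$phase]]
      sched <- stimulus_schedule(stimulus_event(ev_t, cfg$dose,
                                                "compression_MPa",
                                                duration_h = 1))
      rec <- simulate_ensemble(par, sched, load, t_end_h = 216)
      det <- .detrended_ensemble(rec)
      list(summary = list(event_time_h = ev_t,
                          amplitude_pct = amplitude_percent_change(det, ev_t)),
           traces = list(loading_pulse = rec))
    },
    phase_series = {
      exps <- lapply(.phase_categories, function(ph)
        .det_experiment(ph, cfg$dose,
                        if (cfg$kind == "osmotic_mOsm") osm else load))
      prc <- build_prc(unname(exps))
      list(summary = list(prc = as.data.frame(prc)), tables = list(prc = prc))
    },
    dose_series_osmotic = ,
    dose_series_loading = {
      calib <- if (cfg$scenario == "dose_series_osmotic") osm else load
      ph <- .phase_categories[[cfg$phase]]
      exps <- lapply(cfg$doses, function(d) .det_experiment(ph, d, calib))
      dr <- build_dose_response(exps)
      list(summary = list(phase = cfg$phase,
                          dose_table = as.data.frame(dr),
                          concordance = attr(dr, "concordance")),
           tables = list(dose_response = dr))
    },
    antiphase_entrainment = {
      sch <- make_schedule("antiphase_12_12", dose = cfg$dose,
                           days = cfg$days)
      t_end <- 24 * (cfg$days + cfg$free_run_days)
      recs <- lapply(seq_along(sch), function(i)
        simulate_ensemble(.default_ensemble(seed + i - 1L,
                                            init_mode = "desynchronized"),
                          sch[[i]], load, t_end_h = t_end))
      free <- 24 * cfg$days
      fits <- lapply(recs, function(r) {
        s <- as_lum_series(r)
        keep <- s$time_h >= free
        fit_cosinor_fixed_period(s$signal[keep], time_h = s$time_h[keep])
      })
      diff_h <- wrap_phase_h(fits[[1]]$acrophase_h - fits[[2]]$acrophase_h)
      list(summary = list(acrophase_in_phase_h = fits[[1]]$acrophase_h,
                          acrophase_antiphase_h = fits[[2]]$acrophase_h,
                          phase_difference_h = abs(diff_h),
                          phase_difference_deg = abs(diff_h) * 15),
           traces = list(in_phase = recs[[1]], antiphase = recs[[2]]))
    },
    media_swap = {
      par <- .default_ensemble(seed)
      sw <- cfg$swap_time_h
      sched <- stimulus_schedule(stimulus_event(sw, cfg$dose,
                                                "osmotic_mOsm"))
      hyper <- simulate_ensemble(par, sched, osm, t_end_h = sw + 96)
      ctrl <- simulate_ensemble(.default_ensemble(seed + 1L), NULL, NULL,
                                t_end_h = sw + 96)
      amp <- amplitude_percent_change(.detrended_ensemble(hyper), sw,
                                      reference = "peak_24h_after_start")
      amp_ctrl <- amplitude_percent_change(.detrended_ensemble(ctrl), sw,
                                           reference = "peak_24h_after_start")
      list(summary = list(swap_time_h = sw,
                          amplitude_pct_iso_to_hyper = amp,
                          amplitude_pct_control = amp_ctrl),
           traces = list(iso_to_hyper = hyper, control = ctrl))
    },
    osmotic_cycles_young_aged = {
      run_age <- function(phase_noise, s) {
        par <- .default_ensemble(s, phase_noise = phase_noise)
        sched <- make_schedule("osmotic_cycles", dose = cfg$dose,
                               n_cycles = cfg$n_cycles, start_h = 120)
        stim <- simulate_ensemble(par, sched, osm, t_end_h = 240)
        amplitude_percent_change(.detrended_ensemble(stim), 120 +
                                   24 * (cfg$n_cycles - 1) + 12,
                                 reference = "peak_24h_after_start")
      }
      list(summary = list(amplitude_pct_young = run_age(0.1, seed),
                          amplitude_pct_aged = run_age(0.2, seed + 1L)))
    },
    single_cell_osmotic = {
      par <- oscillator_params(n_cells = as.integer(cfg$n_cells),
                               limit_radius = 0.15, init_radius = 0.35,
                               relax_rate = 0.1,
                               init_mode = "desynchronized",
                               phase_noise = 0.05, obs_baseline = 60,
                               obs_gain = 100, obs_noise_sd = 1,
                               seed = seed)
      pop <- simulate_cell_population(par, responder_fraction =
                                        cfg$responder_fraction,
                                      dose = cfg$dose)
      calls <- classify_population(pop)
      rf <- responder_fraction(calls)
      acc <- mean(calls$responder == pop$truth$responder, na.rm = TRUE)
      list(summary = list(responder_percent = rf$percent,
                          responder_ci = rf$ci_percent,
                          n_defined = rf$n_defined,
                          truth_responder_percent =
                            100 * mean(pop$truth$responder),
                          call_accuracy = acc),
           tables = list(responder_calls = calls),
           traces = list(cells = pop))
    },
    rnaseq_osmotic = {
      exp <- simulate_count_timeseries(g_genes = cfg$g_genes,
                                       frac_rhythmic = cfg$frac_rhythmic,
                                       n_reps = cfg$n_reps,
                                       nb_dispersion = cfg$nb_dispersion,
                                       seed = seed)
      filt <- filter_min_counts(exp$counts, exp$samples)
      norm <- normalize_counts(filt)
      tt <- exp$samples$time_h
      rh <- detect_rhythmic_genes(norm, tt)
      de <- differential_response(norm,
                                  exp$samples$sample_id[tt == 0],
                                  exp$samples$sample_id[tt == 4])
      ref_times <- sort(unique(tt))
      ref <- sapply(ref_times, function(x)
        rowMeans(norm[, tt == x, drop = FALSE]))
      colnames(ref) <- ref_times
      rg <- rh$gene_id[rh$tier2]
      proj <- if (length(rg) >= 10)
        project_sample_phase(norm[, 1:2, drop = FALSE], ref, ref_times,
                             genes = rg)
      else NULL
      list(summary = list(n_genes_filtered = nrow(filt),
                          tier1_count = sum(rh$tier1),
                          tier2_count = sum(rh$tier2),
                          de_up = unname(attr(de, "summary")["up"]),
                          de_down = unname(attr(de, "summary")["down"]),
                          projection = if (is.null(proj)) NULL
                                       else as.data.frame(proj)),
           tables = list(rhythm_stats = rh, de_table = de),
           experiment = exp)
    },
    treadmill_in_vivo = {
      sched <- make_schedule("treadmill_in_vivo", dose = cfg$dose,
                             ref_peak_h = 0)
      t_last_end <- max(sched$events$t_h) + 0.75
      t_end <- t_last_end + 62
      treated <- simulate_ensemble(.default_ensemble(seed), sched, load,
                                   t_end_h = t_end)
      control <- simulate_ensemble(.default_ensemble(seed + 1L), NULL, NULL,
                                   t_end_h = t_end)
      sh <- estimate_phase_shift(as_lum_series(treated), t_last_end,
                                 control = as_lum_series(control),
                                 method = "control_referenced")
      list(summary = list(shift_h = sh$shift_h, se_h = sh$se_h,
                          last_pulse_end_h = t_last_end),
           traces = list(treated = treated, control = control))
    })

  summary <- c(summary, res$summary)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(res$traces)) {
      obj <- res$traces[[nm]]
      write_series_csv(obj, file.path(out_dir, paste0(nm, ".csv")))
    }
    for (nm in names(res$tables))
      utils::write.table(as.data.frame(res$tables[[nm]]),
                         file.path(out_dir, paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(res$experiment))
      write_count_experiment(res$experiment, file.path(out_dir, "counts"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }
  invisible(summary)
}
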