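#' Run a full trial: simulate/load, calibrate, process, evaluate
#'
#' Executes the four-phase operation workflow end to end. Phase 1 obtains
#' the raw series (from the digital twin or from CSV); phase 2 fits the
#' per-cell temperature-drift models on the first day/night cycle and
#' estimates the actuator disturbance on a rolling cadence; phase 3 runs
#' the conditioning pipeline; phase 4 books substrate and plant counts and
#' evaluates per-plant mass against ground truth (when available).
#'
#' @param config Configuration list (see [read_trial_config()]) or path to
#'   a YAML file. Recognised sections: `seed`; `simulate` (arguments to
#'   [sim_config()], plus `schedule: test|validation` as a shortcut for
#'   [harvest_schedule()]); `input`/`truth` (CSV paths, alternative to
#'   `simulate`); `calibration` (`t0`, `window_days`, `cadence_h`,
#'   `edge_guard`, `use_truth_load`); `hampel` (`window_s`, `threshold`);
#'   `filter` (`order`, `cutoff`, `mode`); `ledger` (`n0`, `m_basket`);
#'   `evaluate` (`pre_event_window_min`); `out_dir`.
#' @return A list of class `run_report`: stage summaries, calibration
#'   parameters, correlation before/after per actuator, delta estimates,
#'   and the metric block (harvest errors, per-plant resolution, regression
#'   diagnostics). With `out_dir` set, also writes `biomass.csv`,
#'   `calibration.json` and `report.json`.
#' @export
run_trial <- function(config) {
  if (is.character(config)) config <- read_trial_config(config)
  get_or <- function(l, nm, default) if (!is.null(l[[nm]])) l[[nm]] else default

  # ---- phase 1: data ----
  truth <- NULL
  events <- NULL
  n0 <- get_or(config$ledger, "n0", NA_integer_)
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    if (!is.null(sim_args$schedule)) {
      sim_args$harvest_events <- harvest_schedule(sim_args$schedule)
    }
    sim_args$schedule <- NULL
    if (!is.null(sim_args$start)) sim_args$start <- parse_time(sim_args$start)
    if (is.null(sim_args$seed)) sim_args$seed <- config$seed
    cfg <- do.call(sim_config, sim_args)
    sim <- simulate_tray(cfg)
    series <- sim$series
    truth <- sim$truth
    events <- cfg$harvest_events
    if (is.na(n0)) n0 <- cfg$n_plants_initial
  } else if (!is.null(config$input)) {
    series <- read_tray_csv(config$input)
    if (!is.null(config$truth)) {
      truth <- read.csv(config$truth, stringsAsFactors = FALSE)
      truth$timestamp <- parse_time(truth$timestamp)
    }
  } else {
    stop("config needs either a `simulate` section or an `input` path",
         call. = FALSE)
  }
  dt <- series_interval(series)
  t_rel <- as.numeric(series$timestamp) - as.numeric(series$timestamp[1])

  # ---- phase 2: calibration ----
  cal <- config$calibration
  t0_ref <- get_or(cal, "t0", 20)
  window_days <- get_or(cal, "window_days", 1)
  cadence_s <- get_or(cal, "cadence_h", 24) * 3600
  edge_guard <- get_or(cal, "edge_guard", 2L)
  idx <- t_rel <= window_days * 86400
  cal_slice <- series[idx, , drop = FALSE]
  true_loads <- NULL
  if (!is.null(truth) && isTRUE(get_or(cal, "use_truth_load", TRUE))) {
    true_loads <- rep(mean(truth$tray_true_mass_g[idx]) / 4, 4)
  }
  temp_calibs <- fit_temperature_models(cal_slice, t0_ref, true_loads)

  hampel_cfg <- config$hampel
  hampel_window_s <- get_or(hampel_cfg, "window_s", 150)
  hampel_threshold <- get_or(hampel_cfg, "threshold", 3)
  fl <- config$filter
  fspec <- filter_spec(order = get_or(fl, "order", 4L),
                       cutoff = get_or(fl, "cutoff", 0.025),
                       mode = get_or(fl, "mode", "zero-phase"))

  acts <- actuator_columns(series)
  actuator_models <- NULL
  if (length(acts)) {
    pre <- run_pipeline(series, temp_calibs, actuator_deltas = NULL,
                        filter = fspec, hampel_window_s = hampel_window_s,
                        hampel_threshold = hampel_threshold)
    actuator_models <- lapply(acts, function(a) {
      reestimate_delta(pre$m_temp_g, series[[a]], series$timestamp,
                       cadence_s = cadence_s, edge_guard = edge_guard,
                       actuator_id = a)
    })
    names(actuator_models) <- acts
  }

  if (is.null(events) && !is.null(config$ledger$events)) {
    events <- as.data.frame(config$ledger$events)
  }
  ev_df <- NULL
  if (!is.null(events) && nrow(events)) {
    ev_df <- data.frame(
      timestamp = series$timestamp[1] + events$day * 86400,
      plants_removed = events$plants_removed,
      kind = "harvest")
  }

  # ---- phase 3: processing (filter split at the logged harvest steps) ----
  biomass <- run_pipeline(series, temp_calibs, actuator_models,
                          filter = fspec, hampel_window_s = hampel_window_s,
                          hampel_threshold = hampel_threshold,
                          breaks = ev_df$timestamp)

  # ---- phase 4: biomass accounting & evaluation ----
  ev_cfg <- config$evaluate
  pre_win_s <- get_or(ev_cfg, "pre_event_window_min", 10) * 60
  settle_s <- max(pre_win_s, 3 / (2 * pi * fspec$cutoff) * 60)
  start_idx <- t_rel >= settle_s & t_rel <= settle_s + pre_win_s
  m_sub <- init_substrate_mass(mean(biomass$m_filt_g[start_idx]), n0)
  ledger <- plant_ledger(n0, m_sub = m_sub,
                         m_basket = get_or(config$ledger, "m_basket", 0),
                         events = ev_df)

  window_mean <- function(t_end) {
    k <- t_rel >= (t_end - pre_win_s) & t_rel < t_end
    mean(biomass$m_filt_g[k])
  }
  harvest_eval <- NULL
  if (!is.null(ev_df)) {
    rows <- lapply(seq_len(nrow(ev_df)), function(i) {
      te <- as.numeric(ev_df$timestamp[i]) - as.numeric(series$timestamp[1])
      mlc <- mass_per_plant(window_mean(te), ledger, ev_df$timestamp[i] - dt)
      ref <- if (!is.null(truth)) {
        j <- which.min(abs(as.numeric(truth$timestamp) -
                           as.numeric(ev_df$timestamp[i] - pre_win_s / 2)))
        truth$per_plant_mass_g[j]
      } else NA_real_
      err <- if (is.finite(ref)) harvest_error(mlc, ref) else
        list(abs_g = NA_real_, rel_pct = NA_real_)
      data.frame(timestamp = ev_df$timestamp[i], m_lc_g = mlc,
                 reference_g = ref, abs_error_g = err$abs_g,
                 rel_error_pct = err$rel_pct)
    })
    harvest_eval <- do.call(rbind, rows)
  }
  t_end <- t_rel[length(t_rel)]
  final_mlc <- mass_per_plant(window_mean(t_end + dt), ledger,
                              series$timestamp[nrow(series)])
  final_ref <- if (!is.null(truth)) truth$per_plant_mass_g[nrow(truth)] else NA_real_
  final_err <- if (is.finite(final_ref)) harvest_error(final_mlc, final_ref) else
    list(abs_g = NA_real_, rel_pct = NA_real_)
  n_final <- ledger_count(ledger, series$timestamp[nrow(series)])

  regression <- NULL
  if (!is.null(truth)) {
    daily <- t_rel %% 86400 == 0 & t_rel >= settle_s
    mlc_daily <- tryCatch(
      mass_per_plant(biomass$m_filt_g[daily], ledger, series$timestamp[daily]),
      error = function(e) NULL)
    if (!is.null(mlc_daily) && sum(daily) >= 3) {
      regression <- evaluate_regression(mlc_daily, truth$per_plant_mass_g[daily])
    }
  }

  report <- structure(list(
    seed = config$seed,
    n_samples = nrow(series),
    interval_s = dt,
    stages = attr(biomass, "stages"),
    temperature = lapply(temp_calibs, unclass),
    actuators = actuator_models,
    ledger = list(n0 = n0, m_sub_g = m_sub,
                  n_final = n_final),
    metrics = list(
      harvests = harvest_eval,
      final = list(m_lc_g = final_mlc, reference_g = final_ref,
                   abs_error_g = final_err$abs_g,
                   rel_error_pct = final_err$rel_pct),
      per_plant_resolution_g = per_plant_resolution(
        sensor_accuracy(5000, 0.02, 4)$tray_g, max(n_final, 1)),
      regression = regression)
  ), class = "run_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_biomass_csv(biomass, file.path(config$out_dir, "biomass.csv"))
    write_calibration_json(file.path(config$out_dir, "calibration.json"),
                           temp_calibs, actuator_models)
    write_report_json(report, file.path(config$out_dir, "report.json"))
  }
  report$biomass <- biomass
  report
}

#' Write a run report as JSON
#'
#' @param report A `run_report` from [run_trial()].
#' @param path File path.
#' @export
write_report_json <- function(report, path) {
  r <- unclass(report)
  r$biomass <- NULL
  r$actuators <- lapply(r$actuators, function(a) {
    if (is.data.frame(a)) {
      a$window_start <- fmt_time(a$window_start)
      a$window_end <- fmt_time(a$window_end)
    }
    a
  })
  if (!is.null(r$metrics$harvests)) {
    r$metrics$harvests$timestamp <- fmt_time(r$metrics$harvests$timestamp)
  }
  jsonlite::write_json(r, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null", force = TRUE)
  invisible(path)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d samples @ %g s, n0 = %d -> n = %d\n",
              x$n_samples, x$interval_s, x$ledger$n0, x$ledger$n_final))
  cat(sprintf("  m_sub = %.2f g; final m_lc = %.2f g (ref %.2f g, err %.2f g / %.2f%%)\n",
              x$ledger$m_sub_g, x$metrics$final$m_lc_g, x$metrics$final$reference_g,
              x$metrics$final$abs_error_g, x$metrics$final$rel_error_pct))
  for (nm in names(x$stages$actuators)) {
    a <- x$stages$actuators[[nm]]
    cat(sprintf("  actuator %s: rho %.3f -> %.3f\n", nm, a$rho_before, a$rho_after))
  }
  invisible(x)
}
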