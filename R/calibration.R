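#' Span calibration of one load cell
#'
#' Fits the factor converting raw digitizer units into grams from a
#' two-point measurement: the unloaded reading and the reading under a known
#' reference mass (ideally about half the rated payload).
#'
#' @param known_mass Reference mass in grams (> 0).
#' @param raw_reading_loaded,raw_reading_empty Raw readings with and without
#'   the reference mass.
#' @param cell_id Optional cell identifier.
#' @return List of class `span_calibration` with `factor` (g per raw unit),
#'   `tare_offset` (raw units) and `reference_mass`. `convert()` applied to
#'   the loaded reading returns `known_mass` exactly.
#' @examples
#' cal <- fit_span(2500, 500000, 0)
#' convert_raw(cal, 500000) # 2500
#' @export
fit_span <- function(known_mass, raw_reading_loaded, raw_reading_empty,
                     cell_id = NA_character_) {
  if (!is.finite(known_mass) || known_mass <= 0) {
    stop("`known_mass` must be a positive mass in grams", call. = FALSE)
  }
  d <- raw_reading_loaded - raw_reading_empty
  if (d == 0) {
    stop("degenerate calibration: loaded and empty readings are identical",
         call. = FALSE)
  }
  structure(
    list(cell_id = cell_id,
         factor = known_mass / d,
         tare_offset = raw_reading_empty,
         reference_mass = known_mass),
    class = "span_calibration"
  )
}

#' @rdname fit_span
#' @param calibration A `span_calibration`.
#' @param raw Raw reading(s) to convert.
#' @export
convert_raw <- function(calibration, raw) {
  stopifnot(inherits(calibration, "span_calibration"))
  (raw - calibration$tare_offset) * calibration$factor
}

#' Zero-offset (tare) calibration over an empty-tray window
#'
#' Averages each cell over a window known to contain only empty-tray
#' samples; the resulting per-cell offsets are subtracted from all
#' subsequent readings so that the empty tray reads zero.
#'
#' @param series A [tray_series()] recorded with the tray empty.
#' @param window Either `NULL` (whole series), a duration in seconds from
#'   the start of the series, or a length-2 POSIXct range.
#' @return Named numeric vector of per-cell offsets in grams.
#' @export
tare <- function(series, window = NULL) {
  stopifnot(inherits(series, "tray_series"))
  idx <- rep(TRUE, nrow(series))
  if (!is.null(window)) {
    if (inherits(window, "POSIXct")) {
      stopifnot(length(window) == 2L)
      idx <- series$timestamp >= window[1] & series$timestamp <= window[2]
    } else {
      idx <- as.numeric(series$timestamp) - as.numeric(series$timestamp[1]) <= window
    }
  }
  if (!any(idx)) stop("tare window contains no samples", call. = FALSE)
  vapply(series[idx, cell_columns(series), drop = FALSE], mean, numeric(1))
}

#' Per-cell linear temperature-drift model
#'
#' Low-cost load cells drift with temperature. Under a constant true load,
#' the reading of cell i follows `S_i = load + c_t*(T - t0) + c_t0`; this
#' fits `c_t` (g/degC) and `c_t0` (g) by ordinary least squares of the
#' reading against `(T - t0)`, using a calibration recording in which a
#' constant mass rode the tray while the chamber ran through its
#' temperature cycle.
#'
#' @param series A [tray_series()] recorded under constant true load.
#' @param cell Cell column name (e.g. `"s1_g"`) or index.
#' @param t0 Reference temperature in degC (temperature at zero
#'   calibration).
#' @param true_load The known constant load on the cell in grams, or `NULL`.
#'   The regression intercept equals `true_load + c_t0`, so the constant
#'   offset `c_t0` is identifiable only when the load is known; with
#'   `true_load = NULL` only the drift slope is estimated and `c_t0` is 0.
#' @return List of class `temp_calibration`: `cell_id`, `c_t`, `c_t0`, `t0`,
#'   `r_squared`, `n`.
#' @export
fit_temperature_model <- function(series, cell, t0, true_load = NULL) {
  stopifnot(inherits(series, "tray_series"))
  if (is.numeric(cell)) cell <- cell_columns(series)[cell]
  if (!cell %in% names(series)) stop("unknown cell: ", cell, call. = FALSE)
  y <- series[[cell]]
  x <- series$temp_c - t0
  ok <- is.finite(y) & is.finite(x) & series$mask
  y <- y[ok]; x <- x[ok]
  if (length(x) < 3L || var(x) == 0) {
    stop("temperature channel is constant: drift model unidentifiable",
         call. = FALSE)
  }
  fit <- lm(y ~ x)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(residuals(fit)^2) / ss_tot
  structure(
    list(cell_id = cell,
         c_t = unname(coef(fit)[2]),
         c_t0 = if (is.null(true_load)) 0 else unname(coef(fit)[1]) - true_load,
         t0 = t0,
         r_squared = r2,
         n = length(x)),
    class = "temp_calibration"
  )
}

#' @export
print.temp_calibration <- function(x, ...) {
  cat(sprintf("<temp_calibration> %s: c_t = %.4g g/degC, c_t0 = %.4g g, t0 = %g degC (R2 = %.4f, n = %d)\n",
              x$cell_id, x$c_t, x$c_t0, x$t0, x$r_squared, x$n))
  invisible(x)
}

#' Fit temperature-drift models for every cell of a series
#'
#' @inheritParams fit_temperature_model
#' @param true_loads Optional numeric vector of known per-cell loads.
#' @return Named list of `temp_calibration`, one per cell.
#' @export
fit_temperature_models <- function(series, t0, true_loads = NULL) {
  cells <- cell_columns(series)
  out <- lapply(seq_along(cells), function(j) {
    fit_temperature_model(series, cells[j], t0,
                          true_load = if (is.null(true_loads)) NULL else true_loads[j])
  })
  names(out) <- cells
  out
}

guard_edges <- function(u, guard) {
  # drop samples within `guard` samples of an actuator state transition
  keep <- rep(TRUE, length(u))
  if (guard > 0L) {
    edges <- which(diff(u) != 0)
    for (e in edges) {
      lo <- max(1L, e - guard + 1L)
      hi <- min(length(u), e + guard)
      keep[lo:hi] <- FALSE
    }
  }
  keep
}

#' Actuator disturbance magnitude (state-contrast estimate)
#'
#' Actuators such as climate-control units couple into the cells through
#' vibration and pressure changes, adding a shift `delta` to the tray
#' reading while active. The shift is estimated as the mean reading with the
#' actuator on minus the mean with it off:
#' `delta = mean(mass | u = 1) - mean(mass | u = 0)`.
#'
#' @param mass Numeric tray-mass series in grams (normally the
#'   temperature-corrected mass).
#' @param u Binary actuator state series, same length.
#' @param edge_guard Samples to drop on each side of every on/off transition
#'   before averaging, to avoid transient bias. Set 0 to use all samples.
#' @return The shift `delta` in grams.
#' @examples
#' estimate_actuator_delta(c(12, 14, 8, 10), c(0, 0, 1, 1), edge_guard = 0) # -4
#' @export
estimate_actuator_delta <- function(mass, u, edge_guard = 2L) {
  stopifnot(length(mass) == length(u))
  ok <- is.finite(mass) & u %in% c(0, 1)
  keep <- guard_edges(u, as.integer(edge_guard)) & ok
  both <- function(k) any(u[k] == 1) && any(u[k] == 0)
  if (!both(ok)) {
    stop("actuator state is constant: delta unidentifiable", call. = FALSE)
  }
  if (!both(keep)) {
    warning("edge guard left one state empty; using unguarded samples",
            call. = FALSE)
    keep <- ok
  }
  mean(mass[keep & u == 1]) - mean(mass[keep & u == 0])
}

#' Rolling re-estimation of the actuator disturbance
#'
#' During continuous operation the disturbance magnitude can change (e.g.
#' after a harvest or a configuration change), so the state-contrast
#' estimate is recomputed on a regular cadence over rolling windows; the
#' most recent estimate is the one applied to subsequent data. Windows in
#' which the actuator never changes state retain the previous estimate.
#'
#' @inheritParams estimate_actuator_delta
#' @param timestamp POSIXct vector aligned with `mass`.
#' @param cadence_s Re-estimation cadence in seconds (default one day).
#' @param actuator_id Identifier recorded in the output.
#' @return data.frame of class `actuator_models`, one row per window:
#'   `actuator_id`, `window_start`, `window_end`, `delta_g`, `rho_before`,
#'   `n`, `fresh` (FALSE where a degenerate window retained the previous
#'   estimate).
#' @export
reestimate_delta <- function(mass, u, timestamp, cadence_s = 86400,
                             edge_guard = 2L, actuator_id = "actuator") {
  stopifnot(length(mass) == length(u), length(mass) == length(timestamp),
            cadence_s > 0)
  t0 <- as.numeric(timestamp[1])
  bin <- floor((as.numeric(timestamp) - t0) / cadence_s)
  out <- list()
  prev <- NA_real_
  for (b in sort(unique(bin))) {
    k <- bin == b
    delta <- tryCatch(
      suppressWarnings(estimate_actuator_delta(mass[k], u[k], edge_guard)),
      error = function(e) NA_real_)
    fresh <- is.finite(delta)
    if (!fresh) {
      message(sprintf("window %d: actuator single-state, retaining previous delta", b))
      delta <- prev
    }
    rho <- if (fresh && sd(mass[k]) > 0) cor(mass[k], u[k]) else NA_real_
    out[[length(out) + 1L]] <- data.frame(
      actuator_id = actuator_id,
      window_start = timestamp[which(k)[1]],
      window_end = timestamp[rev(which(k))[1]],
      delta_g = delta, rho_before = rho, n = sum(k), fresh = fresh)
    prev <- delta
  }
  structure(do.call(rbind, out), class = c("actuator_models", "data.frame"))
}
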