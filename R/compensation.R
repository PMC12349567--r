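#' Hampel outlier rejection
#'
#' Centered rolling median/MAD filter: a sample deviating from its window
#' median by more than `threshold` scaled median absolute deviations is
#' replaced by the window median and flagged. Removes one-sample spikes from
#' voltage glitches and short-term loads (manual measurements, maintenance)
#' without disturbing trends: on a clean linear ramp the window MAD exceeds
#' every in-window deviation, so nothing is flagged. Windows are truncated
#' at the series edges.
#'
#' @param x Numeric series.
#' @param window Full window length in samples (odd; even values are
#'   extended by one). Must cover at least 3 samples.
#' @param threshold Rejection threshold in scaled-MAD units (scale factor
#'   1.4826).
#' @return List with `cleaned` (numeric) and `outlier` (logical flags).
#' @examples
#' hampel_clean(c(10, 10, 10, 100, 10, 10, 10), window = 11)
#' @export
hampel_clean <- function(x, window = 11L, threshold = 3) {
  window <- as.integer(window)
  if (window < 3L) stop("`window` must span at least 3 samples", call. = FALSE)
  k <- window %/% 2L
  .hampel_cpp(as.numeric(x), k, threshold)
}

#' Window length in samples for a duration-specified Hampel filter
#'
#' Converts a window duration (e.g. 150 s) into an odd sample count on a
#' given grid: 150 s at a 15 s cadence gives an 11-sample centered window.
#'
#' @param window_s Window duration in seconds.
#' @param interval_s Sampling interval in seconds.
#' @return Odd integer window length.
#' @export
hampel_window_samples <- function(window_s, interval_s) {
  k <- floor((window_s / interval_s) / 2)
  as.integer(2L * max(1L, k) + 1L)
}

#' Temperature-drift correction of a cell reading
#'
#' Removes the linear temperature dependence fitted by
#' [fit_temperature_model()]: the corrected reading is
#' `S_T = S - (c_t*(T - t0) + c_t0)`. At the reference temperature with zero
#' constant offset the reading passes through unchanged.
#'
#' @param reading Cell reading(s) in grams.
#' @param t Air temperature(s) in degC, recycled against `reading`.
#' @param calib A `temp_calibration` for this cell.
#' @return Corrected reading(s) in grams.
#' @examples
#' cal <- structure(list(cell_id = "s1_g", c_t = 1.61, c_t0 = -0.46, t0 = 20,
#'                       r_squared = 1, n = 0), class = "temp_calibration")
#' temperature_correct(500, 25, cal) # 492.41
#' @export
temperature_correct <- function(reading, t, calib) {
  if (!inherits(calib, "temp_calibration")) {
    stop("missing or invalid temperature calibration", call. = FALSE)
  }
  reading - (calib$c_t * (t - calib$t0) + calib$c_t0)
}

#' Tray mass as the sum of the corrected cell outputs
#'
#' @param cells Numeric matrix or data.frame with one column per cell
#'   (aligned series of equal length), or a list of equal-length vectors.
#' @return Numeric series: the row-wise sum.
#' @export
tray_mass <- function(cells) {
  if (is.list(cells) && !is.data.frame(cells)) {
    len <- vapply(cells, length, integer(1))
    if (length(unique(len)) != 1L) {
      stop("cell series are misaligned (unequal lengths)", call. = FALSE)
    }
    cells <- do.call(cbind, cells)
  }
  rowSums(as.matrix(cells))
}

#' Pearson correlation between tray mass and an actuator state
#'
#' Used to detect actuator coupling: a non-negligible correlation between
#' the (temperature-corrected) tray mass and a binary actuator trajectory
#' indicates a disturbance worth compensating.
#'
#' @param mass Numeric series.
#' @param u Binary (or numeric) series of equal length.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
correlation <- function(mass, u) {
  stopifnot(length(mass) == length(u))
  ok <- is.finite(mass) & is.finite(u)
  if (sd(mass[ok]) == 0 || sd(u[ok]) == 0) {
    stop("undefined correlation: an input has zero variance", call. = FALSE)
  }
  cor(mass[ok], u[ok])
}

#' Actuator disturbance correction
#'
#' Subtracts the estimated actuator shift while the actuator is active:
#' `M_u = M_T - delta*u`. With the negative shifts typical of climate
#' control (the tray reads too low while the unit runs), the correction
#' raises the active-period readings.
#'
#' @param mass Tray-mass series in grams.
#' @param u Binary actuator state series.
#' @param delta Estimated shift in grams (see [estimate_actuator_delta()]).
#' @return Corrected mass series.
#' @examples
#' actuator_correct(100, 1, -4) # 104
#' @export
actuator_correct <- function(mass, u, delta) {
  mass - delta * u
}

#' Low-pass filter specification
#'
#' @param order Butterworth filter order (>= 1); order 4 gives an
#'   80 dB/decade rolloff above the cutoff.
#' @param cutoff Cutoff frequency in 1/min. The default 0.025 1/min
#'   (40 min time constant) keeps tray-mass changes above the +/-4 g
#'   accuracy of a four-cell 5 kg setup distinguishable from noise.
#' @param mode `"zero-phase"` (forward-backward, no lag; offline default)
#'   or `"causal"` (single pass, for streaming; group delay of an order-4
#'   Butterworth near DC is about `2/(2*pi*cutoff)` minutes).
#' @return List of class `filter_spec`.
#' @export
filter_spec <- function(order = 4L, cutoff = 0.025,
                        mode = c("zero-phase", "causal")) {
  mode <- match.arg(mode)
  if (order < 1L) stop("`order` must be >= 1", call. = FALSE)
  if (cutoff <= 0) stop("`cutoff` must be > 0", call. = FALSE)
  structure(list(order = as.integer(order), cutoff = cutoff, mode = mode),
            class = "filter_spec")
}

#' Low-pass Butterworth filtering of the tray-mass series
#'
#' Removes the high-frequency measurement noise that remains after
#' temperature and actuator correction. DC gain is exactly 1, so slow
#' biomass trends pass unattenuated. In zero-phase mode the filter is
#' applied forward and backward (squared magnitude response, no lag); in
#' causal mode it is applied once. The series mean start value is
#' subtracted before filtering to suppress the start-up transient.
#'
#' @param mass Tray-mass series on a uniform grid.
#' @param spec A [filter_spec()].
#' @param interval_s Sampling interval of the grid in seconds.
#' @return Filtered series in grams.
#' @export
lowpass <- function(mass, spec = filter_spec(), interval_s = 15) {
  stopifnot(inherits(spec, "filter_spec"))
  nyq <- 60 / interval_s / 2            # 1/min
  if (spec$cutoff >= nyq) {
    stop(sprintf("cutoff %g 1/min is at or above the Nyquist frequency %g 1/min",
                 spec$cutoff, nyq), call. = FALSE)
  }
  W <- spec$cutoff / nyq
  bf <- signal::butter(spec$order, W, type = "low")
  n <- length(mass)
  if (spec$mode == "zero-phase") {
    # odd-reflection padding keeps the extension continuous in value and
    # slope, suppressing the start/end transients of the forward-backward pass
    p <- min(n - 1L, ceiling(10 / W))
    x <- mass - mass[1]
    head_pad <- 2 * x[1] - x[(p + 1L):2L]
    tail_pad <- 2 * x[n] - x[(n - 1L):(n - p)]
    y <- signal::filtfilt(bf, c(head_pad, x, tail_pad))
    y[(p + 1L):(p + n)] + mass[1]
  } else {
    x0 <- mass[1]
    as.numeric(signal::filter(bf, mass - x0)) + x0
  }
}

#' Tray-level biomass processing pipeline
#'
#' Runs the full conditioning chain on a raw [tray_series()], in order:
#' Hampel outlier rejection per cell, temperature correction per cell,
#' summation to tray mass, actuator correction, low-pass filtering. All
#' intermediate series are retained.
#'
#' Invalid samples (`mask == FALSE`, e.g. grid gaps) are linearly
#' interpolated before filtering when the gap is shorter than
#' `max_gap_s`; at longer gaps the series is split and each segment is
#' filtered independently (segments too short to filter pass through
#' unfiltered).
#'
#' @param series A [tray_series()].
#' @param temp_calibs Named list of `temp_calibration`, one per cell
#'   (`NULL` skips temperature correction).
#' @param actuator_deltas Actuator models: a named numeric vector of
#'   constant shifts (grams) keyed by actuator column (with or without the
#'   `act_` prefix), a named list mixing constants and
#'   [reestimate_delta()] tables (applied stepwise, each window's estimate
#'   from its window end onward), or `NULL` to skip the correction.
#' @param filter A [filter_spec()].
#' @param hampel_window_s Hampel window duration in seconds.
#' @param hampel_threshold Hampel threshold in scaled-MAD units.
#' @param max_gap_s Longest gap bridged by interpolation, seconds.
#' @param breaks Optional POSIXct vector of known step discontinuities
#'   (e.g. harvest events). The low-pass filter assumes a slowly varying
#'   signal, so it is applied independently on each side of a break instead
#'   of smearing the step across it.
#' @return data.frame of class `biomass_series` with columns `timestamp`,
#'   `m_raw_g` (sum of raw cells), `m_temp_g`, `m_act_g`, `m_filt_g`,
#'   `mask`; attribute `stages` holds per-stage summaries (outlier counts,
#'   correlation before/after per actuator, deltas used).
#' @export
run_pipeline <- function(series, temp_calibs = NULL, actuator_deltas = NULL,
                         filter = filter_spec(), hampel_window_s = 150,
                         hampel_threshold = 3, max_gap_s = 300, breaks = NULL) {
  stopifnot(inherits(series, "tray_series"))
  dt <- series_interval(series)
  cells <- cell_columns(series)
  n <- nrow(series)

  m_raw <- tray_mass(series[cells])

  # stage 1: Hampel per cell
  w <- hampel_window_samples(hampel_window_s, dt)
  outlier_any <- rep(FALSE, n)
  outlier_counts <- integer(length(cells))
  names(outlier_counts) <- cells
  cleaned <- matrix(0, n, length(cells), dimnames = list(NULL, cells))
  for (j in seq_along(cells)) {
    h <- hampel_clean(series[[cells[j]]], window = w, threshold = hampel_threshold)
    cleaned[, j] <- h$cleaned
    outlier_counts[j] <- sum(h$outlier)
    outlier_any <- outlier_any | h$outlier
  }

  # stage 2: temperature correction per cell
  if (!is.null(temp_calibs)) {
    missing_cal <- setdiff(cells, names(temp_calibs))
    if (length(missing_cal)) {
      stop("missing temperature calibration for: ",
           paste(missing_cal, collapse = ", "), call. = FALSE)
    }
    for (j in seq_along(cells)) {
      cleaned[, j] <- temperature_correct(cleaned[, j], series$temp_c,
                                          temp_calibs[[cells[j]]])
    }
  }
  m_temp <- tray_mass(cleaned)

  # stage 3: actuator correction
  m_act <- m_temp
  act_summary <- list()
  if (!is.null(actuator_deltas) && length(actuator_deltas)) {
    if (is.numeric(actuator_deltas)) actuator_deltas <- as.list(actuator_deltas)
    for (nm in names(actuator_deltas)) {
      col <- if (nm %in% names(series)) nm else paste0("act_", nm)
      if (!col %in% names(series)) {
        warning("actuator channel not found, skipping: ", nm, call. = FALSE)
        next
      }
      u <- series[[col]]
      model <- actuator_deltas[[nm]]
      delta_t <- if (is.data.frame(model)) {
        stepwise_delta(model, series$timestamp)
      } else {
        rep(as.numeric(model), n)
      }
      rho_before <- tryCatch(correlation(m_act, u), error = function(e) NA_real_)
      m_act <- m_act - delta_t * u
      rho_after <- tryCatch(correlation(m_act, u), error = function(e) NA_real_)
      act_summary[[nm]] <- list(rho_before = rho_before, rho_after = rho_after,
                                delta_g = if (is.data.frame(model)) model$delta_g else model)
      if (is.finite(rho_before) && is.finite(rho_after) &&
          abs(rho_after) > abs(rho_before)) {
        warning(sprintf("correction increased |rho| for '%s' (%.3f -> %.3f)",
                        nm, rho_before, rho_after), call. = FALSE)
      }
    }
  }

  # stage 4: low-pass filter with gap policy, split at known discontinuities
  seg <- rep(1L, n)
  if (!is.null(breaks) && length(breaks)) {
    seg <- 1L + findInterval(as.numeric(series$timestamp),
                             sort(as.numeric(breaks)))
  }
  m_filt <- m_act
  for (s in unique(seg)) {
    k <- seg == s
    m_filt[k] <- filter_with_gaps(m_act[k], series$mask[k], filter, dt, max_gap_s)
  }

  out <- data.frame(timestamp = series$timestamp,
                    m_raw_g = m_raw, m_temp_g = m_temp, m_act_g = m_act,
                    m_filt_g = m_filt,
                    mask = series$mask & !outlier_any)
  structure(out,
            interval_s = dt,
            stages = list(n = n, hampel_window_samples = w,
                          outliers = outlier_counts,
                          temperature_corrected = !is.null(temp_calibs),
                          actuators = act_summary,
                          filter = filter),
            class = c("biomass_series", "data.frame"))
}

#' @export
print.biomass_series <- function(x, ...) {
  st <- attr(x, "stages")
  cat(sprintf("<biomass_series> %d samples @ %g s\n", nrow(x), attr(x, "interval_s")))
  cat(sprintf("  outliers flagged: %s\n",
              paste(sprintf("%s=%d", names(st$outliers), st$outliers), collapse = " ")))
  for (nm in names(st$actuators)) {
    a <- st$actuators[[nm]]
    cat(sprintf("  actuator %s: rho %.3f -> %.3f\n", nm, a$rho_before, a$rho_after))
  }
  invisible(x)
}

# piecewise-constant delta trajectory from a reestimate_delta() table:
# each window's estimate applies from its window end onward; before the first
# estimate the first value is used.
stepwise_delta <- function(models, timestamp) {
  stopifnot(all(c("window_end", "delta_g") %in% names(models)))
  ends <- as.numeric(models$window_end)
  idx <- findInterval(as.numeric(timestamp), ends) # 0 before first end
  vals <- models$delta_g
  delta <- vals[pmax(idx, 1L)]
  delta[!is.finite(delta)] <- 0
  delta
}

filter_with_gaps <- function(x, mask, spec, interval_s, max_gap_s) {
  n <- length(x)
  bad <- !mask | !is.finite(x)
  y <- x
  if (any(bad) && any(!bad)) {
    y[bad] <- approx(which(!bad), x[!bad], xout = which(bad), rule = 2)$y
  }
  # split at gap runs longer than max_gap_s
  r <- rle(bad)
  long <- which(r$values & r$lengths * interval_s > max_gap_s)
  seg_id <- rep(1L, n)
  if (length(long)) {
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cut <- rep(FALSE, n)
    for (k in long) cut[starts[k]:ends[k]] <- TRUE
    seg_id <- cumsum(c(TRUE, diff(cut) != 0))
    seg_id[cut] <- NA_integer_
  }
  out <- y
  min_len <- 3L * (2L * spec$order + 1L)  # too short to filter stably
  for (s in unique(seg_id[!is.na(seg_id)])) {
    k <- which(seg_id == s & !is.na(seg_id))
    if (length(k) >= min_len) out[k] <- lowpass(y[k], spec, interval_s)
  }
  out
}
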