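#' Aligned multi-channel tray sensor series
#'
#' Container for the raw sensor streams of one tray: per-cell load readings
#' (grams, span-calibrated), chamber air temperature (degrees C) and binary
#' actuator state channels, all on one uniform time grid.
#'
#' @param timestamp POSIXct vector, strictly increasing, uniformly spaced.
#' @param cells Numeric matrix or data.frame of per-cell readings in grams,
#'   one column per cell (columns are named `s1_g`, `s2_g`, ...).
#' @param temperature Numeric vector of air temperature in degrees C.
#' @param actuators Optional data.frame/matrix of 0/1 actuator states; column
#'   names become `act_<name>` channels.
#' @param mask Optional logical vector of per-sample validity flags
#'   (`TRUE` = valid). Defaults to all valid.
#'
#' @return A data.frame of class `tray_series` with columns `timestamp`,
#'   `s<i>_g`, `temp_c`, `act_*`, `mask`, and an `interval_s` attribute.
#' @export
tray_series <- function(timestamp, cells, temperature, actuators = NULL,
                        mask = NULL) {
  if (!inherits(timestamp, "POSIXct")) {
    stop("`timestamp` must be POSIXct", call. = FALSE)
  }
  n <- length(timestamp)
  cells <- as.data.frame(cells)
  if (nrow(cells) != n || length(temperature) != n) {
    stop("all channels must have the same length as `timestamp`", call. = FALSE)
  }
  dt <- diff(as.numeric(timestamp))
  if (n > 1L) {
    if (any(dt <= 0)) stop("timestamps must be strictly increasing", call. = FALSE)
    if (max(dt) - min(dt) > 1e-6) {
      stop("timestamps must be uniformly spaced; regrid first (see read_tray_csv)",
           call. = FALSE)
    }
  }
  names(cells) <- sprintf("s%d_g", seq_along(cells))
  out <- data.frame(timestamp = timestamp, cells, temp_c = as.numeric(temperature))
  if (!is.null(actuators)) {
    actuators <- as.data.frame(actuators)
    if (nrow(actuators) != n) {
      stop("actuator channels must match `timestamp` length", call. = FALSE)
    }
    bad <- !vapply(actuators, function(u) all(u %in% c(0, 1) | is.na(u)), TRUE)
    if (any(bad)) stop("actuator channels must be binary 0/1", call. = FALSE)
    nm <- names(actuators)
    if (is.null(nm)) nm <- sprintf("a%d", seq_along(actuators))
    names(actuators) <- ifelse(grepl("^act_", nm), nm, paste0("act_", nm))
    out <- cbind(out, actuators)
  }
  out$mask <- if (is.null(mask)) rep(TRUE, n) else as.logical(mask)
  structure(out,
            interval_s = if (n > 1L) stats::median(dt) else NA_real_,
            class = c("tray_series", "data.frame"))
}

#' @export
print.tray_series <- function(x, ...) {
  cat(sprintf("<tray_series> %d samples @ %g s, %d cells, %d actuator(s)\n",
              nrow(x), attr(x, "interval_s"), length(cell_columns(x)),
              length(actuator_columns(x))))
  if (nrow(x)) {
    cat(sprintf("  %s .. %s\n",
                format(x$timestamp[1], tz = "UTC", usetz = TRUE),
                format(x$timestamp[nrow(x)], tz = "UTC", usetz = TRUE)))
  }
  invisible(x)
}

#' Cell and actuator channel names of a tray series
#'
#' @param series A [tray_series()].
#' @return Character vector of column names.
#' @export
cell_columns <- function(series) {
  grep("^s[0-9]+_g$", names(series), value = TRUE)
}

#' @rdname cell_columns
#' @export
actuator_columns <- function(series) {
  grep("^act_", names(series), value = TRUE)
}

#' @rdname cell_columns
#' @export
series_interval <- function(series) {
  attr(series, "interval_s")
}
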