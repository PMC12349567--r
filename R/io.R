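fmt_time <- function(t) format(t, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

parse_time <- function(s) {
  t <- as.POSIXct(s, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  if (anyNA(t)) t <- as.POSIXct(s, tz = "UTC")
  t
}

fmt_num <- function(x) {
  # full double precision so files round-trip losslessly
  ifelse(is.finite(x), sprintf("%.17g", x), "")
}

write_numeric_csv <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    if (inherits(out[[nm]], "POSIXct")) out[[nm]] <- fmt_time(out[[nm]])
    else if (is.double(out[[nm]])) out[[nm]] <- fmt_num(out[[nm]])
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write and read tray sensor series as CSV
#'
#' Comma-separated, `.` decimal, header mandatory; `timestamp` in ISO-8601
#' UTC, cell columns `s1_g`..`s4_g`, `temp_c`, one `act_<name>` 0/1 column
#' per actuator, `mask`. Numeric values are written at full double
#' precision, so a write/read round trip is the identity.
#'
#' @param series A [tray_series()].
#' @param path File path.
#' @return `write_tray_csv`: the path, invisibly. `read_tray_csv`: a
#'   validated [tray_series()].
#' @export
write_tray_csv <- function(series, path) {
  stopifnot(inherits(series, "tray_series"))
  write_numeric_csv(as.data.frame(series), path)
}

#' @rdname write_tray_csv
#' @details `read_tray_csv` validates the grid: duplicated or non-monotone
#'   timestamps are an error naming the offending line; missing samples
#'   (spacing at an integer multiple of the base interval) are re-inserted
#'   as `NA` rows flagged `mask = FALSE`.
#' @export
read_tray_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "temp_c")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  cells <- grep("^s[0-9]+_g$", names(df), value = TRUE)
  if (!length(cells)) stop("no cell columns (s<i>_g) found", call. = FALSE)
  ts <- parse_time(df$timestamp)
  if (anyNA(ts)) {
    stop("unparseable timestamp at line ", which(is.na(ts))[1] + 1L, call. = FALSE)
  }
  d <- diff(as.numeric(ts))
  if (any(d == 0)) {
    stop("duplicated timestamp at line ", which(d == 0)[1] + 2L, call. = FALSE)
  }
  if (any(d < 0)) {
    stop("non-monotone timestamp at line ", which(d < 0)[1] + 2L, call. = FALSE)
  }
  base <- if (length(d)) min(d) else NA_real_
  if (length(d) && any(abs(d / base - round(d / base)) > 1e-6)) {
    stop("timestamps are not on a uniform grid (non-integer spacing) near line ",
         which(abs(d / base - round(d / base)) > 1e-6)[1] + 2L, call. = FALSE)
  }
  if (length(d) && any(round(d / base) > 1)) {
    # regrid: insert NA rows at the gaps, flagged invalid
    full <- seq(as.numeric(ts[1]), as.numeric(ts[length(ts)]), by = base)
    pos <- match(round(as.numeric(ts) / base), round(full / base))
    grid <- data.frame(row = rep(NA_integer_, length(full)))
    grid$row[pos] <- seq_along(ts)
    df2 <- df[grid$row, , drop = FALSE]
    mask <- !is.na(grid$row)
    if ("mask" %in% names(df)) {
      m_in <- as.logical(df$mask)
      mask[!is.na(grid$row)] <- m_in[grid$row[!is.na(grid$row)]]
    }
    acts <- grep("^act_", names(df), value = TRUE)
    for (a in acts) df2[[a]][is.na(df2[[a]])] <- 0L
    df2$temp_c[is.na(df2$temp_c)] <- approx(which(!is.na(grid$row)),
                                            df$temp_c[grid$row[!is.na(grid$row)]],
                                            xout = which(is.na(grid$row)),
                                            rule = 2)$y
    return(tray_series(as.POSIXct(full, tz = "UTC", origin = "1970-01-01"),
                       df2[cells], df2$temp_c,
                       actuators = if (length(acts)) df2[acts] else NULL,
                       mask = mask))
  }
  acts <- grep("^act_", names(df), value = TRUE)
  tray_series(ts, df[cells], df$temp_c,
              actuators = if (length(acts)) df[acts] else NULL,
              mask = if ("mask" %in% names(df)) as.logical(df$mask) else NULL)
}

#' Write and read a processed biomass series as CSV
#'
#' Columns `timestamp, m_raw_g, m_temp_g, m_act_g, m_filt_g, mask`.
#'
#' @param biomass A `biomass_series` from [run_pipeline()].
#' @param path File path.
#' @export
write_biomass_csv <- function(biomass, path) {
  stopifnot(inherits(biomass, "biomass_series"))
  write_numeric_csv(as.data.frame(biomass), path)
}

#' @rdname write_biomass_csv
#' @export
read_biomass_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "m_raw_g", "m_temp_g", "m_act_g", "m_filt_g", "mask")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  df$timestamp <- parse_time(df$timestamp)
  df$mask <- as.logical(df$mask)
  structure(df,
            interval_s = stats::median(diff(as.numeric(df$timestamp))),
            class = c("biomass_series", "data.frame"))
}

#' Write and read the plant-event ledger as CSV
#'
#' Columns `timestamp, plants_removed, kind`.
#'
#' @param ledger A [plant_ledger()].
#' @param path File path.
#' @param n0,m_sub,m_basket Passed to [plant_ledger()] on read.
#' @export
write_ledger_csv <- function(ledger, path) {
  stopifnot(inherits(ledger, "plant_ledger"))
  write_numeric_csv(ledger$events, path)
}

#' @rdname write_ledger_csv
#' @export
read_ledger_csv <- function(path, n0, m_sub = NA_real_, m_basket = 0) {
  ev <- read.csv(path, stringsAsFactors = FALSE)
  ev$timestamp <- parse_time(ev$timestamp)
  plant_ledger(n0, m_sub = m_sub, m_basket = m_basket, events = ev)
}

#' Serialize calibration records to a JSON sidecar
#'
#' Stores temperature calibrations (per cell), actuator models (per
#' actuator) and optional span calibrations, keyed by id, with fit
#' diagnostics, for reuse by the processing stage.
#'
#' @param temp_calibs Named list of `temp_calibration`.
#' @param actuator_deltas Named list: constants or [reestimate_delta()]
#'   tables.
#' @param span_calibs Optional named list of `span_calibration`.
#' @param path File path.
#' @export
write_calibration_json <- function(path, temp_calibs = NULL,
                                   actuator_deltas = NULL, span_calibs = NULL) {
  payload <- list(
    temperature = lapply(temp_calibs, unclass),
    actuators = lapply(actuator_deltas, function(a) {
      if (is.data.frame(a)) {
        a$window_start <- fmt_time(a$window_start)
        a$window_end <- fmt_time(a$window_end)
        a
      } else a
    }),
    span = lapply(span_calibs, unclass),
    written_at = fmt_time(Sys.time())
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  temp <- lapply(p$temperature, function(x) {
    structure(as.list(x), class = "temp_calibration")
  })
  acts <- lapply(p$actuators, function(a) {
    if (is.data.frame(a)) {
      a$window_start <- parse_time(a$window_start)
      a$window_end <- parse_time(a$window_end)
      structure(a, class = c("actuator_models", "data.frame"))
    } else a
  })
  span <- lapply(p$span, function(x) structure(as.list(x), class = "span_calibration"))
  list(temperature = temp, actuators = acts, span = span)
}

#' Read and write a trial configuration file
#'
#' YAML with nested sections (`seed`, `simulate`, `calibration`, `hampel`,
#' `filter`, `ledger`, `evaluate`); round-trippable.
#'
#' @param path File path.
#' @param config A configuration list.
#' @return `read_trial_config`: the configuration list.
#' @export
read_trial_config <- function(path) {
  yaml::read_yaml(path)
}

#' @rdname read_trial_config
#' @export
write_trial_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
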