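#' Plant ledger: counts, substrate and basket bookkeeping
#'
#' Time-indexed record of how many plants sit on the tray. The count starts
#' at `n0` and drops at each harvest/thinning event; the wet substrate plug
#' mass per plant (`m_sub`) and the net-pot basket mass (`m_basket`) are the
#' non-plant masses needed to isolate biomass. Baskets are part of the tray
#' tare but do appear in manual whole-plant measurements.
#'
#' @param n0 Initial plant count.
#' @param m_sub Average wet substrate mass per plant, grams (see
#'   [init_substrate_mass()]).
#' @param m_basket Basket (net pot) mass, grams.
#' @param events data.frame with columns `timestamp` (POSIXct),
#'   `plants_removed` and optionally `kind` (`"harvest"`, `"thinning"`,
#'   `"transplant"`); may be empty or `NULL`.
#' @return List of class `plant_ledger`.
#' @export
plant_ledger <- function(n0, m_sub = NA_real_, m_basket = 0, events = NULL) {
  if (n0 < 0) stop("`n0` must be non-negative", call. = FALSE)
  if (is.null(events)) {
    events <- data.frame(timestamp = as.POSIXct(character(), tz = "UTC"),
                         plants_removed = integer(), kind = character())
  }
  events <- as.data.frame(events)
  stopifnot(all(c("timestamp", "plants_removed") %in% names(events)))
  if (!"kind" %in% names(events)) events$kind <- "harvest"
  events <- events[order(events$timestamp), , drop = FALSE]
  running <- n0 - cumsum(events$plants_removed)
  if (any(running < 0)) {
    stop("ledger inconsistency: removals exceed plant count", call. = FALSE)
  }
  structure(list(n0 = as.integer(n0), m_sub = m_sub, m_basket = m_basket,
                 events = events),
            class = "plant_ledger")
}

#' @export
print.plant_ledger <- function(x, ...) {
  cat(sprintf("<plant_ledger> n0 = %d, m_sub = %s g, m_basket = %g g, %d event(s)\n",
              x$n0, format(x$m_sub), x$m_basket, nrow(x$events)))
  invisible(x)
}

#' Initial wet substrate mass per plant
#'
#' At transplant the seedlings' own mass is negligible, so the filtered
#' tray mass divided by the number of plants gives the average wet
#' substrate (rockwool plug) mass per plant.
#'
#' @param m_filt_at_start Filtered tray mass at trial start, grams (tare
#'   already removed).
#' @param n0 Number of plants at transplant.
#' @return `m_sub` in grams.
#' @examples
#' init_substrate_mass(1000, 20) # 50
#' @export
init_substrate_mass <- function(m_filt_at_start, n0) {
  if (n0 == 0) stop("cannot initialise substrate mass with zero plants",
                    call. = FALSE)
  m_filt_at_start / n0
}

#' Plant count at a given time
#'
#' @param ledger A [plant_ledger()].
#' @param t POSIXct time(s).
#' @return Integer count(s): `n0` minus removals at or before `t`.
#' @export
ledger_count <- function(ledger, t) {
  stopifnot(inherits(ledger, "plant_ledger"))
  ev <- ledger$events
  vapply(as.numeric(t), function(ti) {
    ledger$n0 - sum(ev$plants_removed[as.numeric(ev$timestamp) <= ti])
  }, numeric(1))
}

#' Per-plant biomass from filtered tray mass
#'
#' Subtracts the substrate carried by the current plants and divides by the
#' current count: `m_lc = (M_f - n*m_sub)/n`. Harvested plants leave with
#' their plugs, so both the tray mass and `n` reflect the current tray
#' state.
#'
#' @param m_filt Filtered tray mass in grams (scalar or series).
#' @param ledger A [plant_ledger()] with `m_sub` set.
#' @param t POSIXct time(s) matching `m_filt`.
#' @return Mass per plant in grams.
#' @examples
#' led <- plant_ledger(10, m_sub = 50)
#' mass_per_plant(1000, led, as.POSIXct("2026-01-02", tz = "UTC")) # 50
#' @export
mass_per_plant <- function(m_filt, ledger, t) {
  stopifnot(inherits(ledger, "plant_ledger"))
  if (!is.finite(ledger$m_sub)) {
    stop("`m_sub` not initialised (see init_substrate_mass)", call. = FALSE)
  }
  n <- ledger_count(ledger, t)
  if (any(n == 0)) stop("no plants on tray: per-plant mass undefined", call. = FALSE)
  (m_filt - n * ledger$m_sub) / n
}

#' Leaf-share and sampling-bias adjustment factors
#'
#' Manual whole-plant measurements include root, substrate and basket, and
#' come from a small sample of plants. Two factors map them onto the
#' tray-sensor scale: `c_man`, the leaf share of total plant mass
#' (`mean(m_leaf)/(mean(m_leaf)+mean(m_root))`), and `c_sample`, the ratio
#' of the sampled plants' net mass to the harvest-average total mass
#' (`(mean(m_man)-m_sub-m_basket)/(mean(m_leaf)+mean(m_root))`).
#'
#' @param harvests data.frame of harvest records with columns `m_leaf_g`,
#'   `m_root_g` and `m_man_g` (whole measurement incl. substrate+basket).
#' @param ledger A [plant_ledger()] supplying `m_sub` and `m_basket`.
#' @return List of class `adjustment_factors` with `c_man` and `c_sample`.
#' @export
compute_adjustment_factors <- function(harvests, ledger) {
  stopifnot(inherits(ledger, "plant_ledger"))
  harvests <- as.data.frame(harvests)
  stopifnot(all(c("m_leaf_g", "m_root_g", "m_man_g") %in% names(harvests)),
            nrow(harvests) > 0)
  leaf <- mean(harvests$m_leaf_g)
  root <- mean(harvests$m_root_g)
  if (leaf + root == 0) stop("zero total plant mass in harvest records",
                             call. = FALSE)
  c_man <- leaf / (leaf + root)
  c_sample <- (mean(harvests$m_man_g) - ledger$m_sub - ledger$m_basket) /
    (leaf + root)
  structure(list(c_man = c_man, c_sample = c_sample),
            class = "adjustment_factors")
}

#' Adjust a manual whole-plant measurement to wet leaf mass
#'
#' `m_adj = (c_man/c_sample) * (m_man - m_sub - m_basket)`: substrate and
#' basket are removed, the leaf share isolates the shoot, and the sampling
#' factor corrects for the small manual sample not representing the tray
#' average.
#'
#' @param m_man Manual measurement(s) in grams (plant + substrate +
#'   basket).
#' @param factors An [compute_adjustment_factors()] result (or a list with
#'   `c_man`, `c_sample`).
#' @param ledger A [plant_ledger()] supplying `m_sub` and `m_basket`.
#' @return Estimated wet leaf mass in grams.
#' @export
adjust_manual <- function(m_man, factors, ledger) {
  stopifnot(inherits(ledger, "plant_ledger"))
  if (factors$c_sample == 0) stop("`c_sample` is zero", call. = FALSE)
  (factors$c_man / factors$c_sample) *
    (m_man - ledger$m_sub - ledger$m_basket)
}

#' Worst-case accuracy of the tray weighing subsystem
#'
#' A cell rated at `accuracy_pct` percent of full scale contributes
#' `full_scale * accuracy_pct / 100` grams of absolute error; summing the
#' four cells of a tray worst-case gives the tray accuracy. For the 5 kg
#' cells used here (0.02 % of full scale) this is +/-1 g per cell and
#' +/-4 g per tray.
#'
#' @param full_scale Rated range of one cell, grams.
#' @param accuracy_pct Absolute accuracy as a percentage of full scale
#'   (e.g. `0.02` for 0.02 %).
#' @param n_cells Number of cells carrying the tray.
#' @return List with `per_cell_g` and `tray_g`.
#' @examples
#' sensor_accuracy(5000, 0.02, 4) # per cell 1 g, tray 4 g
#' @export
sensor_accuracy <- function(full_scale, accuracy_pct, n_cells) {
  stopifnot(full_scale >= 0, accuracy_pct >= 0, n_cells >= 1)
  per_cell <- full_scale * accuracy_pct / 100
  list(per_cell_g = per_cell, tray_g = n_cells * per_cell)
}

#' Detectable per-plant biomass change
#'
#' The tray-level accuracy divided by the plant count: the smallest
#' per-plant change distinguishable from sensor error. With +/-4 g tray
#' accuracy this is +/-0.4 g at 10 plants and +/-0.66 g at 6 plants.
#'
#' @param tray_accuracy Tray-level accuracy in grams.
#' @param n Plant count (> 0).
#' @return Resolution in grams per plant.
#' @export
per_plant_resolution <- function(tray_accuracy, n) {
  if (any(n <= 0)) stop("`n` must be positive", call. = FALSE)
  tray_accuracy / n
}

#' Harvest-point error of the sensor against manual reference
#'
#' @param m_lc Sensor-derived per-plant mass at harvest, grams.
#' @param m_leaf_mean Mean manually measured wet leaf mass, grams.
#' @return List with `abs_g` and `rel_pct` (percent of the reference;
#'   `NA` when the reference is zero).
#' @examples
#' harvest_error(14.94, 15.19) # 0.25 g, 1.65 %
#' @export
harvest_error <- function(m_lc, m_leaf_mean) {
  abs_err <- abs(m_lc - m_leaf_mean)
  rel <- if (m_leaf_mean > 0) 100 * abs_err / m_leaf_mean else NA_real_
  list(abs_g = abs_err, rel_pct = rel)
}

#' Regression evaluation of sensor mass against reference mass
#'
#' Ordinary least-squares fit of the manual reference on the sensor output
#' with the usual agreement diagnostics. An ideal sensor gives slope 1,
#' intercept 0, R^2 = 1.
#'
#' @param sensor Sensor-derived masses, grams.
#' @param reference Paired reference (manual) masses, grams.
#' @return List: `slope`, `intercept`, `r_squared`, `mae` (g), `rmse` (g),
#'   `n`.
#' @export
evaluate_regression <- function(sensor, reference) {
  stopifnot(length(sensor) == length(reference))
  ok <- is.finite(sensor) & is.finite(reference)
  sensor <- sensor[ok]; reference <- reference[ok]
  if (length(sensor) < 3L) stop("need at least 3 paired points", call. = FALSE)
  if (var(sensor) == 0) stop("degenerate regression: sensor values constant",
                             call. = FALSE)
  fit <- lm(reference ~ sensor)
  res <- residuals(fit)
  ss_tot <- sum((reference - mean(reference))^2)
  list(slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]),
       r_squared = if (ss_tot == 0) 1 else 1 - sum(res^2) / ss_tot,
       mae = mean(abs(res)),
       rmse = sqrt(mean(res^2)),
       n = length(sensor))
}
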