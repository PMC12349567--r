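#' Logistic per-plant growth curve
#'
#' Fresh shoot mass of one plant as a function of trial day, modelled as a
#' logistic sigmoid: slow establishment after transplant, rapid growth in the
#' late phase, saturation at the asymptote. Lettuce in a 32-day hydroponic
#' cycle reaches most of its final head mass in the last week, which this
#' shape reproduces.
#'
#' @param day Trial day (days since transplant), `>= 0`. Vectorised.
#' @param asymptote Final mass in grams (`>= 0`).
#' @param rate Growth rate in 1/day (`> 0`).
#' @param midpoint Day at which half the asymptote is reached (`> 0`).
#'
#' @return Mass in grams, monotone non-decreasing in `day`.
#' @examples
#' growth_curve(0:32, asymptote = 84, rate = 0.425, midpoint = 21.6)
#' @export
growth_curve <- function(day, asymptote = 84, rate = 0.425, midpoint = 21.6) {
  if (any(day < 0)) stop("`day` must be >= 0", call. = FALSE)
  if (asymptote < 0 || rate <= 0 || midpoint <= 0) {
    stop("growth parameters must be positive (`asymptote` >= 0)", call. = FALSE)
  }
  asymptote / (1 + exp(-rate * (day - midpoint)))
}

#' Mid-trial harvest schedules of the reference growth trials
#'
#' Plant-removal schedules of the two reference trials: the test trial
#' removes two plants every two to three days from day 13 (2 on each of days
#' 13, 15, 18, 20, 23, 26 and 29, leaving 6 of 20 at end of trial), the
#' validation trial removes 10 plants on day 18 (leaving 10 of 20).
#'
#' @param trial `"test"` or `"validation"`.
#' @return data.frame with columns `day` and `plants_removed`.
#' @export
harvest_schedule <- function(trial = c("test", "validation")) {
  trial <- match.arg(trial)
  if (trial == "test") {
    data.frame(day = c(13, 15, 18, 20, 23, 26, 29),
               plants_removed = rep(2L, 7L))
  } else {
    data.frame(day = 18, plants_removed = 10L)
  }
}

#' Simulation configuration for the tray digital twin
#'
#' Bundles every knob of [simulate_tray()]. Defaults emulate the validation
#' growth trial of the reference setup: 20 lettuce plants on one tray read by
#' four 5-kg cells at 15 s cadence for 32 days; logistic growth to an 84 g
#' head; 50 g wet rockwool plug per plant; chamber at 20 degC with a 4 degC
#' LED-driven rise over a 17 h photoperiod; per-cell linear temperature drift;
#' a duty-cycled climate-control actuator that shifts the tray reading by
#' -4 g while active; 1 g Gaussian noise per cell and sporadic one-sample
#' spikes from manual handling.
#'
#' @param n_plants_initial Initial plant count.
#' @param tare_mass Residual tray mass after zero calibration, grams.
#' @param substrate_mass_per_plant Wet substrate plug mass, grams/plant.
#' @param growth List: `asymptote` (g), `rate` (1/day), `midpoint` (day).
#'   Set `asymptote = 0` for a static (no-growth) tray.
#' @param temp_profile List: `base` (degC), `amplitude` (degC, added during
#'   the photoperiod), `photoperiod_h` (h), `tau_min` (first-order lag of the
#'   chamber air response, minutes).
#' @param temp_coeffs List of per-cell drift parameters: `c_t` (g/degC,
#'   length 4), `c_t0` (g, length 4), `t0` (reference temperature, degC).
#' @param actuator List or `NULL`: `name`, `period_min`, `duty` (0..1),
#'   `delta` (additive shift in grams on the tray total while active).
#' @param noise_sigma Gaussian measurement noise s.d. per cell, grams.
#' @param spike_rate Expected spike outliers per day (Poisson arrivals).
#' @param spike_magnitude Spike amplitude, grams (sign random).
#' @param harvest_events data.frame `day`, `plants_removed` (see
#'   [harvest_schedule()]), or `NULL`.
#' @param root_fraction Root share of total plant mass; roots hang in the
#'   nutrient solution and are not carried by the tray, but their mass is
#'   tracked in the ground truth.
#' @param sample_interval_s Sampling interval, seconds.
#' @param duration_days Trial length, days.
#' @param start Trial start time (POSIXct, UTC).
#' @param seed Integer seed; mandatory, all randomness derives from it.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_plants_initial = 20L,
                       tare_mass = 0,
                       substrate_mass_per_plant = 50,
                       growth = list(asymptote = 84, rate = 0.425, midpoint = 21.6),
                       temp_profile = list(base = 20, amplitude = 4,
                                           photoperiod_h = 17, tau_min = 30),
                       temp_coeffs = list(c_t = c(1.61, -1.41, 0.61, -1.88),
                                          c_t0 = c(-0.46, -0.27, -0.06, -0.09),
                                          t0 = 20),
                       actuator = list(name = "climate", period_min = 30,
                                       duty = 0.5, delta = -4),
                       noise_sigma = 1,
                       spike_rate = 10,
                       spike_magnitude = 200,
                       harvest_events = NULL,
                       root_fraction = 0.23,
                       sample_interval_s = 15,
                       duration_days = 32,
                       start = as.POSIXct("2026-01-01 06:00:00", tz = "UTC"),
                       seed) {
  if (missing(seed) || is.null(seed)) {
    stop("`seed` is mandatory: the simulator has no implicit randomness",
         call. = FALSE)
  }
  if (sample_interval_s <= 0) stop("`sample_interval_s` must be > 0", call. = FALSE)
  if (duration_days <= 0) stop("`duration_days` must be > 0", call. = FALSE)
  if (n_plants_initial < 1) stop("need at least one plant", call. = FALSE)
  if (!is.null(harvest_events)) {
    harvest_events <- as.data.frame(harvest_events)
    stopifnot(all(c("day", "plants_removed") %in% names(harvest_events)))
    harvest_events <- harvest_events[order(harvest_events$day), , drop = FALSE]
    remaining <- n_plants_initial - cumsum(harvest_events$plants_removed)
    if (any(remaining < 0)) {
      stop("infeasible harvest schedule: removals exceed plant count",
           call. = FALSE)
    }
  }
  structure(
    list(n_plants_initial = as.integer(n_plants_initial), tare_mass = tare_mass,
         substrate_mass_per_plant = substrate_mass_per_plant, growth = growth,
         temp_profile = temp_profile, temp_coeffs = temp_coeffs,
         actuator = actuator, noise_sigma = noise_sigma,
         spike_rate = spike_rate, spike_magnitude = spike_magnitude,
         harvest_events = harvest_events, root_fraction = root_fraction,
         sample_interval_s = sample_interval_s, duration_days = duration_days,
         start = start, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate a tray growth trial (digital twin)
#'
#' Generates the raw sensor streams of one instrumented tray together with
#' the ground truth they encode. Each cell carries a quarter of the true
#' tray mass and is corrupted, in grams, by linear temperature drift
#' `c_t*(T - t0) + c_t0`, a quarter share of the actuator shift while the
#' actuator is active, Gaussian noise, and sporadic one-sample spikes.
#' True tray mass is `tare + n(t)*m_sub + sum of shoot masses`; harvested
#' plants leave with their substrate plug, producing an instantaneous step.
#'
#' @param config A [sim_config()].
#' @return List of class `tray_sim` with elements `series` (a
#'   [tray_series()]) and `truth` (data.frame `timestamp`,
#'   `per_plant_mass_g`, `root_mass_g`, `plant_count`, `tray_true_mass_g`).
#'   Deterministic given `config$seed`.
#' @examples
#' sim <- simulate_tray(sim_config(duration_days = 1, seed = 1))
#' sim$series
#' @export
simulate_tray <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  dt <- config$sample_interval_s
  n <- floor(config$duration_days * 86400 / dt) + 1L
  t_s <- (seq_len(n) - 1L) * dt
  timestamp <- config$start + t_s
  day <- t_s / 86400

  # chamber temperature: photoperiod square wave through a first-order lag
  tp <- config$temp_profile
  hod <- (as.numeric(config$start) %% 86400 + t_s) %% 86400 / 3600
  target <- tp$base + tp$amplitude * (hod < tp$photoperiod_h)
  temp <- numeric(n)
  alpha <- 1 - exp(-dt / (tp$tau_min * 60))
  temp[1] <- target[1]
  for (i in seq_len(n - 1L)) {
    temp[i + 1L] <- temp[i] + alpha * (target[i + 1L] - temp[i])
  }

  # plant count from the harvest ledger
  count <- rep(config$n_plants_initial, n)
  if (!is.null(config$harvest_events)) {
    for (k in seq_len(nrow(config$harvest_events))) {
      ev_t <- config$harvest_events$day[k] * 86400
      count[t_s >= ev_t] <- count[t_s >= ev_t] - config$harvest_events$plants_removed[k]
    }
  }

  g <- config$growth
  shoot <- growth_curve(day, g$asymptote, g$rate, g$midpoint)
  root <- shoot * config$root_fraction / (1 - config$root_fraction)
  true_mass <- config$tare_mass +
    count * (config$substrate_mass_per_plant + shoot)

  # actuator duty cycle
  act <- NULL
  u <- rep(0L, n)
  if (!is.null(config$actuator)) {
    p <- config$actuator$period_min * 60
    u <- as.integer((t_s %% p) < config$actuator$duty * p)
    act <- data.frame(u)
    names(act) <- config$actuator$name
  }

  tc <- config$temp_coeffs
  cells <- matrix(0, n, 4L)
  act_share <- if (is.null(config$actuator)) 0 else config$actuator$delta / 4
  for (j in 1:4) {
    cells[, j] <- true_mass / 4 +
      tc$c_t[j] * (temp - tc$t0) + tc$c_t0[j] +
      act_share * u +
      if (config$noise_sigma > 0) rnorm(n, 0, config$noise_sigma) else 0
  }

  # spike outliers: Poisson arrivals, one sample, one random cell, random sign
  n_spikes <- if (config$spike_rate > 0) {
    rpois(1L, config$spike_rate * config$duration_days)
  } else 0L
  if (n_spikes > 0L) {
    at <- sample.int(n, n_spikes, replace = TRUE)
    on_cell <- sample.int(4L, n_spikes, replace = TRUE)
    sgn <- sample(c(-1, 1), n_spikes, replace = TRUE)
    for (k in seq_len(n_spikes)) {
      cells[at[k], on_cell[k]] <- cells[at[k], on_cell[k]] +
        sgn[k] * config$spike_magnitude
    }
  }

  series <- tray_series(timestamp, cells, temp, actuators = act)
  truth <- data.frame(timestamp = timestamp,
                      per_plant_mass_g = shoot,
                      root_mass_g = root,
                      plant_count = count,
                      tray_true_mass_g = true_mass)
  structure(list(series = series, truth = truth, config = config),
            class = "tray_sim")
}

#' @export
print.tray_sim <- function(x, ...) {
  cat(sprintf("<tray_sim> seed %d, %g days @ %g s\n",
              x$config$seed, x$config$duration_days,
              x$config$sample_interval_s))
  print(x$series)
  invisible(x)
}
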