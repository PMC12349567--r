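# shared fixtures: small simulator configs and brute-force oracles

# a quiet tray: no noise, no spikes, no actuator, constant temperature at t0,
# no growth -- every disturbance channel switched off
quiet_config <- function(..., seed = 1) {
  defaults <- list(
    n_plants_initial = 20L,
    tare_mass = 0,
    substrate_mass_per_plant = 50,
    growth = list(asymptote = 0, rate = 0.425, midpoint = 21.6),
    temp_profile = list(base = 20, amplitude = 0, photoperiod_h = 17, tau_min = 30),
    temp_coeffs = list(c_t = rep(0, 4), c_t0 = rep(0, 4), t0 = 20),
    actuator = NULL,
    noise_sigma = 0,
    spike_rate = 0,
    spike_magnitude = 0,
    duration_days = 0.25,
    seed = seed
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# brute-force Hampel reference: literal rolling median / scaled-MAD with
# edge truncation, independent of the compiled implementation
hampel_oracle <- function(x, window, threshold) {
  k <- window %/% 2L
  n <- length(x)
  out <- x
  flag <- logical(n)
  for (i in seq_len(n)) {
    w <- x[max(1, i - k):min(n, i + k)]
    w <- w[is.finite(w)]
    if (length(w) < 3 || !is.finite(x[i])) next
    m <- median(w)
    s <- 1.4826 * median(abs(w - m))
    if (abs(x[i] - m) > threshold * s) {
      out[i] <- m
      flag[i] <- TRUE
    }
  }
  list(cleaned = out, outlier = flag)
}

# analytic order-n Butterworth magnitude at frequency f for cutoff fc
butter_mag <- function(f, fc, order = 4) 1 / sqrt(1 + (f / fc)^(2 * order))

# steady-state amplitude of a filtered sinusoid (discard settling ends)
settled_amplitude <- function(y, drop_frac = 0.25) {
  n <- length(y)
  keep <- seq(floor(n * drop_frac), ceiling(n * (1 - drop_frac)))
  (max(y[keep]) - min(y[keep])) / 2
}

make_series <- function(n = 100, interval = 15, cells = NULL, temp = NULL,
                        actuators = NULL, start = as.POSIXct("2026-01-01", tz = "UTC")) {
  if (is.null(cells)) cells <- matrix(250, n, 4)
  if (is.null(temp)) temp <- rep(20, n)
  tray_series(start + (seq_len(n) - 1) * interval, cells, temp,
              actuators = actuators)
}
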