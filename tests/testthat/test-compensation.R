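test_that("hampel filter replaces spikes, keeps constants and ramps", {
  const <- hampel_clean(rep(10, 20), window = 11)
  expect_equal(const$cleaned, rep(10, 20))
  expect_false(any(const$outlier))

  spike <- hampel_clean(c(10, 10, 10, 100, 10, 10, 10), window = 11, threshold = 3)
  expect_equal(spike$cleaned, rep(10, 7))
  expect_equal(which(spike$outlier), 4L)

  ramp <- hampel_clean(seq(0, 100, length.out = 50), window = 11)
  expect_false(any(ramp$outlier))
  expect_equal(ramp$cleaned, seq(0, 100, length.out = 50))

  expect_error(hampel_clean(1:10, window = 1), "at least 3")
})

test_that("hampel filter matches the brute-force rolling median/MAD oracle", {
  set.seed(13)
  for (i in 1:50) {
    n <- sample(20:200, 1)
    x <- cumsum(rnorm(n)) + ifelse(runif(n) < 0.05, rnorm(n, 0, 25), 0)
    w <- sample(c(5L, 7L, 11L), 1)
    got <- hampel_clean(x, window = w, threshold = 3)
    ref <- hampel_oracle(x, window = w, threshold = 3)
    expect_equal(got$cleaned, ref$cleaned)
    expect_equal(got$outlier, ref$outlier)
  }
})

test_that("hampel filter passes missing samples through untouched", {
  x <- c(10, 10, NA, 10, 100, 10, 10)
  got <- hampel_clean(x, window = 5, threshold = 3)
  expect_true(is.na(got$cleaned[3]))
  expect_false(got$outlier[3])
  expect_equal(got$cleaned[5], 10)
})

test_that("temperature correction applies the fitted linear drift model", {
  cal <- function(c_t, c_t0, t0 = 20) {
    structure(list(cell_id = "s1_g", c_t = c_t, c_t0 = c_t0, t0 = t0,
                   r_squared = 1, n = 0), class = "temp_calibration")
  }
  # at the reference temperature with no constant offset: unchanged
  expect_equal(temperature_correct(500, 20, cal(1.61, 0)), 500)
  # drift coefficients of the first cell in the two reference trials
  expect_equal(temperature_correct(500, 25, cal(1.61, -0.46)), 492.41)
  expect_equal(temperature_correct(500, 18, cal(-1.54, -0.01)), 496.93)
  expect_error(temperature_correct(500, 25, NULL), "calibration")
})

test_that("tray mass is the order-invariant sum of aligned cells", {
  expect_equal(tray_mass(data.frame(a = 1, b = 2, c = 3, d = 4)), 10)
  expect_equal(tray_mass(matrix(0, 5, 4)), rep(0, 5))
  m <- matrix(rnorm(40), 10, 4)
  expect_equal(tray_mass(m), tray_mass(m[, c(3, 1, 4, 2)]))
  expect_error(tray_mass(list(1:5, 1:4, 1:5, 1:5)), "misaligned")
})

test_that("correlation is Pearson's coefficient with degenerate inputs rejected", {
  x <- c(1, 3, 2, 5, 4)
  expect_equal(correlation(x, x), 1)
  expect_equal(correlation(c(1, 2, 3), c(0, 1, 0)), 0)
  expect_error(correlation(c(1, 2, 3), c(1, 1, 1)), "zero variance")
  expect_error(correlation(c(2, 2, 2), c(0, 1, 0)), "zero variance")
})

test_that("actuator correction shifts active samples by minus delta", {
  expect_equal(actuator_correct(100, 1, -4), 104)
  m <- rnorm(20)
  expect_equal(actuator_correct(m, rep(0, 20), -4), m)
  # correcting with the generating delta kills the correlation
  set.seed(17)
  u <- rep(c(0, 1), 500)
  m <- 1000 - 4 * u + rnorm(1000, 0, 0.5)
  expect_gt(abs(correlation(m, u)), 0.9)
  expect_lt(abs(correlation(actuator_correct(m, u, -4), u)), 0.1)
})

test_that("butterworth response matches the analytic magnitude within 1%", {
  # |H(f)| = 1/sqrt(1 + (f/fc)^8) over two decades around the cutoff
  fs <- 4          # samples per minute (15 s cadence)
  fc <- 0.025      # 1/min
  bf <- signal::butter(4, fc / (fs / 2), type = "low")
  f <- fc * 10^seq(-1, 1, length.out = 41)
  H <- signal::freqz(bf$b, bf$a, n = 2 * pi * f / fs)$h
  expect_equal(abs(H), butter_mag(f, fc, 4), tolerance = 0.01)
})

test_that("lowpass has unit DC gain and the designed rolloff", {
  spec_c <- filter_spec(4, 0.025, "causal")
  spec_z <- filter_spec(4, 0.025, "zero-phase")
  const <- rep(123.4, 2000)
  expect_equal(lowpass(const, spec_z, 15), const, tolerance = 1e-9)
  expect_equal(lowpass(const, spec_c, 15), const, tolerance = 1e-6)

  t_min <- seq(0, 4000, by = 0.25) # 15 s steps
  at_fc <- sin(2 * pi * 0.025 * t_min)
  expect_equal(settled_amplitude(lowpass(at_fc, spec_c, 15)), 1 / sqrt(2),
               tolerance = 0.01)
  expect_equal(settled_amplitude(lowpass(at_fc, spec_z, 15)), 0.5,
               tolerance = 0.01)
  at_10fc <- sin(2 * pi * 0.25 * t_min)
  expect_lt(settled_amplitude(lowpass(at_10fc, spec_c, 15)), 1e-4)

  expect_error(lowpass(const, filter_spec(4, 3), 15), "Nyquist")
})

test_that("pipeline holds a disturbance-free steady tray within the accuracy band", {
  sim <- simulate_tray(quiet_config(noise_sigma = 1, duration_days = 1, seed = 2))
  bm <- run_pipeline(sim$series)
  settled <- seq(floor(nrow(bm) * 0.2), nrow(bm))
  expect_true(all(abs(bm$m_filt_g[settled] - 1000) < 4))
  # no actuator models: corrected mass degenerates to the temperature stage
  expect_equal(bm$m_act_g, bm$m_temp_g)
})

test_that("temperature correction exactly inverts the simulated drift", {
  cfg <- quiet_config(temp_profile = list(base = 20, amplitude = 4,
                                          photoperiod_h = 17, tau_min = 30),
                      temp_coeffs = list(c_t = c(1.61, -1.41, 0.61, -1.88),
                                         c_t0 = c(-0.46, -0.27, -0.06, -0.09),
                                         t0 = 20),
                      duration_days = 1)
  sim <- simulate_tray(cfg)
  calibs <- lapply(1:4, function(j) {
    structure(list(cell_id = sprintf("s%d_g", j), c_t = cfg$temp_coeffs$c_t[j],
                   c_t0 = cfg$temp_coeffs$c_t0[j], t0 = 20, r_squared = 1, n = 0),
              class = "temp_calibration")
  })
  names(calibs) <- sprintf("s%d_g", 1:4)
  bm <- run_pipeline(sim$series, calibs)
  expect_equal(bm$m_temp_g, rep(1000, nrow(bm)), tolerance = 1e-9)
  expect_gt(max(abs(bm$m_raw_g - 1000)), 1) # drift was actually present
})

test_that("adding a constant weight shifts the filtered mass by that weight", {
  sim <- simulate_tray(quiet_config(noise_sigma = 1, duration_days = 2, seed = 9))
  s <- sim$series
  half <- seq_len(nrow(s)) > nrow(s) / 2
  for (cc in cell_columns(s)) s[[cc]][half] <- s[[cc]][half] + 72 / 4
  bm <- run_pipeline(s)
  n <- nrow(bm)
  before <- mean(bm$m_filt_g[floor(n * 0.25):floor(n * 0.45)])
  after <- mean(bm$m_filt_g[floor(n * 0.75):floor(n * 0.95)])
  expect_equal(after - before, 72, tolerance = 4)
})

test_that("short masked gaps are bridged before filtering", {
  n <- 4000
  s <- make_series(n = n, cells = matrix(100, n, 4))
  s$mask[2001:2004] <- FALSE # one-minute dropout
  for (cc in cell_columns(s)) s[[cc]][2001:2004] <- NA
  bm <- run_pipeline(s)
  expect_true(all(is.finite(bm$m_filt_g)))
  expect_equal(bm$m_filt_g, rep(400, n), tolerance = 1e-6)
  expect_false(any(bm$mask[2001:2004]))
})
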