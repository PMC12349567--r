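t0 <- as.POSIXct("2026-01-01", tz = "UTC")

ledger_from_schedule <- function(trial, n0 = 20, m_sub = 50, m_basket = 0) {
  sc <- harvest_schedule(trial)
  plant_ledger(n0, m_sub = m_sub, m_basket = m_basket,
               events = data.frame(timestamp = t0 + sc$day * 86400,
                                   plants_removed = sc$plants_removed,
                                   kind = "harvest"))
}

test_that("substrate mass is the start-of-trial tray mass per plant", {
  expect_equal(init_substrate_mass(1000, 20), 50)
  expect_equal(init_substrate_mass(0, 20), 0)
  expect_error(init_substrate_mass(1000, 0), "zero plants")
})

test_that("ledger reproduces the reference harvest schedules", {
  test_led <- ledger_from_schedule("test")
  # 2 plants on each of days 13,15,18,20,23,26,29 -> 6 remain
  expect_equal(ledger_count(test_led, t0 + 32 * 86400), 6)
  expect_equal(ledger_count(test_led, t0 + 14 * 86400), 18)
  expect_equal(ledger_count(test_led, t0), 20)

  val_led <- ledger_from_schedule("validation")
  expect_equal(ledger_count(val_led, t0 + 17 * 86400), 20)
  expect_equal(ledger_count(val_led, t0 + 18 * 86400), 10)
  expect_equal(ledger_count(val_led, t0 + 32 * 86400), 10)

  # removals plus remaining plants account for every transplant
  expect_equal(sum(harvest_schedule("test")$plants_removed) + 6, 20)
  expect_equal(sum(harvest_schedule("validation")$plants_removed) + 10, 20)

  no_events <- plant_ledger(20)
  expect_equal(ledger_count(no_events, t0 + 100 * 86400), 20)
  expect_error(plant_ledger(5, events = data.frame(timestamp = t0,
                                                   plants_removed = 6)),
               "inconsistency")
})

test_that("per-plant mass subtracts current substrate and divides by count", {
  led <- plant_ledger(10, m_sub = 50)
  expect_equal(mass_per_plant(1000, led, t0), 50)
  expect_equal(mass_per_plant(10 * 50, led, t0), 0) # substrate-only tray
  thin <- plant_ledger(10, m_sub = 50,
                       events = data.frame(timestamp = t0 + 86400,
                                           plants_removed = 4))
  expect_equal(mass_per_plant(700, thin, t0 + 2 * 86400), (700 - 300) / 6)
  expect_error(mass_per_plant(100, plant_ledger(2, m_sub = 50,
    events = data.frame(timestamp = t0, plants_removed = 2)), t0 + 1),
    "no plants")
  expect_error(mass_per_plant(100, plant_ledger(10), t0), "not initialised")
})

test_that("per-plant mass ignores zero-biomass plants removed with their plugs", {
  # removing k massless plants (with substrate) leaves m_lc unchanged
  led_before <- plant_ledger(10, m_sub = 50)
  led_after <- plant_ledger(10, m_sub = 50,
                            events = data.frame(timestamp = t0 + 10,
                                                plants_removed = 3))
  m_tray <- 10 * 50 + 10 * 20 # 20 g per plant
  expect_equal(mass_per_plant(m_tray, led_before, t0), 20)
  # but the 3 removed plants here carry 20 g each, so tray drops by 3*(50+20)
  expect_equal(mass_per_plant(m_tray - 3 * 70, led_after, t0 + 20), 20)
})

test_that("adjustment factors follow the leaf-share and sample-ratio definitions", {
  led <- plant_ledger(10, m_sub = 50, m_basket = 10)
  h <- data.frame(m_leaf_g = c(70, 84), m_root_g = c(20, 26),
                  m_man_g = c(120, 140))
  f <- compute_adjustment_factors(h, led)
  expect_equal(f$c_man, 77 / 100)
  expect_equal(f$c_sample, (130 - 50 - 10) / 100)
  # rootless limit
  f2 <- compute_adjustment_factors(
    data.frame(m_leaf_g = 50, m_root_g = 0, m_man_g = 110), led)
  expect_equal(f2$c_man, 1)
  # unbiased sample: manual net mass equals harvest mean -> c_sample = 1
  f3 <- compute_adjustment_factors(
    data.frame(m_leaf_g = 77, m_root_g = 23, m_man_g = 160), led)
  expect_equal(f3$c_sample, 1)
  expect_error(compute_adjustment_factors(
    data.frame(m_leaf_g = 0, m_root_g = 0, m_man_g = 60), led), "zero")
})

test_that("manual measurements are adjusted to the wet-leaf scale", {
  led <- plant_ledger(10, m_sub = 50, m_basket = 10)
  f <- list(c_man = 0.77, c_sample = 0.67)
  expect_equal(adjust_manual(150, f, led), 0.77 / 0.67 * 90)
  expect_equal(adjust_manual(150, f, led), 103.43, tolerance = 1e-4)
  # identity when factors cancel and there is nothing to subtract
  led0 <- plant_ledger(10, m_sub = 0, m_basket = 0)
  expect_equal(adjust_manual(42, list(c_man = 0.8, c_sample = 0.8), led0), 42)
  # plantless pot measures zero
  expect_equal(adjust_manual(60, f, led), 0)
  expect_error(adjust_manual(150, list(c_man = 0.77, c_sample = 0), led), "zero")
  # linear in the net mass; common scaling of both factors changes nothing
  a <- adjust_manual(100, f, led); b <- adjust_manual(160, f, led)
  expect_equal(adjust_manual(130, f, led), (a + b) / 2)
  f_scaled <- list(c_man = 0.77 * 3, c_sample = 0.67 * 3)
  expect_equal(adjust_manual(150, f_scaled, led), adjust_manual(150, f, led))
})

test_that("sensor accuracy and per-plant resolution arithmetic", {
  acc <- sensor_accuracy(5000, 0.02, 4)
  expect_equal(acc$per_cell_g, 1)
  expect_equal(acc$tray_g, 4)
  expect_equal(sensor_accuracy(5000, 0.02, 1)$tray_g, 1)
  expect_equal(sensor_accuracy(3000, 0, 4)$tray_g, 0)
  expect_equal(per_plant_resolution(4, 10), 0.4)
  expect_equal(round(per_plant_resolution(4, 6), 2) - 0.66, 0, tolerance = 0.011)
  expect_equal(per_plant_resolution(0, 5), 0)
  expect_error(per_plant_resolution(4, 0), "positive")
})

test_that("harvest error returns absolute grams and percent of reference", {
  e1 <- harvest_error(14.94, 15.19)
  expect_equal(e1$abs_g, 0.25)
  expect_equal(round(e1$rel_pct, 2), 1.65)
  e2 <- harvest_error(83.15, 83.8)
  expect_equal(e2$abs_g, 0.65)
  expect_equal(round(e2$rel_pct, 2), 0.78)
  e3 <- harvest_error(10, 10)
  expect_equal(e3$abs_g, 0)
  expect_equal(e3$rel_pct, 0)
  expect_true(is.na(harvest_error(5, 0)$rel_pct))
})

test_that("regression evaluator reports OLS agreement diagnostics", {
  r <- evaluate_regression(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(r$slope, 1)
  expect_equal(r$intercept, 0)
  expect_equal(r$r_squared, 1)
  expect_equal(r$mae, 0)
  expect_equal(r$rmse, 0)
  r2 <- evaluate_regression(c(1, 2, 3), c(2, 4, 6))
  expect_equal(r2$slope, 2)
  expect_equal(r2$intercept, 0, tolerance = 1e-12)
  expect_equal(r2$r_squared, 1)
  expect_error(evaluate_regression(c(1, 2), c(1, 2)), "at least 3")
  expect_error(evaluate_regression(rep(1, 5), 1:5), "degenerate")
  # noisy data: R^2 drops by about var(noise)/var(reference)
  set.seed(19)
  x <- seq(10, 90, length.out = 200)
  y <- x + rnorm(200, 0, 3)
  r3 <- evaluate_regression(x, y)
  expect_equal(r3$r_squared, var(x) / (var(x) + 9), tolerance = 0.02)
  expect_equal(r3$rmse, 3, tolerance = 0.3)
})
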