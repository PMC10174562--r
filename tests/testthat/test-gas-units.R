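test_that("water vapor pressure matches steam-table anchors and is monotone", {
  # inverted from the air-saturation PO2 of tropical seawater at 758 mm Hg:
  # 758 - 152.86 / 0.2095 = 28.36 mm Hg
  expect_equal(water_vapor_pressure(28), 28.36, tolerance = 0.1 / 28.36)
  expect_equal(water_vapor_pressure(25), 23.76, tolerance = 0.1 / 23.76)
  # boiling at standard atmosphere
  expect_equal(water_vapor_pressure(100), 760, tolerance = 1 / 760)
  tt <- seq(0, 100, by = 0.5)
  expect_true(all(diff(water_vapor_pressure(tt)) > 0))
  expect_error(water_vapor_pressure(-1), "0, 100")
  expect_error(water_vapor_pressure(101), "0, 100")
})

test_that("PO2 at full air saturation reproduces the trial-water value", {
  expect_equal(po2_at_full_air_saturation(cond28), 152.86,
               tolerance = 0.05 / 152.86)
  c760 <- gas_conditions(28, 33, 760)
  expect_equal(po2_at_full_air_saturation(c760), 153.28,
               tolerance = 0.05 / 153.28)
  # linear in barometric pressure at fixed temperature
  p1 <- po2_at_full_air_saturation(gas_conditions(28, 33, 700))
  p2 <- po2_at_full_air_saturation(gas_conditions(28, 33, 758))
  p3 <- po2_at_full_air_saturation(gas_conditions(28, 33, 790))
  pv <- water_vapor_pressure(28)
  expect_equal((p2 - p1) / (758 - 700), (p3 - p2) / (790 - 758),
               tolerance = 1e-12)
  # doubling the oxygen mole fraction doubles the result
  cx <- gas_conditions(28, 33, 758, o2_mole_fraction = 0.419)
  expect_equal(po2_at_full_air_saturation(cx),
               2 * po2_at_full_air_saturation(cond28), tolerance = 1e-12)
})

test_that("oxygen solubility matches published values and monotonicity", {
  chpa <- gas_conditions(28, 33, 1011, pressure_unit = "hPa")
  expect_equal(o2_solubility(chpa), 6.45, tolerance = 0.10 / 6.45)
  expect_equal(o2_solubility(gas_conditions(20, 0, 760)), 9.08,
               tolerance = 0.10 / 9.08)
  # strictly decreasing in temperature and salinity
  s30 <- o2_solubility(gas_conditions(30, 33, 758))
  s28 <- o2_solubility(gas_conditions(28, 33, 758))
  expect_lt(s30, s28)
  expect_lt(o2_solubility(gas_conditions(28, 35, 758)), s28)
  temps <- seq(1, 39, by = 2)
  sols <- vapply(temps,
                 function(t) o2_solubility(gas_conditions(t, 33, 758)),
                 numeric(1))
  expect_true(all(diff(sols) < 0))
})

test_that("percent saturation converts linearly to PO2 and DO", {
  expect_equal(percent_sat_to_po2(30.7, cond28), 46.93, tolerance = 2e-4)
  expect_equal(percent_sat_to_po2(23.8, cond28), 36.38, tolerance = 2e-4)
  expect_equal(percent_sat_to_po2(42.0, cond28),
               0.42 * po2_at_full_air_saturation(cond28),
               tolerance = 1e-12)
  expect_identical(percent_sat_to_po2(0, cond28), 0)
  expect_identical(percent_sat_to_do(0, cond28), 0)
  expect_equal(percent_sat_to_do(100, gas_conditions(28, 33, 758)), 6.45,
               tolerance = 0.10 / 6.45)
  # self-consistent DO at the 6-dph LOE level (the published rounding gives
  # 1.99; product of the published factors gives 1.98)
  expect_equal(percent_sat_to_do(30.7, cond28), 1.98, tolerance = 0.05 / 2)
  expect_error(percent_sat_to_po2(-1, cond28), "non-negative")
  expect_error(percent_sat_to_do(-1, cond28), "non-negative")
  pct <- seq(0, 120, by = 5)
  expect_true(all(diff(percent_sat_to_po2(pct, cond28)) > 0))
  expect_true(all(diff(percent_sat_to_do(pct, cond28)) > 0))
})

test_that("unit conversions round-trip and the two pressure units agree", {
  set.seed(4)
  for (i in 1:25) {
    cond <- gas_conditions(runif(1, 1, 39), runif(1, 0, 40),
                           runif(1, 510, 790))
    pct <- runif(1, 0, 150)
    expect_equal(po2_to_percent_sat(percent_sat_to_po2(pct, cond), cond),
                 pct, tolerance = 1e-9)
    expect_equal(do_to_percent_sat(percent_sat_to_do(pct, cond), cond),
                 pct, tolerance = 1e-9)
  }
  # the trial water was reported as both 758 mm Hg and 1011 hPa
  a <- po2_at_full_air_saturation(gas_conditions(28, 33, 758))
  b <- po2_at_full_air_saturation(
    gas_conditions(28, 33, 1011, pressure_unit = "hPa"))
  expect_equal(a, b, tolerance = 1e-3)
})

test_that("oxygen readings are internally consistent and inputs validated", {
  r <- oxygen_reading(c(42.0, 30.7, 23.8), cond28)
  expect_equal(nrow(r), 3)
  expect_equal(po2_to_percent_sat(r$po2, cond28),
               r$percent_air_saturation, tolerance = 1e-9)
  expect_equal(do_to_percent_sat(r$dissolved_o2, cond28),
               r$percent_air_saturation, tolerance = 1e-9)
  expect_error(gas_conditions(-5, 33, 758), "temperature")
  expect_error(gas_conditions(28, 55, 758), "salinity")
  expect_error(gas_conditions(28, 33, 300), "pressure")
})
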