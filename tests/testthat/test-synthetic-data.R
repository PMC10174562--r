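test_that("cohort generation follows the growth regression and is seeded", {
  cfg <- cohort_config(ages = 9, n_per_age = 5, mass_noise_sd = 0,
                       seed = 2)
  fish <- generate_cohort(cfg)
  # noiseless limit of the mass-age regression
  expect_true(all(fish$mass_mg == 0.422 * 9 + 0.0328))

  cfg <- cohort_config(seed = 123)
  f1 <- generate_cohort(cfg)
  f2 <- generate_cohort(cfg)
  expect_identical(f1, f2)
  f3 <- generate_cohort(cohort_config(seed = 124))
  expect_false(identical(f1$mass_mg, f3$mass_mg))

  # default 77-fish cohort recovers the generating mass-age slope, with
  # the moderate explanatory power of a real larval growth regression
  expect_equal(nrow(f1), 77)
  gr <- lm(mass_mg ~ age_dph, f1)
  expect_lt(abs(unname(coef(gr)[2]) - 0.422) / 0.422, 0.15)
  expect_gt(summary(gr)$r.squared, 0.45)
  expect_lt(summary(gr)$r.squared, 0.85)
})

test_that("simulated swim trials start saturated and encode true rates", {
  cfg <- quiet_config()
  pr <- swim_protocol(increment_cm_s = 1, habituation_min = 5)
  ch <- chamber_spec()
  fish <- make_fish_row(length_cm = 1, true_ucrit_bl_s = 4.5,
                        true_smr = 1.2, true_cost_coeff = 0.04)
  tr <- simulate_swim_trial(fish, pr, ch, cfg)
  expect_equal(tr$o2_percent_sat[1], 100)
  expect_equal(tr$time_s[1], 0)

  # zero-noise, zero-background: per-step uptake within 0.5% of truth
  fr <- fish_record(fish$fish_id, fish$age_dph, fish$mass_mg,
                    fish$length_cm)
  steps <- step_measurements(tr, fr, ch, gas_conditions(28, 33, 758))
  true_rate <- fish$true_smr +
    fish$true_cost_coeff * steps$speed_cm_s^fish$true_cost_exponent
  expect_true(all(abs(steps$mo2 - true_rate) / true_rate < 0.005))

  # fatigue recorded 10 min into the 5 cm/s step
  win <- measure_windows(tr)
  last <- win[nrow(win), ]
  expect_equal(last$speed_cm_s, 5)
  expect_equal(last$n, 600)

  # a trace survives a write/read cycle unchanged
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, path)
  back <- read_trace(path)
  expect_equal(back$o2_percent_sat, tr$o2_percent_sat)
  expect_equal(back$speed_cm_s, tr$speed_cm_s)
})

test_that("background subtraction in the analysis matches the simulator", {
  cfg <- quiet_config(background_slope_range = c(-8e-6, -8e-6))
  pr <- swim_protocol(increment_cm_s = 1, habituation_min = 5)
  ch <- chamber_spec()
  fish <- make_fish_row(length_cm = 1, true_ucrit_bl_s = 3.5,
                        bg_pre_slope = -8e-6, bg_post_slope = -1.2e-5)
  tr <- simulate_swim_trial(fish, pr, ch, cfg)
  fr <- fish_record(fish$fish_id, fish$age_dph, fish$mass_mg,
                    fish$length_cm)
  cond <- gas_conditions(28, 33, 758)
  bg <- background_rate(tr, tr, cond)
  steps <- step_measurements(tr, fr, ch, cond, bg)
  true_rate <- fish$true_smr +
    fish$true_cost_coeff * steps$speed_cm_s^fish$true_cost_exponent
  expect_true(all(abs(steps$mo2 - true_rate) / true_rate < 0.005))
})

test_that("closed-vial LOE trials conserve oxygen and respect thresholds", {
  cfg <- quiet_config()
  ch <- chamber_spec()
  fish <- make_fish_row(mass_mg = 3.8, true_smr = 2,
                        true_loe_percent = 23.8)
  sim <- simulate_loe_trial(fish, ch, cfg)
  # continuous observation records the threshold crossing exactly
  expect_equal(sim$loe_percent_recorded, 23.8, tolerance = 1e-9)

  # oxygen removed from the water equals integrated uptake
  cond <- gas_conditions(28, 33, 758)
  sol <- o2_solubility(cond)
  v_eff <- effective_volume_l(ch, fish$mass_mg, "vial")
  removed_mg <- (100 - 23.8) / 100 * sol * v_eff
  uptake_mg <- fish$true_smr * fish$mass_mg / 1000 / 3600 * sim$t_loe_s
  expect_equal(removed_mg, uptake_mg, tolerance = 1e-3)

  # drawdown takes longer in a larger vial
  t_small <- sim$t_loe_s
  t_big <- simulate_loe_trial(fish, chamber_spec(vial_volume_ml = 3),
                              cfg)$t_loe_s
  expect_gt(t_big, t_small)

  # observer-check quantisation records at or below the true threshold
  cfgq <- quiet_config(loe_check_interval_s = 180)
  simq <- simulate_loe_trial(fish, ch, cfgq)
  expect_lte(simq$loe_percent_recorded, 23.8)
})

test_that("whole-study simulation is deterministic and writes clean files", {
  cfg <- quiet_config()
  co1 <- simulate_cohort(cfg, habituation_min = 5)
  co2 <- simulate_cohort(cfg, habituation_min = 5)
  expect_identical(co1$fish, co2$fish)
  expect_identical(co1$traces, co2$traces)
  expect_identical(co1$loe, co2$loe)

  dir <- withr::local_tempdir()
  write_cohort(co1, dir)
  expect_true(file.exists(file.path(dir, "metadata.csv")))
  expect_true(file.exists(file.path(dir, "loe.csv")))
  meta <- read_fish_metadata(file.path(dir, "metadata.csv"))
  expect_equal(nrow(meta), nrow(co1$fish))
  loe <- read_loe_table(file.path(dir, "loe.csv"))
  expect_equal(nrow(loe), nrow(co1$loe))
  tr <- read_trace(file.path(dir, "traces", paste0(meta$fish_id[1],
                                                   ".csv")))
  expect_equal(tr$o2_percent_sat, co1$traces[[meta$fish_id[1]]]$o2_percent_sat)
})
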