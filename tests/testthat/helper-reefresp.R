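# shared fixtures built in code

cond28 <- gas_conditions(28, 33, 758)

# a fish row shaped like one row of generate_cohort(), with every true
# parameter chosen by the caller
make_fish_row <- function(fish_id = "f1", age_dph = 9, mass_mg = 4,
                          length_cm = 1, true_smr = 1,
                          true_cost_coeff = 0.05, true_cost_exponent = 2,
                          true_ucrit_bl_s = 4.5,
                          true_loe_percent = 23.8,
                          bg_pre_slope = 0, bg_post_slope = 0) {
  data.frame(fish_id = fish_id, age_dph = age_dph, mass_mg = mass_mg,
             length_cm = length_cm, true_smr = true_smr,
             true_cost_coeff = true_cost_coeff,
             true_cost_exponent = true_cost_exponent,
             true_ucrit_cm_s = true_ucrit_bl_s * length_cm,
             true_ucrit_bl_s = true_ucrit_bl_s,
             true_mmr = true_smr + true_cost_coeff *
               (ceiling(true_ucrit_bl_s) * length_cm)^true_cost_exponent,
             true_loe_percent = true_loe_percent,
             bg_pre_slope = bg_pre_slope, bg_post_slope = bg_post_slope,
             stringsAsFactors = FALSE)
}

# deterministic small-cohort configuration used by several files: short
# habituation keeps traces small, all noise off unless a test turns it on
quiet_config <- function(...) {
  args <- list(ages = c(5, 9), n_per_age = 2, sensor_noise_sd = 0,
               smr_lognorm_sd = 0, ucrit_cv = 0, mass_noise_sd = 0,
               background_slope_range = c(0, 0), seed = 11)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(cohort_config, args)
}

run_swim_quiet <- function(...) {
  suppressWarnings(suppressMessages(run_swim_analysis(...)))
}

# a noiseless synthetic measurement trace: linear dissolved-oxygen decline
# expressed in % air saturation, with minimal flush bookends
linear_measure_trace <- function(do_start, do_end, duration_s,
                                 cond = cond28, speed = 5,
                                 temp = cond$temperature) {
  n <- duration_s + 1
  conc <- seq(do_start, do_end, length.out = n)
  pct <- do_to_percent_sat(conc, cond)
  data.frame(time_s = 0:duration_s, o2_percent_sat = pct,
             temp_c = rep(temp, n), phase = rep("measure", n),
             speed_cm_s = rep(speed, n), stringsAsFactors = FALSE)
}
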