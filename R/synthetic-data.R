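#' Configuration for a synthetic larval cohort
#'
#' Defines the statistical structure of a simulated cohort of larval
#' anemonefish: a linear mass--age growth regression, a cube-root
#' mass--length allometry, allometric mass-specific standard metabolic rate
#' (exponent -0.8 by default), a power-shaped swimming cost, an age trend in
#' critical swimming speed, an age trend in the loss-of-equilibrium (LOE)
#' threshold, microbial background respiration, and optode-like Gaussian
#' sensor noise. The defaults describe a 77-fish cohort spanning ages 1--9
#' days post hatch with LOE trials at 4, 6 and 9 dph.
#'
#' @param ages Ages (dph) in the swim cohort (default 1:9).
#' @param n_per_age Fish per age; recycled against `ages`
#'   (default 9,8,9,9,8,9,8,9,8 -> 77 fish).
#' @param mass_intercept,mass_slope Growth regression
#'   `mass_mg = slope * age + intercept` (defaults 0.0328 mg and
#'   0.422 mg per day).
#' @param mass_noise_cv Coefficient of variation of the size-proportional
#'   mass residual (default 0.33): the residual SD at each age is
#'   `cv * mean mass`, so hatchlings vary by ~0.15 mg and settlers by
#'   ~1.3 mg, reproducing the moderate explanatory power (r-squared about
#'   0.65) of a larval growth regression while keeping masses positive.
#' @param mass_noise_sd Optional absolute residual SD in mg overriding the
#'   proportional model (truncated at `mass_min`). `NULL` (default) uses
#'   `mass_noise_cv`; 0 disables mass noise entirely.
#' @param mass_min Smallest admissible mass, mg (default 0.05).
#' @param length_coeff,length_exponent Mass--length allometry
#'   `length_cm = coeff * mass_mg^exponent` (defaults 0.511 and 1/3,
#'   giving ~0.8 cm at settlement size).
#' @param smr_coeff,smr_exponent True mass-specific SMR allometry
#'   `SMR = coeff * mass_mg^exponent` in mg O2 g^-1 h^-1 (defaults 5
#'   and -0.8).
#' @param smr_lognorm_sd SD of the lognormal individual scatter on true SMR
#'   (default 0.15).
#' @param speed_cost_exponent Exponent `d` of the swimming cost term
#'   `c * u^d` (default 2, the conventional hydrodynamic cost shape).
#' @param speed_cost_fas Target factorial aerobic scope at the speed of
#'   the fish's fatigue step, where maximum uptake is measured
#'   (default 2.2); the cost coefficient is derived per fish as
#'   `c = (FAS - 1) * SMR / u_fatigue^d` unless `speed_cost_coeff`
#'   overrides it.
#' @param speed_cost_coeff Optional fixed cost coefficient overriding the
#'   FAS-based parameterisation (default `NULL`).
#' @param ucrit_bl_hatch,ucrit_bl_settle True Ucrit trend in BL s^-1,
#'   linear in age from hatch (age 0) to `settle_age`
#'   (defaults 2.5 and 9.4).
#' @param settle_age Age of settlement, dph (default 9).
#' @param ucrit_cv Coefficient of variation of individual Ucrit scatter
#'   (default 0.12).
#' @param loe_ages,loe_means,loe_sds,loe_n LOE trial ages (dph), group mean
#'   thresholds (% air saturation), group SDs and group sizes (defaults
#'   4/6/9 dph, 42.0/30.7/23.8 %, 4.6/7.1/3.7 %, 13/12/9 fish).
#' @param sensor_noise_sd SD of i.i.d. Gaussian sensor noise on % air
#'   saturation (default 0.2).
#' @param background_slope_range Range (negative, mg O2 L^-1 s^-1) from
#'   which the pre-trial microbial background slope is drawn
#'   (default -1e-5 to -1e-6); the post-trial slope is the pre-trial slope
#'   times a growth factor in \[1.2, 2\].
#' @param flush_tau_s Time constant of the exponential flush relaxation,
#'   seconds (default 60, restoring > 95% of the deficit in a 3-min
#'   flush).
#' @param saturation_floor Percent air saturation at which a measurement
#'   period is cut short and flushing starts early (default 90).
#' @param loe_check_interval_s Spacing of observer checks in LOE trials,
#'   seconds; 0 (default) records the threshold crossing exactly, a
#'   positive value quantises the recorded level to the first check at or
#'   after the crossing.
#' @param conform_below_percent Oxygen level below which the resting uptake
#'   of an LOE trial declines in proportion to ambient oxygen
#'   (oxyconformity); 0 (default) keeps uptake constant.
#' @param temperature,salinity,pressure_mmhg Trial water conditions
#'   (defaults 28 degC, 33 ppt, 758 mm Hg).
#' @param seed Integer RNG seed (default 1); a fixed seed makes cohort
#'   generation bit-identical.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(ages = 1:9,
                          n_per_age = c(9, 8, 9, 9, 8, 9, 8, 9, 8),
                          mass_intercept = 0.0328, mass_slope = 0.422,
                          mass_noise_cv = 0.33, mass_noise_sd = NULL,
                          mass_min = 0.05,
                          length_coeff = 0.511, length_exponent = 1 / 3,
                          smr_coeff = 5, smr_exponent = -0.8,
                          smr_lognorm_sd = 0.15,
                          speed_cost_exponent = 2, speed_cost_fas = 2.2,
                          speed_cost_coeff = NULL,
                          ucrit_bl_hatch = 2.5, ucrit_bl_settle = 9.4,
                          settle_age = 9, ucrit_cv = 0.12,
                          loe_ages = c(4, 6, 9),
                          loe_means = c(42.0, 30.7, 23.8),
                          loe_sds = c(4.6, 7.1, 3.7),
                          loe_n = c(13, 12, 9),
                          sensor_noise_sd = 0.2,
                          background_slope_range = c(-1e-5, -1e-6),
                          flush_tau_s = 60, saturation_floor = 90,
                          loe_check_interval_s = 0,
                          conform_below_percent = 0,
                          temperature = 28, salinity = 33,
                          pressure_mmhg = 758, seed = 1L) {
  n_per_age <- rep_len(n_per_age, length(ages))
  stopifnot(all(n_per_age >= 1), mass_noise_cv >= 0,
            is.null(mass_noise_sd) || mass_noise_sd >= 0,
            sensor_noise_sd >= 0,
            length(loe_ages) == length(loe_means),
            length(loe_ages) == length(loe_sds),
            length(loe_ages) == length(loe_n),
            all(background_slope_range <= 0), flush_tau_s > 0)
  structure(as.list(environment()), class = "cohort_config")
}

.trend_at <- function(x, xs, ys) {
  if (length(xs) == 1) return(rep(ys, length(x)))
  stats::approx(xs, ys, xout = x, rule = 2)$y
}

.true_mo2 <- function(fish, u) {
  fish$true_smr + fish$true_cost_coeff * u^fish$true_cost_exponent
}

rtruncnorm_pos <- function(n, mean, sd, lower) {
  sd <- rep_len(sd, n)
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower)
  guard <- 0L
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean[bad], sd[bad])
    bad <- which(x < lower)
    guard <- guard + 1L
    if (guard > 1000L) { x[bad] <- lower; break }
  }
  x
}

#' Generate a cohort of virtual larvae with hidden true parameters
#'
#' Draws one fish per row: mass from the mass--age growth regression plus
#' truncated-normal noise, body length from the mass--length allometry,
#' true SMR from the SMR allometry with lognormal individual scatter, the
#' swimming-cost coefficient from the target factorial scope at the true
#' Ucrit, true Ucrit from the age trend with proportional scatter, a true
#' LOE threshold from the LOE age trend, and per-trial microbial background
#' slopes.
#'
#' @param config A [cohort_config()].
#' @return A data frame with one row per fish. Observable columns:
#'   `fish_id`, `age_dph`, `mass_mg`, `length_cm`. Hidden-truth columns
#'   (prefixed `true_`): `true_smr`, `true_cost_coeff`,
#'   `true_cost_exponent`, `true_ucrit_cm_s`, `true_ucrit_bl_s`,
#'   `true_mmr`, `true_loe_percent`, plus `bg_pre_slope`, `bg_post_slope`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  .draw_cohort(config)
}

# one cohort draw from the current RNG state
.draw_cohort <- function(config) {
  age <- rep(config$ages, rep_len(config$n_per_age, length(config$ages)))
  n <- length(age)
  mass_mean <- config$mass_slope * age + config$mass_intercept
  mass_sd <- if (!is.null(config$mass_noise_sd))
    rep_len(config$mass_noise_sd, n)
  else config$mass_noise_cv * mass_mean
  mass <- if (any(mass_sd > 0))
    rtruncnorm_pos(n, mass_mean, mass_sd, config$mass_min)
  else mass_mean
  len <- config$length_coeff * mass^config$length_exponent
  smr <- config$smr_coeff * mass^config$smr_exponent
  if (config$smr_lognorm_sd > 0)
    smr <- smr * exp(stats::rnorm(n, 0, config$smr_lognorm_sd))
  ucrit_bl <- config$ucrit_bl_hatch +
    (config$ucrit_bl_settle - config$ucrit_bl_hatch) *
      age / config$settle_age
  if (config$ucrit_cv > 0)
    ucrit_bl <- ucrit_bl * pmax(stats::rnorm(n, 1, config$ucrit_cv), 0.2)
  ucrit_cm <- ucrit_bl * len
  d <- config$speed_cost_exponent
  # speed of the step during which the fish fatigues (increment = 1 BL/s);
  # the maximum uptake is measured at this speed, so the factorial-scope
  # anchor applies here
  frac <- ucrit_bl - floor(ucrit_bl)
  fatigue_speed_cm <- ifelse(frac > 0, floor(ucrit_bl) + 1, ucrit_bl) * len
  cc <- if (!is.null(config$speed_cost_coeff))
    rep(config$speed_cost_coeff, n)
  else (config$speed_cost_fas - 1) * smr / fatigue_speed_cm^d
  true_mmr <- smr + cc * fatigue_speed_cm^d
  loe_mean <- .trend_at(age, config$loe_ages, config$loe_means)
  loe_sd <- .trend_at(age, config$loe_ages, config$loe_sds)
  loe <- pmin(pmax(stats::rnorm(n, loe_mean, loe_sd), 2), 95)
  bg_pre <- stats::runif(n, min(config$background_slope_range),
                         max(config$background_slope_range))
  bg_post <- bg_pre * stats::runif(n, 1.2, 2)
  data.frame(
    fish_id = sprintf("fish%03d", seq_len(n)),
    age_dph = age, mass_mg = mass, length_cm = len,
    true_smr = smr, true_cost_coeff = cc, true_cost_exponent = d,
    true_ucrit_cm_s = ucrit_cm, true_ucrit_bl_s = ucrit_bl,
    true_mmr = true_mmr, true_loe_percent = loe,
    bg_pre_slope = bg_pre, bg_post_slope = bg_post,
    stringsAsFactors = FALSE)
}

# piecewise trace assembly helper: one phase segment of constant or
# linearly varying depletion slope, integrated with midpoint rule (exact
# for a linearly drifting slope)
.decline_segment <- function(p0, n, t0, slope_pct_fun) {
  if (n <= 0) return(numeric(0))
  p <- numeric(n)
  p[1] <- p0
  if (n > 1) {
    mids <- t0 + seq_len(n - 1) - 0.5
    p[-1] <- p0 + cumsum(slope_pct_fun(mids))
  }
  p
}

#' Simulate the oxygen trace of one stepped-velocity swim trial
#'
#' Builds a 1 Hz trace following the trial schedule: a 10-min empty-chamber
#' background window, habituation at the holding speed, then repeated
#' sealed measurement periods (oxygen declining at the rate implied by the
#' fish's true speed-dependent uptake plus microbial background) and flush
#' periods (exponential relaxation to full saturation), ending when the
#' fish fatigues at its true Ucrit, followed by a final background window.
#' A measurement period is cut short if oxygen would fall below the
#' saturation floor. Gaussian sensor noise is added last.
#'
#' @param fish One row of the data frame from [generate_cohort()].
#' @param protocol A [swim_protocol()] (its increment should be the fish's
#'   body length for a nominal 1 BL s^-1 step).
#' @param chamber A [chamber_spec()].
#' @param config A [cohort_config()] (noise, flush and water-condition
#'   settings).
#' @return An `oxygen_trace` data frame with attributes `fatigue_time_s`
#'   (trial time of fatigue) and `fatigued_in_habituation` (logical).
#' @export
simulate_swim_trial <- function(fish, protocol, chamber, config) {
  cond <- gas_conditions(config$temperature, config$salinity,
                         config$pressure_mmhg)
  sol <- o2_solubility(cond)
  v_eff <- effective_volume_l(chamber, fish$mass_mg, "respirometer")
  hab_n <- round(protocol$habituation_min * 60)
  meas_n <- round(protocol$interval_min * 60)
  flush_n <- round(protocol$flush_min * 60)
  bg_n <- 600L
  vi <- protocol$increment_cm_s

  if (fish$true_ucrit_cm_s < protocol$habituation_speed_cm_s) {
    tr <- data.frame(time_s = seq_len(bg_n) - 1,
                     o2_percent_sat = rep(100, bg_n),
                     temp_c = rep(config$temperature, bg_n),
                     phase = rep("background_pre", bg_n),
                     speed_cm_s = rep(0, bg_n))
    tr <- validate_trace(tr)
    attr(tr, "fatigued_in_habituation") <- TRUE
    return(tr)
  }

  n_steps_full <- floor(fish$true_ucrit_cm_s / vi)
  frac <- fish$true_ucrit_cm_s / vi - n_steps_full
  t_fatigue_s <- round(frac * meas_n)
  # a partial window too short to regress is folded into the boundary case
  if (t_fatigue_s < 2) t_fatigue_s <- 0

  # background drift: linear in trial time between the pre- and post-window
  # midpoints, mirroring microbial growth over the trial
  n_meas_windows <- n_steps_full + (t_fatigue_s > 0)
  approx_trial_len <- bg_n + hab_n +
    n_meas_windows * (meas_n + flush_n) + flush_n + bg_n
  t_pre_mid <- (bg_n - 1) / 2
  t_post_mid <- approx_trial_len - bg_n + (bg_n - 1) / 2
  bg_fun <- function(t) {
    tt <- pmin(pmax(t, t_pre_mid), t_post_mid)
    fish$bg_pre_slope + (fish$bg_post_slope - fish$bg_pre_slope) *
      (tt - t_pre_mid) / (t_post_mid - t_pre_mid)
  }
  bg_pct <- function(t) bg_fun(t) / sol * 100

  time <- numeric(0); o2 <- numeric(0); phase <- character(0)
  speed <- numeric(0)
  t_now <- 0
  add_phase <- function(p, ph, spd) {
    n <- length(p)
    time <<- c(time, t_now + seq_len(n) - 1)
    o2 <<- c(o2, p)
    phase <<- c(phase, rep(ph, n))
    speed <<- c(speed, rep(spd, n))
    t_now <<- t_now + n
  }

  # pre-trial background, starts at full saturation
  add_phase(.decline_segment(100, bg_n, 0, bg_pct), "background_pre", 0)
  # habituation: flush pump on, chamber held at saturation
  add_phase(rep(100, hab_n), "habituation", 0)

  p_now <- 100
  fatigue_time <- NA_real_
  steps <- seq_len(n_meas_windows)
  for (k in steps) {
    u <- k * vi
    last_partial <- (k == n_steps_full + 1)
    n_this <- if (last_partial) t_fatigue_s else meas_n
    fish_slope_pct <- -(.true_mo2(fish, u) * fish$mass_mg / 1000 / 3600 /
                          v_eff) / sol * 100
    seg_fun <- function(m) fish_slope_pct + bg_pct(m)
    step_start <- t_now
    seg <- .decline_segment(p_now, n_this, t_now, seg_fun)
    # saturation floor: truncate the sealed period where the floor is
    # crossed (early flush), unless this is the fatigue window
    if (!last_partial && any(seg < config$saturation_floor)) {
      cut <- which(seg < config$saturation_floor)[1]
      if (cut > 2) seg <- seg[seq_len(cut - 1)]
    }
    add_phase(seg, "measure", u)
    p_now <- seg[length(seg)]
    # the fish swims to the scheduled end of the step even when the sealed
    # window was cut short by the saturation floor
    if (last_partial) {
      fatigue_time <- step_start + t_fatigue_s
    } else if (k == n_steps_full && t_fatigue_s == 0) {
      fatigue_time <- step_start + meas_n
    }
    # flush after every completed step; after the fatigue window the fish
    # is removed and the chamber is flushed before the final background
    deficit <- 100 - p_now
    fl <- 100 - deficit * exp(-(seq_len(flush_n)) / config$flush_tau_s)
    add_phase(fl, "flush", 0)
    p_now <- fl[length(fl)]
    if (last_partial) break
  }
  if (is.na(fatigue_time)) fatigue_time <- t_now
  # post-trial background on the re-aerated empty chamber
  add_phase(.decline_segment(100, bg_n, t_now, bg_pct),
            "background_post", 0)

  if (config$sensor_noise_sd > 0)
    o2 <- pmax(o2 + stats::rnorm(length(o2), 0, config$sensor_noise_sd), 0)
  tr <- data.frame(time_s = time, o2_percent_sat = o2,
                   temp_c = rep(config$temperature, length(time)),
                   phase = phase, speed_cm_s = speed,
                   stringsAsFactors = FALSE)
  tr <- validate_trace(tr)
  attr(tr, "fatigue_time_s") <- fatigue_time
  attr(tr, "fatigued_in_habituation") <- FALSE
  tr
}

#' Simulate one closed-vial loss-of-equilibrium trial
#'
#' Well-mixed closed-chamber drawdown: the larva's resting oxygen uptake
#' removes oxygen from the vial water at a constant rate (optionally
#' declining in proportion to ambient oxygen below a conformity threshold)
#' until the fish's true LOE threshold is reached. The recorded LOE level
#' is the trace value at the first observer check at or after the
#' crossing; with a check interval of 0 the crossing is recorded exactly.
#'
#' @param fish One row of the data frame from [generate_cohort()].
#' @param chamber A [chamber_spec()]; its vial volume is used.
#' @param config A [cohort_config()].
#' @return A list with `trace` (an `oxygen_trace`, phases all `measure`),
#'   `loe_percent_recorded` and `t_loe_s` (crossing time, seconds).
#' @export
simulate_loe_trial <- function(fish, chamber, config) {
  cond <- gas_conditions(config$temperature, config$salinity,
                         config$pressure_mmhg)
  sol <- o2_solubility(cond)
  v_eff <- effective_volume_l(chamber, fish$mass_mg, "vial")
  rate_pct <- (fish$true_smr * fish$mass_mg / 1000 / 3600 / v_eff) /
    sol * 100  # % air sat per second
  thr <- fish$true_loe_percent
  conf <- config$conform_below_percent
  if (conf <= 0 || thr >= conf) {
    t_loe <- (100 - thr) / rate_pct
  } else {
    # linear decline to the conformity threshold, then exponential decay
    t1 <- (100 - conf) / rate_pct
    t_loe <- t1 + conf / rate_pct * log(conf / thr)
  }
  if (config$loe_check_interval_s > 0) {
    ci <- config$loe_check_interval_s
    t_rec <- ceiling(t_loe / ci) * ci
  } else {
    t_rec <- t_loe
  }
  pct_at <- function(t) {
    if (conf <= 0) return(pmax(100 - rate_pct * t, 0))
    t1 <- (100 - conf) / rate_pct
    ifelse(t <= t1, 100 - rate_pct * t,
           conf * exp(-rate_pct / conf * (t - t1)))
  }
  recorded <- pct_at(t_rec)
  n <- ceiling(t_rec) + 1
  tt <- seq_len(n) - 1
  o2 <- pct_at(tt)
  if (config$sensor_noise_sd > 0)
    o2 <- pmax(o2 + stats::rnorm(n, 0, config$sensor_noise_sd), 0)
  tr <- data.frame(time_s = tt, o2_percent_sat = o2,
                   temp_c = rep(config$temperature, n),
                   phase = rep("measure", n),
                   speed_cm_s = rep(0, n), stringsAsFactors = FALSE)
  list(trace = validate_trace(tr), loe_percent_recorded = recorded,
       t_loe_s = t_loe)
}

#' Simulate a full study: swim trials and LOE trials
#'
#' Seeds the RNG once from the config, generates the swim cohort and one
#' trace per fish (with a per-fish velocity increment of one body length
#' per second), then generates an independent LOE cohort at the configured
#' LOE ages and group sizes and simulates a closed-vial trial per fish.
#'
#' @param config A [cohort_config()].
#' @param chamber A [chamber_spec()].
#' @param interval_min,flush_min,habituation_min Trial schedule, minutes
#'   (defaults 20 / 3 / 60).
#' @return A `reefresp_cohort` list: `fish` (swim cohort with hidden
#'   truth), `traces` (named list of `oxygen_trace`), `protocols` (named
#'   list of per-fish [swim_protocol()]), `loe` (data frame of LOE trials
#'   with truth and recorded values), `config`, `chamber`, `conditions`.
#' @export
simulate_cohort <- function(config = cohort_config(),
                            chamber = chamber_spec(),
                            interval_min = 20, flush_min = 3,
                            habituation_min = 60) {
  fish <- generate_cohort(config)  # seeds the RNG
  protocols <- traces <- vector("list", nrow(fish))
  names(protocols) <- names(traces) <- fish$fish_id
  for (i in seq_len(nrow(fish))) {
    pr <- swim_protocol(interval_min = interval_min,
                        flush_min = flush_min,
                        increment_cm_s = fish$length_cm[i],
                        habituation_min = habituation_min)
    protocols[[i]] <- pr
    traces[[i]] <- simulate_swim_trial(fish[i, ], pr, chamber, config)
  }
  loe_cfg <- config
  loe_cfg$ages <- config$loe_ages
  loe_cfg$n_per_age <- config$loe_n
  loe_fish <- .draw_cohort(loe_cfg)  # continues the seeded stream
  loe_rows <- lapply(seq_len(nrow(loe_fish)), function(i) {
    sim <- simulate_loe_trial(loe_fish[i, ], chamber, config)
    data.frame(fish_id = sprintf("loe%03d", i),
               age_dph = loe_fish$age_dph[i],
               mass_mg = loe_fish$mass_mg[i],
               loe_percent_sat = sim$loe_percent_recorded,
               true_loe_percent = loe_fish$true_loe_percent[i],
               t_loe_s = sim$t_loe_s,
               temp_c = config$temperature,
               salinity_ppt = config$salinity,
               pressure_mmhg = config$pressure_mmhg,
               stringsAsFactors = FALSE)
  })
  structure(list(fish = fish, traces = traces, protocols = protocols,
                 loe = do.call(rbind, loe_rows), config = config,
                 chamber = chamber,
                 conditions = gas_conditions(config$temperature,
                                             config$salinity,
                                             config$pressure_mmhg)),
            class = "reefresp_cohort")
}

#' Write a simulated cohort to disk
#'
#' Emits one trace CSV per fish (the documented respirometry dialect), a
#' fish metadata CSV, an LOE trial CSV, and a hidden-truth CSV for testing.
#'
#' @param cohort A `reefresp_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  trace_dir <- file.path(dir, "traces")
  dir.create(trace_dir, showWarnings = FALSE)
  for (id in names(cohort$traces))
    write_trace(cohort$traces[[id]],
                file.path(trace_dir, paste0(id, ".csv")))
  meta <- cohort$fish[, c("fish_id", "age_dph", "mass_mg", "length_cm")]
  meta$clutch_id <- NA_character_
  utils::write.csv(
    meta[, c("fish_id", "clutch_id", "age_dph", "mass_mg", "length_cm")],
    file.path(dir, "metadata.csv"), row.names = FALSE)
  utils::write.csv(
    cohort$loe[, c("fish_id", "age_dph", "mass_mg", "loe_percent_sat",
                   "temp_c", "salinity_ppt", "pressure_mmhg")],
    file.path(dir, "loe.csv"), row.names = FALSE)
  utils::write.csv(cohort$fish, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}
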