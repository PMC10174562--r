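#' Respirometry chamber geometry
#'
#' Volumes used to turn an oxygen depletion slope into a whole-animal oxygen
#' uptake rate. The effective respirometer volume is the chamber volume minus
#' the volume displaced by the fish, which is estimated from body mass
#' assuming a tissue density of 1.0 g ml^-1.
#'
#' @param respirometer_volume_ml Working-section volume of the swimming
#'   respirometer, ml (default 3.5).
#' @param vial_volume_ml Closed-vial volume used in hypoxia trials, ml
#'   (default 1.5).
#' @param fish_density_g_ml Assumed tissue density for the displacement
#'   correction, g ml^-1 (default 1.0).
#' @return A `chamber_spec` list.
#' @examples
#' chamber_spec()
#' @export
chamber_spec <- function(respirometer_volume_ml = 3.5, vial_volume_ml = 1.5,
                         fish_density_g_ml = 1.0) {
  stopifnot(respirometer_volume_ml > 0, vial_volume_ml > 0,
            fish_density_g_ml > 0)
  structure(list(respirometer_volume_ml = respirometer_volume_ml,
                 vial_volume_ml = vial_volume_ml,
                 fish_density_g_ml = fish_density_g_ml),
            class = "chamber_spec")
}

#' Effective chamber volume for a given fish
#'
#' @param chamber A [chamber_spec()].
#' @param mass_mg Fish body mass, mg.
#' @param which `"respirometer"` or `"vial"`.
#' @return Effective (water) volume in litres.
#' @export
effective_volume_l <- function(chamber, mass_mg,
                               which = c("respirometer", "vial")) {
  which <- match.arg(which)
  vol_ml <- switch(which, respirometer = chamber$respirometer_volume_ml,
                   vial = chamber$vial_volume_ml)
  fish_ml <- (mass_mg / 1000) / chamber$fish_density_g_ml
  eff <- vol_ml - fish_ml
  if (eff <= 0)
    stop("fish volume (", format(fish_ml), " ml) exceeds chamber volume (",
         vol_ml, " ml)")
  eff / 1000
}

#' One fish's identity and morphometrics
#'
#' @param fish_id Character identifier.
#' @param age_dph Age in days post hatch.
#' @param mass_mg Body mass, mg (> 0).
#' @param length_cm Total body length, cm (> 0).
#' @param clutch_id Optional clutch identifier.
#' @return A `fish_record` list.
#' @export
fish_record <- function(fish_id, age_dph, mass_mg, length_cm,
                        clutch_id = NA_character_) {
  stopifnot(mass_mg > 0, length_cm > 0, age_dph >= 0)
  structure(list(fish_id = as.character(fish_id), clutch_id = clutch_id,
                 age_dph = age_dph, mass_mg = mass_mg,
                 length_cm = length_cm),
            class = "fish_record")
}

.trace_phases <- c("habituation", "measure", "flush",
                   "background_pre", "background_post")
.trace_columns <- c("time_s", "o2_percent_sat", "temp_c", "phase",
                    "speed_cm_s")

validate_trace <- function(trace) {
  missing <- setdiff(.trace_columns, names(trace))
  if (length(missing))
    stop("trace is missing column(s): ", paste(missing, collapse = ", "))
  bad_phase <- which(!trace$phase %in% .trace_phases)
  if (length(bad_phase))
    stop("unknown phase label '", trace$phase[bad_phase[1]],
         "' at row ", bad_phase[1])
  dt <- diff(trace$time_s)
  if (any(dt <= 0)) {
    k <- which(dt <= 0)[1] + 1L
    stop("time not strictly increasing at row ", k)
  }
  if (any(trace$o2_percent_sat < 0)) {
    k <- which(trace$o2_percent_sat < 0)[1]
    stop("negative oxygen reading at row ", k)
  }
  class(trace) <- unique(c("oxygen_trace", class(trace)))
  trace
}

#' Read an oxygen logger trace
#'
#' Reads the package's documented trace CSV dialect: UTF-8, '.' decimal,
#' header `time_s,o2_percent_sat,temp_c,phase,speed_cm_s`, one file per fish
#' per trial. Time is in seconds from trial start, oxygen in % air
#' saturation, and `phase` one of `habituation`, `measure`, `flush`,
#' `background_pre`, `background_post`.
#'
#' @param path Path to the CSV file.
#' @return A validated `oxygen_trace` data frame.
#' @seealso [write_trace()]
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("no such trace file: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_trace(raw)
}

#' Write an oxygen trace to CSV
#'
#' Inverse of [read_trace()]; a write/read cycle reproduces the trace
#' bit-exactly (numbers are written with full precision).
#'
#' @param trace An `oxygen_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  trace <- validate_trace(as.data.frame(trace))
  df <- as.data.frame(trace)[, .trace_columns]
  df$time_s <- format(df$time_s, digits = 15, trim = TRUE,
                      scientific = FALSE)
  df$o2_percent_sat <- format(df$o2_percent_sat, digits = 17, trim = TRUE)
  df$temp_c <- format(df$temp_c, digits = 17, trim = TRUE)
  df$speed_cm_s <- format(df$speed_cm_s, digits = 17, trim = TRUE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Locate the sealed measurement windows of a trace
#'
#' @param trace An `oxygen_trace`.
#' @return A data frame with one row per contiguous `measure` phase:
#'   `start` and `end` row indices, `speed_cm_s`, `t_start`, `t_end`
#'   (seconds) and `n` samples.
#' @export
measure_windows <- function(trace) {
  trace <- validate_trace(as.data.frame(trace))
  is_meas <- trace$phase == "measure"
  if (!any(is_meas))
    return(data.frame(start = integer(), end = integer(),
                      speed_cm_s = numeric(), t_start = numeric(),
                      t_end = numeric(), n = integer()))
  r <- rle(is_meas)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  starts <- starts[keep]; ends <- ends[keep]
  data.frame(start = starts, end = ends,
             speed_cm_s = trace$speed_cm_s[starts],
             t_start = trace$time_s[starts],
             t_end = trace$time_s[ends],
             n = ends - starts + 1L)
}

#' Fit the oxygen depletion slope of one measurement window
#'
#' Ordinary least-squares regression of dissolved oxygen (mg L^-1, converted
#' from % air saturation at the window's mean temperature) against time
#' (seconds). The slope of this regression is the raw, uncorrected oxygen
#' depletion rate of the sealed chamber.
#'
#' @param trace An `oxygen_trace`.
#' @param phase_index Which `measure` window (1-based, in time order).
#' @param cond A [gas_conditions()] object giving salinity and pressure for
#'   the % saturation to mg L^-1 conversion; its temperature is replaced by
#'   the window's mean measured temperature.
#' @param trim_seconds Leading seconds of the window to drop before fitting
#'   (mixing/equilibration guard; default 0).
#' @return A list with `slope` (mg O2 L^-1 s^-1, signed; depletion is
#'   negative), `r_squared`, `n`, `speed_cm_s`, `t_mid` (window midpoint,
#'   seconds) and `min_percent_sat`.
#' @export
fit_slope <- function(trace, phase_index, cond, trim_seconds = 0) {
  win <- measure_windows(trace)
  if (phase_index < 1 || phase_index > nrow(win))
    stop("phase_index ", phase_index, " out of range: trace has ",
         nrow(win), " measure window(s)")
  w <- win[phase_index, ]
  idx <- seq(w$start, w$end)
  tt <- trace$time_s[idx]
  keep <- tt >= tt[1] + trim_seconds
  idx <- idx[keep]; tt <- tt[keep]
  if (length(unique(tt)) < 2)
    stop("measurement window degenerate after trimming (",
         length(tt), " samples)")
  temp_mean <- mean(trace$temp_c[idx])
  cw <- gas_conditions(temp_mean, cond$salinity, cond$barometric_pressure,
                       o2_mole_fraction = cond$o2_mole_fraction)
  y <- percent_sat_to_do(trace$o2_percent_sat[idx], cw)
  fit <- stats::lm(y ~ tt)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  list(slope = unname(stats::coef(fit)[2]), r_squared = r2,
       n = length(idx), speed_cm_s = w$speed_cm_s,
       t_mid = (tt[1] + tt[length(tt)]) / 2,
       min_percent_sat = min(trace$o2_percent_sat[idx]))
}

.background_slope <- function(trace, phase, cond) {
  idx <- which(trace$phase == phase)
  if (!length(idx)) return(NULL)
  tt <- trace$time_s[idx]
  temp_mean <- mean(trace$temp_c[idx])
  cw <- gas_conditions(temp_mean, cond$salinity, cond$barometric_pressure,
                       o2_mole_fraction = cond$o2_mole_fraction)
  y <- percent_sat_to_do(trace$o2_percent_sat[idx], cw)
  fit <- stats::lm(y ~ tt)
  list(slope = unname(stats::coef(fit)[2]), t_mid = mean(range(tt)))
}

#' Background (microbial) respiration rate as a function of trial time
#'
#' Fits the oxygen depletion slope of the 10-minute empty-chamber
#' measurements taken before and after the trial and interpolates linearly
#' in time between them, so that microbial growth over the trial is
#' accounted for. If only one background window is available its slope is
#' used as a constant.
#'
#' @param pre An `oxygen_trace` containing a `background_pre` phase, or
#'   `NULL`.
#' @param post An `oxygen_trace` containing a `background_post` phase, or
#'   `NULL`. `pre` and `post` may be the same trace.
#' @param cond A [gas_conditions()] object.
#' @return A function of trial time (seconds) returning the background slope
#'   in mg O2 L^-1 s^-1.
#' @export
background_rate <- function(pre = NULL, post = NULL, cond) {
  b_pre <- if (!is.null(pre)) .background_slope(pre, "background_pre", cond)
  b_post <- if (!is.null(post))
    .background_slope(post, "background_post", cond)
  if (is.null(b_pre) && is.null(b_post))
    stop("no background window found in either trace")
  if (is.null(b_pre)) return(function(t) rep(b_post$slope, length(t)))
  if (is.null(b_post)) return(function(t) rep(b_pre$slope, length(t)))
  t1 <- b_pre$t_mid; t2 <- b_post$t_mid
  s1 <- b_pre$slope; s2 <- b_post$slope
  if (t2 <= t1) return(function(t) rep(mean(c(s1, s2)), length(t)))
  function(t) {
    t <- pmin(pmax(t, t1), t2)
    s1 + (s2 - s1) * (t - t1) / (t2 - t1)
  }
}

#' Mass-specific oxygen uptake rate from a depletion slope
#'
#' Computes MO2 (mg O2 g^-1 h^-1) from a background-corrected chamber slope:
#' `MO2 = |slope - background| * V_eff * 3600 / M`, where `V_eff` is the
#' respirometer volume minus the fish's displacement volume (litres) and `M`
#' the body mass in grams. The factor 3600 converts the per-second slope to
#' an hourly rate.
#'
#' @param slope Raw chamber slope, mg O2 L^-1 s^-1 (depletion negative).
#' @param t_mid Trial time (seconds) at the window midpoint, at which the
#'   background function is evaluated.
#' @param fish A [fish_record()].
#' @param chamber A [chamber_spec()].
#' @param background A function of trial time returning the background slope
#'   (as from [background_rate()]), or `NULL` for no correction.
#' @return A list with `mo2` (mg O2 g^-1 h^-1) and `qc_flags` (character
#'   vector; contains `"background_exceeds_slope"` when the background
#'   correction exceeds the measured depletion, in which case `mo2` is 0).
#' @examples
#' f <- fish_record("f1", 9, mass_mg = 4, length_cm = 0.8)
#' compute_mo2(-5e-4, 0, f, chamber_spec(respirometer_volume_ml = 3.5), NULL)
#' @export
compute_mo2 <- function(slope, t_mid, fish, chamber, background = NULL) {
  v_eff <- effective_volume_l(chamber, fish$mass_mg, "respirometer")
  bg <- if (is.null(background)) 0 else background(t_mid)
  slope_fish <- slope - bg
  flags <- character()
  if (slope_fish > 0) {
    # corrected fish slope implies oxygen production: background estimate
    # exceeds the measured depletion
    flags <- "background_exceeds_slope"
    mo2 <- 0
  } else {
    mo2 <- abs(slope_fish) * v_eff * 3600 / (fish$mass_mg / 1000)
  }
  list(mo2 = mo2, qc_flags = flags)
}

#' Quality-control flags for one measurement window
#'
#' Flags a window when any sample falls below the air-saturation floor used
#' during trials (90% by default, protecting the fish from hypoxia), when
#' the depletion regression is poor, or when the window is short.
#'
#' @param slope_fit Result of [fit_slope()].
#' @param r2_threshold Minimum acceptable r-squared (default 0.95).
#' @param min_samples Minimum window length in samples (default 30).
#' @param saturation_floor Minimum acceptable % air saturation (default 90).
#' @return Character vector drawn from `low_r2`, `below_90pct_sat`,
#'   `short_window` (empty when the window is clean).
#' @export
qc_step <- function(slope_fit, r2_threshold = 0.95, min_samples = 30,
                    saturation_floor = 90) {
  flags <- character()
  if (slope_fit$min_percent_sat < saturation_floor)
    flags <- c(flags, "below_90pct_sat")
  if (slope_fit$r_squared < r2_threshold) flags <- c(flags, "low_r2")
  if (slope_fit$n < min_samples) flags <- c(flags, "short_window")
  flags
}

#' Analyse every measurement window of a swim trial trace
#'
#' Convenience wrapper running [fit_slope()], [compute_mo2()] and
#' [qc_step()] over all `measure` windows of a trace.
#'
#' @param trace An `oxygen_trace`.
#' @param fish A [fish_record()].
#' @param chamber A [chamber_spec()].
#' @param cond A [gas_conditions()] object.
#' @param background Background slope function or `NULL`.
#' @param trim_seconds Leading trim passed to [fit_slope()].
#' @param r2_threshold,min_samples,saturation_floor Passed to [qc_step()].
#' @return A data frame of step measurements: `speed_cm_s`, `slope`,
#'   `r_squared`, `mo2`, `n`, `t_mid`, `qc_flags` (comma-joined string,
#'   empty if clean).
#' @export
step_measurements <- function(trace, fish, chamber, cond,
                              background = NULL, trim_seconds = 0,
                              r2_threshold = 0.95, min_samples = 30,
                              saturation_floor = 90) {
  win <- measure_windows(trace)
  if (!nrow(win)) stop("trace has no measurement windows")
  rows <- lapply(seq_len(nrow(win)), function(i) {
    sf <- fit_slope(trace, i, cond, trim_seconds)
    m <- compute_mo2(sf$slope, sf$t_mid, fish, chamber, background)
    flags <- c(qc_step(sf, r2_threshold, min_samples, saturation_floor),
               m$qc_flags)
    data.frame(speed_cm_s = sf$speed_cm_s, slope = sf$slope,
               r_squared = sf$r_squared, mo2 = m$mo2, n = sf$n,
               t_mid = sf$t_mid,
               qc_flags = paste(flags, collapse = ","))
  })
  do.call(rbind, rows)
}

#' Read a fish metadata table
#'
#' Columns: `fish_id,clutch_id,age_dph,mass_mg,length_cm`.
#'
#' @param path CSV path.
#' @return A data frame, one row per fish.
#' @export
read_fish_metadata <- function(path) {
  if (!file.exists(path)) stop("no such metadata file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("fish_id", "age_dph", "mass_mg", "length_cm")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("metadata missing column(s): ", paste(missing, collapse = ", "))
  if (any(df$mass_mg <= 0)) stop("non-positive mass in metadata")
  if (any(df$length_cm <= 0)) stop("non-positive length in metadata")
  df
}
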