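#' Stepped-velocity swim protocol
#'
#' The schedule of a critical-swimming-speed trial: after a habituation
#' period at a gentle holding speed, water velocity is raised by one
#' increment (nominally 1 body length s^-1, recorded per fish in cm s^-1)
#' every interval until the fish fatigues against the downstream barrier.
#' Each interval consists of a sealed measurement period followed by a flush
#' period that restores full air saturation.
#'
#' @param interval_min Duration of each speed step, minutes (default 20).
#' @param flush_min Flush duration between steps, minutes (default 3).
#' @param increment_cm_s Velocity increment per step, cm s^-1.
#' @param habituation_min Habituation duration, minutes (default 60).
#' @param habituation_speed_cm_s Holding speed during habituation, cm s^-1
#'   (defaults to one increment).
#' @return A `swim_protocol` list.
#' @export
swim_protocol <- function(interval_min = 20, flush_min = 3,
                          increment_cm_s = 1, habituation_min = 60,
                          habituation_speed_cm_s = increment_cm_s) {
  stopifnot(interval_min > 0, flush_min > 0, increment_cm_s > 0,
            habituation_min > 0, habituation_speed_cm_s >= 0)
  structure(list(interval_min = interval_min, flush_min = flush_min,
                 increment_cm_s = increment_cm_s,
                 habituation_min = habituation_min,
                 habituation_speed_cm_s = habituation_speed_cm_s),
            class = "swim_protocol")
}

#' Critical swimming speed
#'
#' `Ucrit = Vf + (T / t) * Vi`, where `Vf` is the penultimate (last fully
#' completed) speed, `T` the time swum at the fatigue speed, `t` the step
#' interval and `Vi` the velocity increment.
#'
#' @param vf Penultimate speed, cm s^-1 (>= 0).
#' @param time_at_fatigue_min Time swum into the fatigue step, minutes, in
#'   \[0, `interval_min`\].
#' @param interval_min Step interval, minutes.
#' @param increment_cm_s Velocity increment, cm s^-1.
#' @return Ucrit in cm s^-1.
#' @examples
#' compute_ucrit(4, 10, 20, 1)  # 4.5
#' @export
compute_ucrit <- function(vf, time_at_fatigue_min, interval_min,
                          increment_cm_s) {
  if (any(vf < 0)) stop("penultimate speed must be non-negative")
  if (any(increment_cm_s <= 0)) stop("increment must be positive")
  if (any(interval_min <= 0)) stop("interval must be positive")
  if (any(time_at_fatigue_min < 0 | time_at_fatigue_min > interval_min))
    stop("time at fatigue speed must lie in [0, interval]")
  vf + (time_at_fatigue_min / interval_min) * increment_cm_s
}

#' Convert Ucrit to body lengths per second
#'
#' @param ucrit_cm_s Critical swimming speed, cm s^-1.
#' @param body_length_cm Total body length, cm (> 0).
#' @return Ucrit in BL s^-1.
#' @export
ucrit_in_body_lengths <- function(ucrit_cm_s, body_length_cm) {
  if (any(body_length_cm <= 0)) stop("body length must be positive")
  ucrit_cm_s / body_length_cm
}

#' Extract fatigue speed and time from a trial trace
#'
#' The trial ends when the fish fatigues, so the final `measure` window of a
#' trace is truncated at the fatigue time. `Vf` is the speed of the last
#' fully completed step and `T` the time swum into the step during which
#' fatigue occurred. Fatigue exactly at a step boundary (final window
#' spanning the full interval) counts as `T = 0` of the next, never-started
#' step, so `Ucrit` equals the completed speed.
#'
#' A trace carrying a `fatigue_time_s` attribute (as produced by
#' [simulate_swim_trial()]) is read from that annotation directly; without
#' it the fatigue point is inferred from the truncation of the final
#' window, which is correct whenever the final window was not itself cut
#' short by the saturation floor.
#'
#' @param trace An `oxygen_trace` from a swim trial.
#' @param protocol A [swim_protocol()].
#' @return A list with `vf` (cm s^-1), `time_at_fatigue_min`,
#'   `fatigue_speed_cm_s` and `flagged` (TRUE when fatigue occurred during
#'   the first step or habituation, in which case Ucrit is undefined and
#'   `vf` is `NA`).
#' @export
extract_fatigue <- function(trace, protocol) {
  win <- measure_windows(trace)
  if (!nrow(win))
    return(list(vf = NA_real_, time_at_fatigue_min = NA_real_,
                fatigue_speed_cm_s = NA_real_, flagged = TRUE))
  m <- nrow(win)
  ft <- attr(trace, "fatigue_time_s")
  if (!is.null(ft) && is.finite(ft)) {
    full_s <- protocol$interval_min * 60
    last <- which(win$t_start <= ft)
    if (!length(last))
      return(list(vf = NA_real_, time_at_fatigue_min = NA_real_,
                  fatigue_speed_cm_s = NA_real_, flagged = TRUE))
    k <- max(last)
    into_s <- ft - win$t_start[k]
    if (into_s >= full_s - 0.5)
      return(list(vf = win$speed_cm_s[k], time_at_fatigue_min = 0,
                  fatigue_speed_cm_s = win$speed_cm_s[k] +
                    protocol$increment_cm_s,
                  flagged = FALSE))
    if (k == 1)
      return(list(vf = NA_real_, time_at_fatigue_min = into_s / 60,
                  fatigue_speed_cm_s = win$speed_cm_s[1], flagged = TRUE))
    return(list(vf = win$speed_cm_s[k - 1],
                time_at_fatigue_min = into_s / 60,
                fatigue_speed_cm_s = win$speed_cm_s[k], flagged = FALSE))
  }
  # window duration: samples span t_end - t_start; at 1 Hz a full interval
  # of t minutes spans t*60 samples, i.e. t*60 - 1 seconds between first
  # and last sample
  dur_s <- win$t_end[m] - win$t_start[m] + 1
  full_s <- protocol$interval_min * 60
  if (dur_s >= full_s - 0.5) {
    # final step fully completed: fatigue at the boundary of the next step
    return(list(vf = win$speed_cm_s[m], time_at_fatigue_min = 0,
                fatigue_speed_cm_s = win$speed_cm_s[m] +
                  protocol$increment_cm_s,
                flagged = FALSE))
  }
  if (m == 1) {
    # fatigued during the very first step: no completed speed exists
    return(list(vf = NA_real_,
                time_at_fatigue_min = dur_s / 60,
                fatigue_speed_cm_s = win$speed_cm_s[1], flagged = TRUE))
  }
  list(vf = win$speed_cm_s[m - 1], time_at_fatigue_min = dur_s / 60,
       fatigue_speed_cm_s = win$speed_cm_s[m], flagged = FALSE)
}

#' Critical swimming speed of one trial trace
#'
#' @param trace An `oxygen_trace` from a swim trial.
#' @param protocol A [swim_protocol()].
#' @param body_length_cm Body length for the BL s^-1 conversion, cm.
#' @return A list with `ucrit_cm_s`, `ucrit_bl_s`, `vf`,
#'   `time_at_fatigue_min` and `flagged`.
#' @export
trial_ucrit <- function(trace, protocol, body_length_cm) {
  f <- extract_fatigue(trace, protocol)
  if (f$flagged)
    return(list(ucrit_cm_s = NA_real_, ucrit_bl_s = NA_real_, vf = f$vf,
                time_at_fatigue_min = f$time_at_fatigue_min,
                flagged = TRUE))
  u <- compute_ucrit(f$vf, f$time_at_fatigue_min, protocol$interval_min,
                     protocol$increment_cm_s)
  list(ucrit_cm_s = u,
       ucrit_bl_s = ucrit_in_body_lengths(u, body_length_cm),
       vf = f$vf, time_at_fatigue_min = f$time_at_fatigue_min,
       flagged = FALSE)
}
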