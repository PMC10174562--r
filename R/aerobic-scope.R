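#' Fit the swimming speed--oxygen uptake relationship of one fish
#'
#' Fits both candidate models of mass-specific oxygen uptake against
#' swimming speed `u`:
#' a straight line `R(u) = a + b*u` (ordinary least squares) and a power
#' curve `R(u) = a + c*u^b` (nonlinear least squares, initialised from a
#' log-log regression of the uptake above its minimum on speed). The model
#' with the lower AIC is selected. The intercept `a` of the selected model
#' estimates the standard metabolic rate (uptake extrapolated to zero
#' speed); a non-positive intercept means no physiologically meaningful line
#' could be drawn and the fish is excluded from oxygen uptake analysis.
#'
#' The power model is attempted only when at least four distinct speeds are
#' available: with three points its three mean parameters interpolate the
#' data exactly and the AIC comparison is meaningless.
#'
#' @param steps Data frame of step measurements with columns `speed_cm_s`
#'   and `mo2` (as from [step_measurements()]). Rows with `NA` uptake are
#'   dropped.
#' @param epsilon Positive guard added inside the log-log initialiser
#'   (default 1e-6).
#' @return A `metabolic_profile` list: `model` ("linear" or "power"), `a`,
#'   `b`, `c` (NA for the linear model), `aic_linear`, `aic_power`, `smr`,
#'   `mmr`, `aas`, `fas`, `excluded` (logical), `reason`, and `n_steps`.
#'   SMR/MMR/AAS/FAS are `NA` when `excluded`.
#' @examples
#' st <- data.frame(speed_cm_s = 1:5, mo2 = 1 + 0.05 * (1:5))
#' fit_speed_mo2(st)$model  # "linear"
#' @export
fit_speed_mo2 <- function(steps, epsilon = 1e-6) {
  stopifnot(is.data.frame(steps),
            all(c("speed_cm_s", "mo2") %in% names(steps)))
  ok <- is.finite(steps$speed_cm_s) & is.finite(steps$mo2)
  u <- steps$speed_cm_s[ok]
  y <- steps$mo2[ok]
  prof <- list(model = NA_character_, a = NA_real_, b = NA_real_,
               c = NA_real_, aic_linear = NA_real_, aic_power = NA_real_,
               smr = NA_real_, mmr = NA_real_, aas = NA_real_,
               fas = NA_real_, excluded = FALSE, reason = NA_character_,
               n_steps = length(u))
  class(prof) <- "metabolic_profile"
  if (length(unique(u)) < 3) {
    prof$excluded <- TRUE
    prof$reason <- "insufficient_steps"
    return(prof)
  }
  lin <- stats::lm(y ~ u)
  prof$aic_linear <- stats::AIC(lin)
  pow <- NULL
  if (length(unique(u)) >= 4) {
    pow <- tryCatch({
      y0 <- y - min(y) + epsilon
      init <- stats::lm(log(y0) ~ log(u))
      start <- list(a = min(y), c = exp(unname(stats::coef(init)[1])),
                    b = max(unname(stats::coef(init)[2]), 0.1))
      minpack.lm::nlsLM(y ~ a + c * u^b, start = start,
                        control = minpack.lm::nls.lm.control(
                          maxiter = 200, ftol = 1e-12, ptol = 1e-12))
    }, error = function(e) NULL)
    if (!is.null(pow)) prof$aic_power <- stats::AIC(pow)
  }
  use_power <- !is.null(pow) && is.finite(prof$aic_power) &&
    prof$aic_power < prof$aic_linear
  if (use_power) {
    cf <- stats::coef(pow)
    prof$model <- "power"
    prof$a <- unname(cf["a"]); prof$b <- unname(cf["b"])
    prof$c <- unname(cf["c"])
  } else {
    cf <- stats::coef(lin)
    prof$model <- "linear"
    prof$a <- unname(cf[1]); prof$b <- unname(cf[2])
  }
  smr <- derive_smr(prof)
  if (is.na(smr)) {
    prof$excluded <- TRUE
    prof$reason <- "negative_intercept"
    return(prof)
  }
  mmr <- derive_mmr(steps)
  prof$smr <- smr
  prof$mmr <- mmr
  if (is.finite(mmr) && mmr >= smr) {
    sc <- derive_scope(smr, mmr)
    prof$aas <- sc$aas
    prof$fas <- sc$fas
  }
  prof
}

#' @export
print.metabolic_profile <- function(x, ...) {
  if (isTRUE(x$excluded)) {
    cat("Metabolic profile: excluded (", x$reason, ")\n", sep = "")
  } else {
    cat(sprintf(
      "Metabolic profile (%s fit): SMR %.3f, MMR %.3f, AAS %.3f, FAS %.2f mg O2 g-1 h-1\n",
      x$model, x$smr, x$mmr, x$aas, x$fas))
  }
  invisible(x)
}

#' Standard metabolic rate from a fitted speed--uptake profile
#'
#' The y-intercept of the selected speed--uptake model: oxygen uptake
#' extrapolated to zero swimming speed. A non-positive intercept (line
#' passing through the negative y-axis) is biologically impossible, so `NA`
#' is returned and the fish should be excluded from uptake analysis (it can
#' still contribute a Ucrit).
#'
#' @param profile A `metabolic_profile` (or any list with element `a`).
#' @return SMR in mg O2 g^-1 h^-1, or `NA` if the intercept is
#'   non-positive.
#' @export
derive_smr <- function(profile) {
  a <- profile$a
  if (!is.finite(a) || a <= 0) return(NA_real_)
  a
}

#' Maximum metabolic rate from step measurements
#'
#' The maximum observed per-step oxygen uptake (attained at the highest
#' swimming speeds just before fatigue), not the fitted curve's value.
#'
#' @param steps Data frame with column `mo2`; rows whose `qc_flags` (if
#'   present) contain `background_exceeds_slope` are ignored.
#' @return MMR in mg O2 g^-1 h^-1, or `NA` if no valid step exists.
#' @export
derive_mmr <- function(steps) {
  y <- steps$mo2
  if (!is.null(steps$qc_flags))
    y <- y[!grepl("background_exceeds_slope", steps$qc_flags)]
  y <- y[is.finite(y)]
  if (!length(y)) return(NA_real_)
  max(y)
}

#' Absolute and factorial aerobic scope
#'
#' `AAS = MMR - SMR` is the absolute increase in oxygen uptake available
#' above rest; `FAS = MMR / SMR` is the fold increase.
#'
#' @param smr Standard metabolic rate (> 0).
#' @param mmr Maximum metabolic rate (>= `smr`).
#' @return A list with `aas` and `fas`.
#' @examples
#' derive_scope(2, 4)  # AAS 2, FAS 2
#' @export
derive_scope <- function(smr, mmr) {
  if (any(smr <= 0)) stop("SMR must be positive")
  if (any(mmr < smr)) stop("MMR must be at least SMR")
  list(aas = mmr - smr, fas = mmr / smr)
}

#' Allometric mass-scaling of a metabolic rate
#'
#' Fits the power law `y = a * x^b` (rate against body mass) by ordinary
#' least squares on the log-log scale: `log(y) = log(a) + b*log(x)`. A
#' negative exponent `b` means mass-specific rates fall as fish grow.
#'
#' @param mass_mg Body masses, mg (all > 0).
#' @param rate Mass-specific rates, mg O2 g^-1 h^-1 (all > 0).
#' @return A `scaling_fit` list: `a`, `b`, `r_squared` (on the log scale)
#'   and `n`.
#' @examples
#' m <- c(0.5, 1, 2, 4)
#' fit_allometry(m, 10 * m^-0.8)$b  # -0.8
#' @export
fit_allometry <- function(mass_mg, rate) {
  ok <- is.finite(mass_mg) & is.finite(rate)
  mass_mg <- mass_mg[ok]; rate <- rate[ok]
  if (length(mass_mg) < 3) stop("need at least 3 fish for a scaling fit")
  if (any(mass_mg <= 0) || any(rate <= 0))
    stop("mass and rate must be positive for log-log scaling")
  lx <- log(mass_mg); ly <- log(rate)
  fit <- stats::lm(ly ~ lx)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((ly - mean(ly))^2)
  r2 <- if (ss_tot == 0) NA_real_ else 1 - ss_res / ss_tot
  structure(list(a = exp(unname(stats::coef(fit)[1])),
                 b = unname(stats::coef(fit)[2]),
                 r_squared = r2, n = length(mass_mg)),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("Scaling fit: y = %.4g * mass^%.3f (r2 = %.3f, n = %d)\n",
              x$a, x$b, x$r_squared, x$n))
  invisible(x)
}
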