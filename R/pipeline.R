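#' Run the full swim-trial analysis over a cohort
#'
#' For every fish: fit the background respiration function from the
#' trace's own pre/post windows, fit each sealed measurement window's
#' depletion slope, convert to mass-specific oxygen uptake, extract the
#' fatigue point and Ucrit, fit the speed--uptake relationship and derive
#' SMR, MMR, AAS and FAS. Fish whose uptake profile cannot be fitted
#' (insufficient steps, negative intercept) are retained with an exclusion
#' reason — their Ucrit is still reported. Unreadable traces produce a
#' warning and an `NA` row; the run continues.
#'
#' @param traces A `reefresp_cohort` from [simulate_cohort()], a named list
#'   of `oxygen_trace` objects, or a directory containing `<fish_id>.csv`
#'   trace files.
#' @param metadata Fish metadata data frame (or CSV path) with columns
#'   `fish_id`, `age_dph`, `mass_mg`, `length_cm`. Ignored when `traces`
#'   is a cohort object.
#' @param chamber A [chamber_spec()].
#' @param cond A [gas_conditions()] object.
#' @param interval_min,flush_min,habituation_min Trial schedule, minutes.
#' @param trim_seconds Leading trim for slope fits (default 0).
#' @param r2_threshold QC threshold for per-step regressions.
#' @return A data frame with one row per fish: morphometrics, `ucrit_cm_s`,
#'   `ucrit_bl_s`, `smr`, `mmr`, `aas`, `fas`, `model`, `n_steps`,
#'   `excluded`, `reason`, `n_flagged_steps`.
#' @export
run_swim_analysis <- function(traces, metadata = NULL,
                              chamber = chamber_spec(),
                              cond = gas_conditions(),
                              interval_min = 20, flush_min = 3,
                              habituation_min = 60, trim_seconds = 0,
                              r2_threshold = 0.95) {
  protocols <- NULL
  if (inherits(traces, "reefresp_cohort")) {
    cohort <- traces
    traces <- cohort$traces
    metadata <- cohort$fish
    chamber <- cohort$chamber
    cond <- cohort$conditions
    protocols <- cohort$protocols
  }
  if (is.character(traces) && length(traces) == 1) {
    dir <- traces
    files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
    if (!length(files)) stop("no trace CSVs found in ", dir)
    traces <- stats::setNames(vector("list", length(files)),
                              sub("\\.csv$", "", basename(files)))
    for (f in files) {
      id <- sub("\\.csv$", "", basename(f))
      traces[[id]] <- tryCatch(read_trace(f), error = function(e) {
        warning("skipping unreadable trace ", f, ": ",
                conditionMessage(e))
        NULL
      })
    }
  }
  if (is.character(metadata)) metadata <- read_fish_metadata(metadata)
  if (is.null(metadata)) stop("fish metadata is required")
  if (!length(traces)) stop("no traces supplied")

  rows <- lapply(names(traces), function(id) {
    na_row <- data.frame(
      fish_id = id, age_dph = NA_real_, mass_mg = NA_real_,
      length_cm = NA_real_, ucrit_cm_s = NA_real_, ucrit_bl_s = NA_real_,
      smr = NA_real_, mmr = NA_real_, aas = NA_real_, fas = NA_real_,
      model = NA_character_, n_steps = NA_integer_, excluded = TRUE,
      reason = "unreadable_trace", n_flagged_steps = NA_integer_,
      stringsAsFactors = FALSE)
    tr <- traces[[id]]
    if (is.null(tr)) return(na_row)
    mi <- match(id, metadata$fish_id)
    if (is.na(mi)) {
      warning("no metadata for trace ", id)
      na_row$reason <- "missing_metadata"
      return(na_row)
    }
    fish <- fish_record(id, metadata$age_dph[mi], metadata$mass_mg[mi],
                        metadata$length_cm[mi])
    pr <- if (!is.null(protocols)) protocols[[id]] else
      swim_protocol(interval_min = interval_min, flush_min = flush_min,
                    increment_cm_s = metadata$length_cm[mi],
                    habituation_min = habituation_min)
    res <- tryCatch({
      bg <- background_rate(tr, tr, cond)
      steps <- step_measurements(tr, fish, chamber, cond, bg,
                                 trim_seconds = trim_seconds,
                                 r2_threshold = r2_threshold)
      uc <- trial_ucrit(tr, pr, fish$length_cm)
      prof <- fit_speed_mo2(steps)
      data.frame(
        fish_id = id, age_dph = fish$age_dph, mass_mg = fish$mass_mg,
        length_cm = fish$length_cm, ucrit_cm_s = uc$ucrit_cm_s,
        ucrit_bl_s = uc$ucrit_bl_s, smr = prof$smr, mmr = prof$mmr,
        aas = prof$aas, fas = prof$fas, model = prof$model,
        n_steps = prof$n_steps, excluded = prof$excluded,
        reason = if (is.na(prof$reason)) "" else prof$reason,
        n_flagged_steps = sum(nzchar(steps$qc_flags)),
        stringsAsFactors = FALSE)
    }, error = function(e) {
      warning("analysis failed for ", id, ": ", conditionMessage(e))
      na_row$age_dph <- fish$age_dph
      na_row$mass_mg <- fish$mass_mg
      na_row$length_cm <- fish$length_cm
      na_row$reason <- "analysis_error"
      na_row
    })
    res
  })
  out <- do.call(rbind, rows)
  n_excl <- sum(out$excluded)
  if (n_excl)
    message(n_excl, " of ", nrow(out),
            " fish excluded from oxygen uptake analysis (",
            paste(unique(out$reason[out$excluded]), collapse = ", "), ")")
  out
}

#' Summarise and compare hypoxia-tolerance trials by age
#'
#' Per-age mean and SD of the LOE threshold with gas-unit conversions,
#' plus a categorical-age comparison (one-way linear model, Tukey-adjusted
#' pairwise contrasts, compact letter display). With a single age group the
#' comparison is skipped with a message.
#'
#' @param loe LOE trial data frame (or CSV path) with columns `age_dph`
#'   and `loe_percent_sat`.
#' @param cond A [gas_conditions()] object.
#' @param alpha Significance level for the letter display.
#' @param method Pairwise adjustment method (see [pairwise_contrasts()]).
#' @return A list with `summary` (from [summarize_loe()]) and `comparison`
#'   (a `group_comparison`, or `NULL` with one group).
#' @export
run_hypoxia_analysis <- function(loe, cond = gas_conditions(),
                                 alpha = 0.05,
                                 method = c("tukey", "holm")) {
  method <- match.arg(method)
  if (is.character(loe)) loe <- read_loe_table(loe)
  summ <- summarize_loe(loe, cond)
  comparison <- NULL
  if (length(unique(loe$age_dph)) >= 2) {
    comparison <- compare_groups(loe$loe_percent_sat, loe$age_dph,
                                 alpha = alpha, method = method)
  } else {
    message("single age group: comparison skipped")
  }
  list(summary = summ, comparison = comparison)
}

#' Mass-scaling of SMR and MMR across a cohort
#'
#' Fits the allometric power law `rate = a * mass^b` (log-log least
#' squares) separately for SMR and for MMR over the non-excluded fish of a
#' swim-analysis table.
#'
#' @param swim Data frame from [run_swim_analysis()].
#' @return A list with `smr` and `mmr` (`scaling_fit` objects) and `data`
#'   (the plot-ready table of mass and rates used).
#' @export
run_scaling <- function(swim) {
  ok <- !swim$excluded & is.finite(swim$smr) & is.finite(swim$mmr) &
    swim$smr > 0 & swim$mmr > 0
  if (sum(ok) < 3)
    stop("need at least 3 non-excluded fish for scaling fits, have ",
         sum(ok))
  dat <- swim[ok, c("fish_id", "age_dph", "mass_mg", "smr", "mmr")]
  list(smr = fit_allometry(dat$mass_mg, dat$smr),
       mmr = fit_allometry(dat$mass_mg, dat$mmr),
       data = dat)
}
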