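#' Loss-of-equilibrium record for one hypoxia trial
#'
#' In a closed-vial hypoxia trial the larva's own respiration draws oxygen
#' down until loss of equilibrium (LOE), the behavioural endpoint taken as
#' "ecological death". The observer records the water oxygen level at LOE in
#' % air saturation; this constructor attaches the equivalent partial
#' pressure and dissolved concentration under the trial's gas conditions.
#'
#' @param fish A [fish_record()].
#' @param percent_sat Percent air saturation at LOE, strictly inside
#'   (0, 100): a fish cannot lose equilibrium at full saturation.
#' @param cond A [gas_conditions()] object.
#' @return A `loe_record` list: `fish`, `loe_percent_sat`, `loe_po2`
#'   (mm Hg), `loe_do` (mg O2 L^-1) and `conditions`.
#' @examples
#' f <- fish_record("f1", 6, 2.5, 0.7)
#' make_loe_record(f, 30.7, gas_conditions(28, 33, 758))
#' @export
make_loe_record <- function(fish, percent_sat, cond) {
  if (!is.finite(percent_sat) || percent_sat <= 0 || percent_sat >= 100)
    stop("LOE percent air saturation must lie strictly in (0, 100), got ",
         percent_sat)
  structure(list(fish = fish, loe_percent_sat = percent_sat,
                 loe_po2 = percent_sat_to_po2(percent_sat, cond),
                 loe_do = percent_sat_to_do(percent_sat, cond),
                 conditions = cond),
            class = "loe_record")
}

#' Summarise LOE trials by age group
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of the
#' LOE threshold per age group, with group size and unit conversions of the
#' group mean.
#'
#' @param records A list of `loe_record` objects, or a data frame with
#'   columns `age_dph` and `loe_percent_sat`.
#' @param cond A [gas_conditions()] object used to convert group means
#'   (defaults to the first record's conditions when `records` is a list).
#' @return A data frame with one row per age group: `age_dph`, `n`,
#'   `mean_percent_sat`, `sd_percent_sat` (`NA` for singleton groups),
#'   `mean_po2`, `mean_do`.
#' @export
summarize_loe <- function(records, cond = NULL) {
  if (is.data.frame(records)) {
    df <- records
    if (is.null(cond)) stop("cond is required with data-frame input")
  } else {
    if (!length(records)) stop("no LOE records supplied")
    df <- data.frame(
      age_dph = vapply(records, function(r) r$fish$age_dph, numeric(1)),
      loe_percent_sat = vapply(records, function(r) r$loe_percent_sat,
                               numeric(1)))
    if (is.null(cond)) cond <- records[[1]]$conditions
  }
  stopifnot(all(c("age_dph", "loe_percent_sat") %in% names(df)))
  ages <- sort(unique(df$age_dph))
  rows <- lapply(ages, function(a) {
    x <- df$loe_percent_sat[df$age_dph == a]
    m <- mean(x)
    data.frame(age_dph = a, n = length(x), mean_percent_sat = m,
               sd_percent_sat = if (length(x) > 1) stats::sd(x) else
                 NA_real_,
               mean_po2 = percent_sat_to_po2(m, cond),
               mean_do = percent_sat_to_do(m, cond))
  })
  do.call(rbind, rows)
}

#' Read a table of LOE trials
#'
#' Columns: `fish_id,age_dph,mass_mg,loe_percent_sat,temp_c,salinity_ppt,`
#' `pressure_mmhg`.
#'
#' @param path CSV path.
#' @return A data frame, one row per trial.
#' @export
read_loe_table <- function(path) {
  if (!file.exists(path)) stop("no such LOE file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("fish_id", "age_dph", "loe_percent_sat")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("LOE table missing column(s): ", paste(missing, collapse = ", "))
  bad <- which(df$loe_percent_sat <= 0 | df$loe_percent_sat >= 100)
  if (length(bad))
    stop("LOE percent out of (0, 100) at row ", bad[1])
  df
}
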