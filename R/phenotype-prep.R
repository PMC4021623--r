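# EMR-style phenotype derivation: longitudinal records are collapsed to one
# value per individual by taking the median within each calendar year and then
# the median across the yearly medians. A single observation suffices.

#' Median of yearly medians
#'
#' Collapses repeated measurements for one individual and trait to a single
#' value: group records by calendar year, take the median within each year,
#' then the median across yearly medians. Even-count medians are the midpoint
#' of the two central order statistics ([stats::median()] convention).
#'
#' @param values Numeric measurements.
#' @param years Calendar year of each measurement (integer or anything
#'   coercible; dates are accepted and their year is used).
#' @return A single numeric value, or `NA` if no finite measurements exist.
#' @examples
#' median_of_yearly_medians(c(1, 3, 5), c(2001, 2001, 2002))  # medians 2, 5 -> 3.5
#' @export
median_of_yearly_medians <- function(values, years) {
  if (inherits(years, "Date")) years <- as.integer(format(years, "%Y"))
  years <- as.integer(years)
  stopifnot(length(values) == length(years))
  ok <- is.finite(values) & !is.na(years)
  if (!any(ok)) return(NA_real_)
  yearly <- tapply(values[ok], years[ok], stats::median)
  stats::median(as.numeric(yearly))
}

#' Aggregate a longitudinal record table to one value per sample and trait
#'
#' Applies [median_of_yearly_medians()] within each `sample_id` x `trait`
#' group and returns a wide per-sample table.
#'
#' @param records Data frame with columns `sample_id`, `trait`, `date`
#'   (a `Date`, or an ISO `yyyy-mm-dd` string, or a bare year) and `value`.
#' @return A tibble with one row per sample and one column per trait.
#' @export
aggregate_longitudinal <- function(records) {
  stopifnot(all(c("sample_id", "trait", "date", "value") %in% names(records)))
  rec <- tibble::as_tibble(records)
  rec$year <- extract_year(rec$date)
  rec |>
    dplyr::group_by(.data$sample_id, .data$trait) |>
    dplyr::summarise(
      value = median_of_yearly_medians(.data$value, .data$year),
      .groups = "drop") |>
    tidyr::pivot_wider(names_from = "trait", values_from = "value")
}

extract_year <- function(x) {
  if (inherits(x, "Date")) return(as.integer(format(x, "%Y")))
  x <- as.character(x)
  as.integer(substr(x, 1L, 4L))
}

#' Dichotomize hypertension status from blood-pressure and medication history
#'
#' An individual is a case if any systolic reading is >= 140 mmHg, any
#' diastolic reading is >= 90 mmHg, or they are currently taking hypertension
#' medication. Non-cases with a history of prescribed hypertension medication
#' are excluded rather than used as controls; the remainder are controls.
#'
#' @param sbp,dbp Numeric vectors of systolic/diastolic readings (mmHg) for one
#'   individual; may be empty.
#' @param current_med Logical: currently taking any hypertension medication.
#' @param med_history Logical: any history of prescribed hypertension
#'   medication.
#' @return One of `"case"`, `"control"`, `"excluded"`, or `NA_character_` when
#'   no blood-pressure or medication information is available.
#' @examples
#' dichotomize_hypertension(140, 80, FALSE, FALSE)        # boundary reading: case
#' dichotomize_hypertension(118, 76, FALSE, TRUE)         # prior meds: excluded
#' @export
dichotomize_hypertension <- function(sbp, dbp, current_med = FALSE,
                                     med_history = current_med) {
  sbp <- sbp[!is.na(sbp)]
  dbp <- dbp[!is.na(dbp)]
  current_med <- isTRUE(current_med)
  med_history <- isTRUE(med_history) || current_med
  if (length(sbp) == 0 && length(dbp) == 0 && !current_med && !med_history) {
    return(NA_character_)
  }
  if (any(sbp >= 140) || any(dbp >= 90) || current_med) return("case")
  if (med_history) return("excluded")
  "control"
}

#' Encode case/control labels as 0/1
#'
#' `"case"` -> 1, `"control"` -> 0, `"excluded"` and `NA` -> `NA`.
#'
#' @param status Character vector of labels from [dichotomize_hypertension()].
#' @return Integer vector.
#' @export
casecontrol_to_binary <- function(status) {
  out <- rep(NA_integer_, length(status))
  out[status == "case"] <- 1L
  out[status == "control"] <- 0L
  out
}

#' Remove physiologically implausible BMI values
#'
#' Values outside `[lower, upper]` are set missing before aggregation; such
#' outliers in EMR data typically reflect unit-conversion errors. Defaults
#' bound BMI to 10-100 kg/m^2.
#'
#' @param values Numeric BMI measurements.
#' @param lower,upper Plausibility bounds (kg/m^2), `lower < upper`.
#' @return `values` with out-of-range entries set to `NA`.
#' @export
clean_bmi <- function(values, lower = 10, upper = 100) {
  stopifnot(is.finite(lower), is.finite(upper), lower < upper)
  values[!is.na(values) & (values < lower | values > upper)] <- NA_real_
  values
}
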