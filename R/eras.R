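#' Collapse dated treatment events into treatment eras
#'
#' Core persistence-gap rule shared by drugs and procedures. Each event
#' covers the closed day interval `[start, start + duration_days]`. Within a
#' `(person_id, treatment_category)` group, events are chained: an event
#' whose start is at most `gap_days` after the running covered end (the
#' maximum covered end so far) extends the current era; a larger gap opens a
#' new one. Era start is the first event start in the chain, era end the
#' last covered end, so eras of one patient and category are disjoint and
#' separated by more than `gap_days`.
#'
#' @param events Tibble with columns `person_id`, `treatment_category`,
#'   `start` (Date) and `duration_days` (nonnegative integer).
#' @param gap_days Maximum allowed gap, in days, between the covered end and
#'   the next event start (inclusive: a gap of exactly `gap_days` merges).
#' @return Tibble with columns `person_id`, `treatment_category`,
#'   `era_start`, `era_end`, `n_source_events`.
#' @keywords internal
build_treatment_eras <- function(events, gap_days = 30L) {
  if (any(events$duration_days < 0, na.rm = TRUE)) {
    abort_data("negative event duration / days_supply")
  }
  if (nrow(events) == 0) {
    return(tibble::tibble(person_id = integer(),
                          treatment_category = character(),
                          era_start = as.Date(character()),
                          era_end = as.Date(character()),
                          n_source_events = integer()))
  }
  events |>
    dplyr::mutate(cov_end = .data$start + .data$duration_days) |>
    dplyr::arrange(.data$person_id, .data$treatment_category, .data$start,
                   .data$cov_end) |>
    dplyr::group_by(.data$person_id, .data$treatment_category) |>
    dplyr::mutate(
      run_end = as.Date(cummax(as.integer(.data$cov_end)), origin = "1970-01-01"),
      new_era = is.na(dplyr::lag(.data$run_end)) |
        as.integer(.data$start - dplyr::lag(.data$run_end)) > gap_days,
      era_id = cumsum(.data$new_era)) |>
    dplyr::group_by(.data$era_id, .add = TRUE) |>
    dplyr::summarise(era_start = min(.data$start),
                     era_end = max(.data$cov_end),
                     n_source_events = dplyr::n(), .groups = "drop") |>
    dplyr::select(!"era_id") |>
    dplyr::arrange(.data$person_id, .data$treatment_category, .data$era_start)
}

#' Build drug eras from dispensings
#'
#' Each dispensing covers its start date plus the days' supply; dispensings
#' of the same patient and treatment class merge into one era when the gap
#' beyond the covered supply is at most `gap_days` (inclusive). In-class
#' events merge identically, so in-class switching is invisible. Overlapping
#' fills extend coverage from the union of covered days (no stockpiling of
#' early-refill supply).
#'
#' @param drug_exposures Tibble with columns `person_id`, `start_date`,
#'   `days_supply`, `treatment_category` (extra columns ignored). Negative
#'   supplies are a data error; missing supplies are imputed with
#'   `default_days_supply`.
#' @param gap_days Persistence gap in days (default 30).
#' @param default_days_supply Imputed supply for missing values (default 30).
#' @return Tibble of eras; see [build_treatment_eras()].
#' @export
#' @examples
#' fills <- tibble::tibble(
#'   person_id = 1L, treatment_category = "SSRI",
#'   start_date = as.Date("2015-01-01") + c(0, 45),
#'   days_supply = c(30L, 30L))
#' build_drug_eras(fills)  # gap 15 <= 30: one era
build_drug_eras <- function(drug_exposures, gap_days = 30L,
                            default_days_supply = 30L) {
  supply <- drug_exposures$days_supply
  if (any(supply < 0, na.rm = TRUE)) {
    abort_data("negative days_supply in drug_exposures")
  }
  n_imputed <- sum(is.na(supply))
  supply[is.na(supply)] <- as.integer(default_days_supply)
  out <- build_treatment_eras(
    tibble::tibble(person_id = drug_exposures$person_id,
                   treatment_category = drug_exposures$treatment_category,
                   start = drug_exposures$start_date,
                   duration_days = supply),
    gap_days = gap_days)
  attr(out, "n_imputed_supply") <- n_imputed
  out
}

#' Build procedure eras from dated visits
#'
#' The data carry no duration for therapy sessions, so each visit is given a
#' persistence window of `session_persistence_days`; visits then merge under
#' the same gap rule as drug dispensings.
#'
#' @param procedure_occurrences Tibble with columns `person_id`,
#'   `procedure_date`, `treatment_category` (extra columns ignored).
#' @param session_persistence_days Days of assumed persistence per visit
#'   (default 30).
#' @param gap_days Persistence gap in days (default 30).
#' @return Tibble of eras; see [build_treatment_eras()].
#' @export
build_procedure_eras <- function(procedure_occurrences,
                                 session_persistence_days = 30L,
                                 gap_days = 30L) {
  build_treatment_eras(
    tibble::tibble(person_id = procedure_occurrences$person_id,
                   treatment_category = procedure_occurrences$treatment_category,
                   start = procedure_occurrences$procedure_date,
                   duration_days = as.integer(session_persistence_days)),
    gap_days = gap_days)
}

#' Build all treatment eras for a bundle
#'
#' Convenience wrapper: drug eras from `drug_exposures` and procedure eras
#' from `procedure_occurrences`, stacked.
#'
#' @inheritParams build_drug_eras
#' @inheritParams build_procedure_eras
#' @param bundle A [claims_bundle()].
#' @return Tibble of eras across both modalities.
#' @export
build_all_eras <- function(bundle, gap_days = 30L,
                           session_persistence_days = 30L,
                           default_days_supply = 30L) {
  out <- dplyr::bind_rows(
    build_drug_eras(bundle$drug_exposures, gap_days = gap_days,
                    default_days_supply = default_days_supply),
    build_procedure_eras(bundle$procedure_occurrences,
                         session_persistence_days = session_persistence_days,
                         gap_days = gap_days))
  dplyr::arrange(out, .data$person_id, .data$era_start, .data$treatment_category)
}
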