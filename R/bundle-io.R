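bundle_schemas <- function() {
  list(
    persons = list(
      file = "persons.csv",
      cols = readr::cols(person_id = readr::col_integer(),
                         birth_year = readr::col_integer(),
                         sex = readr::col_character(),
                         race = readr::col_character())),
    observation_periods = list(
      file = "observation_periods.csv",
      cols = readr::cols(person_id = readr::col_integer(),
                         start_date = readr::col_date(),
                         end_date = readr::col_date())),
    condition_occurrences = list(
      file = "condition_occurrences.csv",
      cols = readr::cols(person_id = readr::col_integer(),
                         condition_date = readr::col_date(),
                         condition_category = readr::col_character(),
                         source_code = readr::col_character())),
    drug_exposures = list(
      file = "drug_exposures.csv",
      cols = readr::cols(person_id = readr::col_integer(),
                         start_date = readr::col_date(),
                         days_supply = readr::col_integer(),
                         treatment_category = readr::col_character(),
                         source_code = readr::col_character())),
    procedure_occurrences = list(
      file = "procedure_occurrences.csv",
      cols = readr::cols(person_id = readr::col_integer(),
                         procedure_date = readr::col_date(),
                         treatment_category = readr::col_character(),
                         source_code = readr::col_character()))
  )
}

#' Construct a claims bundle
#'
#' A claims bundle holds the five OMOP-style input tables as one dataset keyed
#' by `person_id`: `persons`, `observation_periods`, `condition_occurrences`,
#' `drug_exposures` (with days' supply) and `procedure_occurrences`.
#'
#' @param persons,observation_periods,condition_occurrences,drug_exposures,procedure_occurrences
#'   Data frames matching the documented schemas (see [read_bundle()]).
#' @param validate Check referential and temporal invariants (default `TRUE`).
#' @return A list of five tibbles with class `"claims_bundle"`.
#' @export
claims_bundle <- function(persons, observation_periods, condition_occurrences,
                          drug_exposures, procedure_occurrences,
                          validate = TRUE) {
  b <- list(persons = tibble::as_tibble(persons),
            observation_periods = tibble::as_tibble(observation_periods),
            condition_occurrences = tibble::as_tibble(condition_occurrences),
            drug_exposures = tibble::as_tibble(drug_exposures),
            procedure_occurrences = tibble::as_tibble(procedure_occurrences))
  schemas <- bundle_schemas()
  for (tab in names(schemas)) {
    want <- names(schemas[[tab]]$cols$cols)
    miss <- setdiff(want, names(b[[tab]]))
    if (length(miss)) {
      abort_data(sprintf("table `%s` is missing column(s): %s",
                         tab, paste(miss, collapse = ", ")))
    }
    b[[tab]] <- b[[tab]][want]
  }
  class(b) <- "claims_bundle"
  if (validate) validate_bundle(b)
  b
}

#' Validate claims-bundle invariants
#'
#' Checks, exhaustively over all rows: every event's `person_id` exists in
#' `persons`; observation periods have `start_date <= end_date`; every event
#' date falls inside at least one observation period of its patient; days'
#' supply is nonnegative.
#'
#' @param bundle A [claims_bundle()].
#' @return `bundle`, invisibly, if valid; otherwise a data error.
#' @export
validate_bundle <- function(bundle) {
  ids <- bundle$persons$person_id
  if (anyDuplicated(ids)) abort_data("duplicate person_id in persons")
  op <- bundle$observation_periods
  if (any(op$start_date > op$end_date)) {
    abort_data("observation period with start_date > end_date")
  }
  events <- list(
    observation_periods = op$person_id,
    condition_occurrences = bundle$condition_occurrences$person_id,
    drug_exposures = bundle$drug_exposures$person_id,
    procedure_occurrences = bundle$procedure_occurrences$person_id)
  for (tab in names(events)) {
    bad <- setdiff(unique(events[[tab]]), ids)
    if (length(bad)) {
      abort_data(sprintf("referential integrity: `%s` references unknown person_id %s",
                         tab, paste(utils::head(bad, 5), collapse = ", ")))
    }
  }
  if (any(bundle$drug_exposures$days_supply < 0, na.rm = TRUE)) {
    abort_data("negative days_supply in drug_exposures")
  }
  check_in_obs <- function(pid, date, tab) {
    if (!length(pid)) return(invisible())
    ev <- tibble::tibble(person_id = pid, .d = date, .row = seq_along(pid))
    j <- dplyr::inner_join(ev, op, by = "person_id",
                           relationship = "many-to-many")
    covered <- unique(j$.row[j$.d >= j$start_date & j$.d <= j$end_date])
    if (length(covered) < length(pid)) {
      abort_data(sprintf("%d event(s) in `%s` dated outside the patient's observation periods",
                         length(pid) - length(covered), tab))
    }
  }
  check_in_obs(bundle$condition_occurrences$person_id,
               bundle$condition_occurrences$condition_date, "condition_occurrences")
  check_in_obs(bundle$drug_exposures$person_id,
               bundle$drug_exposures$start_date, "drug_exposures")
  check_in_obs(bundle$procedure_occurrences$person_id,
               bundle$procedure_occurrences$procedure_date, "procedure_occurrences")
  invisible(bundle)
}

#' @export
print.claims_bundle <- function(x, ...) {
  cat("<claims_bundle>\n")
  for (tab in names(x)) {
    cat(sprintf("  %-22s %7d rows\n", tab, nrow(x[[tab]])))
  }
  invisible(x)
}

#' Write a claims bundle to a directory of CSV files
#'
#' Emits five comma-delimited files with header rows and ISO-8601 dates:
#' `persons.csv`, `observation_periods.csv`, `condition_occurrences.csv`,
#' `drug_exposures.csv`, `procedure_occurrences.csv`.
#'
#' @param bundle A [claims_bundle()].
#' @param directory Output directory (created if absent).
#' @return The directory path, invisibly.
#' @seealso [read_bundle()] for the inverse; the round trip is lossless.
#' @export
write_bundle <- function(bundle, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  schemas <- bundle_schemas()
  for (tab in names(schemas)) {
    readr::write_csv(bundle[[tab]], file.path(directory, schemas[[tab]]$file),
                     na = "")
  }
  invisible(directory)
}

#' Read a claims bundle from a directory of CSV files
#'
#' Expects the five files written by [write_bundle()]. Malformed values,
#' unknown or missing columns, and missing files raise a parse error naming
#' the file (and line, where applicable); referential-integrity violations
#' raise a data error.
#'
#' @param directory Directory containing the five CSV files.
#' @return A validated [claims_bundle()].
#' @export
read_bundle <- function(directory) {
  schemas <- bundle_schemas()
  tabs <- list()
  for (tab in names(schemas)) {
    path <- file.path(directory, schemas[[tab]]$file)
    if (!file.exists(path)) {
      abort_parse(sprintf("missing table file: %s", path), file = path)
    }
    hdr <- names(readr::spec_csv(path, col_types = readr::cols(.default = "c"))$cols)
    want <- names(schemas[[tab]]$cols$cols)
    extra <- setdiff(hdr, want); miss <- setdiff(want, hdr)
    if (length(extra) || length(miss)) {
      abort_parse(sprintf(
        "%s: unexpected header (unknown: %s; missing: %s)", path,
        paste(extra, collapse = ", ") %|e|% "none",
        paste(miss, collapse = ", ") %|e|% "none"), file = path)
    }
    x <- suppressWarnings(
      readr::read_csv(path, col_types = schemas[[tab]]$cols, na = "",
                      progress = FALSE))
    pr <- readr::problems(x)
    if (nrow(pr)) {
      abort_parse(sprintf("%s: malformed value at line %d (%s)",
                          path, pr$row[1], pr$expected[1]),
                  file = path, line = pr$row[1])
    }
    attr(x, "spec") <- NULL
    attr(x, "problems") <- NULL
    tabs[[tab]] <- x
  }
  claims_bundle(tabs$persons, tabs$observation_periods,
                tabs$condition_occurrences, tabs$drug_exposures,
                tabs$procedure_occurrences)
}

`%|e|%` <- function(a, b) if (identical(a, "")) b else a
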