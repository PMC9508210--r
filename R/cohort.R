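#' Entry criteria for the incident cohort
#'
#' Encodes the claims-based case definition: two coded diagnoses on distinct
#' dates within `max_days_between_dx` of each other, the first falling in the
#' study entry window; at least `min_prior_observation_days` of continuous
#' observation before the first diagnosis (a single observation period, no
#' gaps); `required_followup_days` of observation after it (abutting periods
#' allowed by default); and no earlier coded diagnosis anywhere in observed
#' history (incidence).
#'
#' @param diagnosis_codes Code strings identifying the condition.
#' @param study_entry_start,study_entry_end Entry window for the first
#'   diagnosis.
#' @param max_days_between_dx Maximum days between the two diagnoses
#'   (inclusive).
#' @param min_prior_observation_days Washout length before index, inclusive
#'   of the index date.
#' @param required_followup_days Observation required after index.
#' @param allow_abutting_followup If `TRUE` (default), follow-up may be
#'   pieced together from observation periods that abut with a 0-day gap
#'   (next start = previous end + 1 day); if `FALSE` a single period must
#'   cover it.
#' @param strict_incidence If `TRUE` (default) no coded diagnosis may
#'   precede the index at any observed time; if `FALSE` only the washout
#'   window must be free of them.
#' @return A list of class `"cohort_criteria"`.
#' @export
cohort_criteria <- function(diagnosis_codes = asd_diagnosis_codes(),
                            study_entry_start = as.Date("2015-01-01"),
                            study_entry_end = as.Date("2016-12-31"),
                            max_days_between_dx = 365L,
                            min_prior_observation_days = 180L,
                            required_followup_days = 1095L,
                            allow_abutting_followup = TRUE,
                            strict_incidence = TRUE) {
  crit <- list(
    diagnosis_codes = as.character(diagnosis_codes),
    study_entry_start = as_date_scalar(study_entry_start, "study_entry_start"),
    study_entry_end = as_date_scalar(study_entry_end, "study_entry_end"),
    max_days_between_dx = as.integer(max_days_between_dx),
    min_prior_observation_days = as.integer(min_prior_observation_days),
    required_followup_days = as.integer(required_followup_days),
    allow_abutting_followup = isTRUE(allow_abutting_followup),
    strict_incidence = isTRUE(strict_incidence))
  if (!length(crit$diagnosis_codes)) {
    abort_config("`diagnosis_codes` must be nonempty", field = "diagnosis_codes")
  }
  for (f in c("max_days_between_dx", "min_prior_observation_days",
              "required_followup_days")) {
    if (!is_count(crit[[f]]) || crit[[f]] <= 0) {
      abort_config(sprintf("`%s` must be a positive day count", f), field = f)
    }
  }
  if (crit$study_entry_start > crit$study_entry_end) {
    abort_config("`study_entry_start` must be <= `study_entry_end`",
                 field = "study_entry_start")
  }
  class(crit) <- "cohort_criteria"
  crit
}

fine_age_group <- function(age) {
  cut(age, breaks = c(-Inf, 4, 9, 14, 17, Inf),
      labels = c("0-4", "5-9", "10-14", "15-17", "18+"))
}

coarse_age_group <- function(age) {
  cut(age, breaks = c(-Inf, 9, 17, Inf), labels = c("0-9", "10-17", "18+"))
}

#' Build the incident cohort
#'
#' Applies the entry criteria patient by patient and returns one row per
#' admitted patient with index date, age at index (index year minus birth
#' year), fine and coarse age groups, sex, and follow-up end. Patients
#' failing a criterion are silently excluded; per-criterion exclusion counts
#' are attached as the `"attrition"` attribute (counted sequentially in the
#' order: any coded diagnosis, second diagnosis in window, entry window,
#' washout, follow-up, incidence).
#'
#' @param bundle A [claims_bundle()].
#' @param criteria A [cohort_criteria()].
#' @return A tibble with columns `person_id`, `index_date`, `age_at_index`,
#'   `age_group_fine`, `age_group_coarse`, `sex`, `index_year`,
#'   `followup_end`, plus an `"attrition"` attribute.
#' @export
build_cohort <- function(bundle, criteria = cohort_criteria()) {
  dx <- bundle$condition_occurrences
  dx <- dx[dx$source_code %in% criteria$diagnosis_codes, c("person_id", "condition_date")]
  dx <- dplyr::distinct(dx)
  attrition <- c(no_coded_diagnosis = 0L, second_dx_outside_window = 0L,
                 index_outside_entry_window = 0L, insufficient_washout = 0L,
                 insufficient_followup = 0L, prior_diagnosis = 0L)

  n_all <- nrow(bundle$persons)
  if (nrow(dx) == 0) {
    attrition["no_coded_diagnosis"] <- n_all
    return(empty_cohort(attrition))
  }

  per <- dx |>
    dplyr::group_by(.data$person_id) |>
    dplyr::arrange(.data$condition_date, .by_group = TRUE) |>
    dplyr::summarise(
      first_dx = .data$condition_date[1],
      second_dx = if (dplyr::n() >= 2) .data$condition_date[2] else as.Date(NA),
      .groups = "drop")
  attrition["no_coded_diagnosis"] <- n_all - nrow(per)

  if (criteria$strict_incidence) {
    per$index_date <- per$first_dx
    per$prior_ok <- TRUE
  } else {
    # Non-strict: index = first diagnosis in/after the entry window; the
    # washout window alone must be free of earlier codes.
    idx <- dx |>
      dplyr::filter(.data$condition_date >= criteria$study_entry_start) |>
      dplyr::group_by(.data$person_id) |>
      dplyr::summarise(index_date = min(.data$condition_date), .groups = "drop")
    per <- dplyr::left_join(per, idx, by = "person_id")
    prior <- dplyr::inner_join(dx, per[c("person_id", "index_date")], by = "person_id")
    bad <- prior$condition_date < prior$index_date &
      prior$condition_date >= prior$index_date - criteria$min_prior_observation_days
    per$prior_ok <- !(per$person_id %in% unique(prior$person_id[bad]))
    # second diagnosis relative to the chosen index
    nxt <- dplyr::inner_join(dx, per[c("person_id", "index_date")], by = "person_id")
    nxt <- nxt[nxt$condition_date > nxt$index_date, ]
    nxt <- nxt |>
      dplyr::group_by(.data$person_id) |>
      dplyr::summarise(second_dx = min(.data$condition_date), .groups = "drop")
    per$second_dx <- NULL
    per <- dplyr::left_join(per, nxt, by = "person_id")
  }
  per <- per[!is.na(per$index_date), ]

  ok_pair <- !is.na(per$second_dx) &
    as.integer(per$second_dx - per$index_date) <= criteria$max_days_between_dx
  attrition["second_dx_outside_window"] <- sum(!ok_pair)
  per <- per[ok_pair, ]

  ok_entry <- per$index_date >= criteria$study_entry_start &
    per$index_date <= criteria$study_entry_end
  attrition["index_outside_entry_window"] <- sum(!ok_entry)
  per <- per[ok_entry, ]

  op <- bundle$observation_periods
  op_split <- split(op[c("start_date", "end_date")], op$person_id)
  ok_wash <- vapply(seq_len(nrow(per)), function(i) {
    p <- op_split[[as.character(per$person_id[i])]]
    !is.null(p) &&
      any(p$start_date <= per$index_date[i] - criteria$min_prior_observation_days &
            p$end_date >= per$index_date[i])
  }, logical(1))
  attrition["insufficient_washout"] <- sum(!ok_wash)
  per <- per[ok_wash, ]

  ok_fup <- vapply(seq_len(nrow(per)), function(i) {
    p <- op_split[[as.character(per$person_id[i])]]
    !is.null(p) && covered_through(
      p, per$index_date[i],
      per$index_date[i] + criteria$required_followup_days,
      criteria$allow_abutting_followup)
  }, logical(1))
  attrition["insufficient_followup"] <- sum(!ok_fup)
  per <- per[ok_fup, ]

  attrition["prior_diagnosis"] <- sum(!per$prior_ok)
  per <- per[per$prior_ok, ]

  if (nrow(per) == 0) return(empty_cohort(attrition))

  out <- dplyr::inner_join(per[c("person_id", "index_date")],
                           bundle$persons[c("person_id", "birth_year", "sex")],
                           by = "person_id")
  out$index_year <- as.integer(format(out$index_date, "%Y"))
  out$age_at_index <- out$index_year - out$birth_year
  out$age_group_fine <- as.character(fine_age_group(out$age_at_index))
  out$age_group_coarse <- as.character(coarse_age_group(out$age_at_index))
  out$followup_end <- out$index_date + criteria$required_followup_days
  out <- out[order(out$person_id),
             c("person_id", "index_date", "age_at_index", "age_group_fine",
               "age_group_coarse", "sex", "index_year", "followup_end")]
  out <- tibble::as_tibble(out)
  attr(out, "attrition") <- attrition
  out
}

empty_cohort <- function(attrition) {
  out <- tibble::tibble(person_id = integer(), index_date = as.Date(character()),
                        age_at_index = integer(), age_group_fine = character(),
                        age_group_coarse = character(), sex = character(),
                        index_year = integer(),
                        followup_end = as.Date(character()))
  attr(out, "attrition") <- attrition
  out
}

# Is [from, to] fully covered by the patient's observation periods?
# With abutting allowed, periods whose gap is 0 days (next start = previous
# end + 1) chain together; otherwise one period must span the interval.
covered_through <- function(periods, from, to, allow_abutting) {
  if (nrow(periods) == 0) return(FALSE)
  if (!allow_abutting) {
    return(any(periods$start_date <= from & periods$end_date >= to))
  }
  p <- periods[order(periods$start_date), ]
  cur_s <- p$start_date[1]; cur_e <- p$end_date[1]
  merged <- list()
  if (nrow(p) > 1) {
    for (i in 2:nrow(p)) {
      if (as.integer(p$start_date[i] - cur_e) <= 1L) {
        cur_e <- max(cur_e, p$end_date[i])
      } else {
        merged[[length(merged) + 1L]] <- c(cur_s, cur_e)
        cur_s <- p$start_date[i]; cur_e <- p$end_date[i]
      }
    }
  }
  merged[[length(merged) + 1L]] <- c(cur_s, cur_e)
  any(vapply(merged, function(m) m[1] <= from && m[2] >= to, logical(1)))
}

#' Demographic summary of a cohort
#'
#' Counts and percentages by fine age group, sex, and index year; within each
#' stratification the percentages sum to 100 (up to rounding).
#'
#' @param cohort Output of [build_cohort()]; must be nonempty.
#' @return A tibble with columns `variable`, `level`, `n`, `pct`.
#' @export
demographic_summary <- function(cohort) {
  if (nrow(cohort) == 0) {
    rlang::abort("cannot summarise an empty cohort", class = "txp_empty_cohort_error")
  }
  one <- function(var, values, levels) {
    n <- table(factor(values, levels = levels))
    tibble::tibble(variable = var, level = names(n), n = as.integer(n),
                   pct = 100 * as.integer(n) / nrow(cohort))
  }
  dplyr::bind_rows(
    one("age_group_fine", cohort$age_group_fine,
        c("0-4", "5-9", "10-14", "15-17", "18+")),
    one("sex", cohort$sex, sort(unique(cohort$sex), method = "radix")),
    one("index_year", cohort$index_year, sort(unique(cohort$index_year))))
}
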