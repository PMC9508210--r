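#' Baseline comorbidity prevalence
#'
#' For each condition category, counts cohort patients with at least one
#' occurrence dated in `[index_date - window_days, index_date]` (the index
#' date itself counts) and reports the prevalence proportion overall and
#' stratified by coarse age group and by sex. Multiple occurrences of a
#' condition count once.
#'
#' @param bundle A [claims_bundle()].
#' @param cohort Output of [build_cohort()]; must be nonempty.
#' @param window_days Length of the pre-index window in days (default 180,
#'   i.e. six months, coinciding with the washout the cohort guarantees).
#' @param conditions Condition-category labels to tabulate; defaults to the
#'   full vocabulary minus the entry condition. Unknown labels raise a
#'   configuration error.
#' @return A tibble with columns `condition`, `stratum_type` (`"overall"`,
#'   `"age_group"`, `"sex"`), `stratum`, `n_patients`, `denominator`,
#'   `proportion` (exactly `n_patients / denominator`).
#' @export
baseline_prevalence <- function(bundle, cohort, window_days = 180L,
                                conditions = NULL) {
  if (nrow(cohort) == 0) {
    rlang::abort("cannot compute prevalence for an empty cohort",
                 class = "txp_empty_cohort_error")
  }
  if (!is_count(window_days) || window_days <= 0) {
    abort_config("`window_days` must be a positive day count", field = "window_days")
  }
  conditions <- conditions %||% setdiff(condition_categories(), "ASD")
  unknown <- setdiff(conditions, condition_categories())
  if (length(unknown)) {
    abort_config(sprintf("unknown condition categor%s: %s",
                         if (length(unknown) > 1) "ies" else "y",
                         paste(unknown, collapse = ", ")),
                 field = "conditions")
  }

  occ <- bundle$condition_occurrences
  occ <- occ[occ$condition_category %in% conditions, ]
  occ <- dplyr::inner_join(occ, cohort[c("person_id", "index_date")],
                           by = "person_id")
  occ <- occ[occ$condition_date >= occ$index_date - as.integer(window_days) &
               occ$condition_date <= occ$index_date, ]
  hits <- dplyr::distinct(occ[c("person_id", "condition_category")])

  strata <- list(
    overall = tibble::tibble(person_id = cohort$person_id,
                             stratum_type = "overall", stratum = "overall"),
    age = tibble::tibble(person_id = cohort$person_id,
                         stratum_type = "age_group",
                         stratum = cohort$age_group_coarse),
    sex = tibble::tibble(person_id = cohort$person_id,
                         stratum_type = "sex", stratum = cohort$sex))
  members <- dplyr::bind_rows(strata)
  denoms <- members |>
    dplyr::count(.data$stratum_type, .data$stratum, name = "denominator")

  grid <- tidyr_expand_grid(conditions, denoms)
  nums <- dplyr::inner_join(members, hits, by = "person_id",
                            relationship = "many-to-many") |>
    dplyr::count(.data$condition_category, .data$stratum_type, .data$stratum,
                 name = "n_patients")
  out <- dplyr::left_join(grid, nums,
                          by = c(condition = "condition_category",
                                 "stratum_type", "stratum"))
  out$n_patients[is.na(out$n_patients)] <- 0L
  out$proportion <- out$n_patients / out$denominator
  out[order(match(out$condition, conditions), out$stratum_type, out$stratum,
            method = "radix"),
      c("condition", "stratum_type", "stratum", "n_patients", "denominator",
        "proportion")]
}

# cross of conditions x strata without a tidyr dependency
tidyr_expand_grid <- function(conditions, denoms) {
  tibble::tibble(
    condition = rep(conditions, each = nrow(denoms)),
    stratum_type = rep(denoms$stratum_type, times = length(conditions)),
    stratum = rep(denoms$stratum, times = length(conditions)),
    denominator = rep(denoms$denominator, times = length(conditions)))
}
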