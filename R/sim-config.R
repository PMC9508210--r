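#' Default regimen transition map for the synthetic generator
#'
#' The generator models treatment as a discrete-time regimen process: after an
#' exponentially distributed dwell on the current regimen, the patient either
#' stops, switches the whole regimen to a new category, or adds a category to
#' the current regimen. This map gives, for each "current" category (the most
#' recently started member of the regimen), a named probability vector over
#' actions `"stop"`, `"switch:<label>"` and `"add:<label>"`; each row sums
#' to 1. Categories without a row stop with probability 1.
#'
#' The default rows loosely echo what claims cohorts of newly diagnosed autism
#' patients show: behavioral-therapy initiators most often switch to, or add,
#' centrally acting sympathomimetics or imidazoline receptor agonists, while
#' pharmacotherapy initiators most often add behavioral therapy.
#'
#' @return Named list of named numeric vectors (row-stochastic).
#' @export
default_transition_matrix <- function() {
  list(
    behavioral_therapy = c(
      "stop" = 0.38,
      "switch:centrally_acting_sympathomimetic" = 0.14,
      "switch:imidazoline_agonist" = 0.11,
      "add:centrally_acting_sympathomimetic" = 0.12,
      "add:imidazoline_agonist" = 0.09,
      "switch:SSRI" = 0.06,
      "add:SSRI" = 0.05,
      "switch:antipsychotic" = 0.05
    ),
    centrally_acting_sympathomimetic = c(
      "stop" = 0.30, "add:behavioral_therapy" = 0.25,
      "switch:imidazoline_agonist" = 0.12,
      "switch:atypical_antipsychotic" = 0.10,
      "add:imidazoline_agonist" = 0.08,
      "switch:SSRI" = 0.08, "switch:anticonvulsant" = 0.07
    ),
    imidazoline_agonist = c(
      "stop" = 0.30, "add:behavioral_therapy" = 0.25,
      "switch:centrally_acting_sympathomimetic" = 0.15,
      "add:centrally_acting_sympathomimetic" = 0.10,
      "switch:atypical_antipsychotic" = 0.10,
      "switch:SSRI" = 0.10
    ),
    antipsychotic = c(
      "stop" = 0.30, "add:behavioral_therapy" = 0.22,
      "add:atypical_antipsychotic" = 0.18,
      "switch:atypical_antipsychotic" = 0.15,
      "switch:anticonvulsant" = 0.15
    ),
    SSRI = c(
      "stop" = 0.32, "add:behavioral_therapy" = 0.25,
      "switch:SNRI" = 0.10, "switch:other_antidepressant" = 0.12,
      "add:anxiolytic" = 0.11, "switch:anticonvulsant" = 0.10
    ),
    anticonvulsant = c(
      "stop" = 0.35, "add:behavioral_therapy" = 0.25,
      "switch:antipsychotic" = 0.20, "add:atypical_antipsychotic" = 0.20
    ),
    atypical_antipsychotic = c(
      "stop" = 0.35, "add:behavioral_therapy" = 0.25,
      "switch:antipsychotic" = 0.20, "switch:anticonvulsant" = 0.20
    ),
    hypnotic_sedative = c(
      "stop" = 0.50, "add:behavioral_therapy" = 0.30, "switch:SSRI" = 0.20
    ),
    anxiolytic = c(
      "stop" = 0.50, "add:behavioral_therapy" = 0.30, "switch:SSRI" = 0.20
    ),
    other_antidepressant = c(
      "stop" = 0.50, "add:behavioral_therapy" = 0.30, "switch:SSRI" = 0.20
    ),
    SNRI = c(
      "stop" = 0.50, "add:behavioral_therapy" = 0.30, "switch:SSRI" = 0.20
    )
  )
}

default_comorbidity_prevalences <- function() {
  c(ADHD = 0.48, anxiety = 0.18, mood_disorder = 0.17,
    developmental_delay = 0.15, seizure_disorder = 0.08,
    malaise_and_fatigue = 0.013)
}

default_treatment_init_probs <- function() {
  c(behavioral_therapy = 0.55,
    centrally_acting_sympathomimetic = 0.11,
    imidazoline_agonist = 0.09,
    antipsychotic = 0.08,
    SSRI = 0.07,
    anticonvulsant = 0.05,
    atypical_antipsychotic = 0.05)
}

# Age weights over 0..64 loosely matching the age mix of newly diagnosed
# claims cohorts: mass concentrated in children, a long thin adult tail.
default_age_weights <- function() {
  w <- c(rep(3.4, 5),     # 0-4
         rep(5.2, 5),     # 5-9
         rep(3.9, 5),     # 10-14
         rep(2.7, 3),     # 15-17
         rep(0.57, 47))   # 18-64
  w / sum(w)
}

#' Configuration for the synthetic claims generator
#'
#' Defines the data-generating process behind [generate_claims()]. Defaults
#' are the study conditions the pipeline is exercised under: an incident
#' cohort entering 2015--2016, 87% of patients ever treated, behavioral
#' therapy as first treatment for 55% of initiators, and comorbidity
#' prevalences near those reported for Medicaid autism cohorts.
#'
#' @param n_patients Number of patients to simulate (>= 1).
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @param enrollment_start_range Length-2 date vector; enrollment start is
#'   uniform over this range.
#' @param enrollment_span_days_range Length-2 integer vector; enrollment
#'   length in days is uniform over this range.
#' @param p_asd Probability a patient truly has ASD (and receives coded
#'   diagnoses).
#' @param p_second_dx_within_year Probability a true-ASD patient's
#'   confirmatory second diagnosis falls within 365 days of the first
#'   (otherwise it falls 366--730 days after).
#' @param p_treated Probability an ASD patient initiates any treatment.
#' @param p_male Probability of male sex.
#' @param dx_date_range Window the first ASD diagnosis is aimed at (the
#'   study entry window).
#' @param comorbidity_prevalences Named numeric vector (condition label ->
#'   probability), or named list mapping condition label to a vector with
#'   names `"0-9"`, `"10-17"`, `"18+"` for age-specific prevalence. A
#'   condition-positive patient always receives one occurrence inside the
#'   baseline window, so these are the effective baseline rates.
#' @param comorbidity_window_days Baseline window the guaranteed occurrence
#'   is placed in (before or at index).
#' @param treatment_init_probs Named numeric vector over treatment category
#'   labels, summing to 1: distribution of the first treatment.
#' @param line_transition_matrix Named list of row-stochastic action vectors;
#'   see [default_transition_matrix()].
#' @param mean_line_duration_days Mean of the exponential regimen dwell time.
#' @param min_line_duration_days Lower clip on the dwell (keeps combinations
#'   identifiable).
#' @param treatment_start_lag_range Integer range of first-treatment lag
#'   relative to the index date (may be negative: pre-index starts).
#' @param switch_gap_days_range Integer range of the gap between a stopped
#'   regimen's covered end and the start of the switched-to category.
#' @param refill_gap_days_distribution Function `function(n)` returning `n`
#'   integer gaps inserted between successive dispensings beyond the days'
#'   supply. Default: always 0 (back-to-back refills).
#' @param days_supply_choices,days_supply_weights Allowed days'-supply values
#'   and their sampling weights.
#' @param session_interval_days Cadence of procedure-modality visits
#'   (behavioral therapy), in days.
#' @param age_distribution Numeric weight vector over ages 0..64.
#' @param max_transitions Cap on regimen changes per patient.
#'
#' @return A validated list of class `"sim_config"`.
#' @seealso [generate_claims()]
#' @export
sim_config <- function(n_patients,
                       seed = 1L,
                       enrollment_start_range = as.Date(c("2013-06-01", "2015-12-31")),
                       enrollment_span_days_range = c(1600L, 2600L),
                       p_asd = 0.85,
                       p_second_dx_within_year = 0.90,
                       p_treated = 0.87,
                       p_male = 0.76,
                       dx_date_range = as.Date(c("2015-01-01", "2016-12-31")),
                       comorbidity_prevalences = default_comorbidity_prevalences(),
                       comorbidity_window_days = 180L,
                       treatment_init_probs = default_treatment_init_probs(),
                       line_transition_matrix = default_transition_matrix(),
                       mean_line_duration_days = 240,
                       min_line_duration_days = 30L,
                       treatment_start_lag_range = c(-30L, 150L),
                       switch_gap_days_range = c(1L, 45L),
                       refill_gap_days_distribution = function(n) rep(0L, n),
                       days_supply_choices = c(30L, 90L),
                       days_supply_weights = c(0.8, 0.2),
                       session_interval_days = 7L,
                       age_distribution = default_age_weights(),
                       max_transitions = 6L) {
  cfg <- list(
    n_patients = n_patients, seed = seed,
    enrollment_start_range = as.Date(enrollment_start_range),
    enrollment_span_days_range = as.integer(enrollment_span_days_range),
    p_asd = p_asd, p_second_dx_within_year = p_second_dx_within_year,
    p_treated = p_treated, p_male = p_male,
    dx_date_range = as.Date(dx_date_range),
    comorbidity_prevalences = comorbidity_prevalences,
    comorbidity_window_days = as.integer(comorbidity_window_days),
    treatment_init_probs = treatment_init_probs,
    line_transition_matrix = line_transition_matrix,
    mean_line_duration_days = mean_line_duration_days,
    min_line_duration_days = as.integer(min_line_duration_days),
    treatment_start_lag_range = as.integer(treatment_start_lag_range),
    switch_gap_days_range = as.integer(switch_gap_days_range),
    refill_gap_days_distribution = refill_gap_days_distribution,
    days_supply_choices = as.integer(days_supply_choices),
    days_supply_weights = days_supply_weights,
    session_interval_days = as.integer(session_interval_days),
    age_distribution = age_distribution,
    max_transitions = as.integer(max_transitions)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a synthetic-claims configuration
#'
#' Checks every invariant the generator relies on and fails with a
#' configuration error naming the offending field.
#'
#' @param config A [sim_config()] object (or bare list with the same fields).
#' @return `config`, invisibly, if valid.
#' @export
validate_sim_config <- function(config) {
  if (!is_count(config$n_patients) || config$n_patients < 1) {
    abort_config("`n_patients` must be a positive integer count",
                 field = "n_patients")
  }
  if (!is_count(config$seed)) {
    abort_config("`seed` must be a single integer", field = "seed")
  }
  for (f in c("p_asd", "p_second_dx_within_year", "p_treated", "p_male")) {
    check_prob(config[[f]], f)
  }
  if (anyNA(config$enrollment_start_range) ||
      length(config$enrollment_start_range) != 2L ||
      config$enrollment_start_range[1] > config$enrollment_start_range[2]) {
    abort_config("`enrollment_start_range` must be two ordered dates",
                 field = "enrollment_start_range")
  }
  sp <- config$enrollment_span_days_range
  if (length(sp) != 2L || anyNA(sp) || sp[1] < 1L || sp[1] > sp[2]) {
    abort_config("`enrollment_span_days_range` must be two positive ordered day counts",
                 field = "enrollment_span_days_range")
  }

  cond_vocab <- setdiff(condition_categories(), "ASD")
  cp <- config$comorbidity_prevalences
  cp_names <- names(cp)
  if (is.null(cp_names) || !all(cp_names %in% cond_vocab)) {
    abort_config(
      paste0("`comorbidity_prevalences` names must come from the condition vocabulary: ",
             paste(cond_vocab, collapse = ", ")),
      field = "comorbidity_prevalences")
  }
  if (is.list(cp)) {
    for (nm in cp_names) {
      v <- cp[[nm]]
      if (!setequal(names(v), c("0-9", "10-17", "18+"))) {
        abort_config(sprintf(
          "age-specific `comorbidity_prevalences[['%s']]` must be named '0-9','10-17','18+'", nm),
          field = "comorbidity_prevalences")
      }
      check_prob(v, "comorbidity_prevalences")
    }
  } else {
    check_prob(cp, "comorbidity_prevalences")
  }

  tx_vocab <- treatment_category_labels()
  ip <- config$treatment_init_probs
  if (is.null(names(ip)) || !all(names(ip) %in% tx_vocab)) {
    abort_config("`treatment_init_probs` names must be treatment category labels",
                 field = "treatment_init_probs")
  }
  check_prob(ip, "treatment_init_probs")
  if (abs(sum(ip) - 1) > 1e-9) {
    abort_config("`treatment_init_probs` must sum to 1", field = "treatment_init_probs")
  }

  tm <- config$line_transition_matrix
  if (!is.list(tm) || (length(tm) > 0 && is.null(names(tm)))) {
    abort_config("`line_transition_matrix` must be a named list of action vectors",
                 field = "line_transition_matrix")
  }
  if (!all(names(tm) %in% tx_vocab)) {
    abort_config("`line_transition_matrix` row names must be treatment category labels",
                 field = "line_transition_matrix")
  }
  for (nm in names(tm)) {
    row <- tm[[nm]]
    check_prob(row, sprintf("line_transition_matrix[['%s']]", nm))
    if (abs(sum(row) - 1) > 1e-9) {
      abort_config(sprintf("`line_transition_matrix[['%s']]` must sum to 1 (row-stochastic)", nm),
                   field = "line_transition_matrix")
    }
    acts <- names(row)
    if (is.null(acts)) {
      abort_config(sprintf("`line_transition_matrix[['%s']]` actions must be named", nm),
                   field = "line_transition_matrix")
    }
    targeted <- grepl("^(switch|add):", acts)
    if (!all(acts[!targeted] == "stop")) {
      abort_config(sprintf(
        "`line_transition_matrix[['%s']]` actions must be 'stop', 'switch:<label>' or 'add:<label>'", nm),
        field = "line_transition_matrix")
    }
    targets <- sub("^(switch|add):", "", acts[targeted])
    if (!all(targets %in% tx_vocab)) {
      abort_config(sprintf(
        "`line_transition_matrix[['%s']]` targets unknown treatment category", nm),
        field = "line_transition_matrix")
    }
  }

  if (!is.function(config$refill_gap_days_distribution)) {
    abort_config("`refill_gap_days_distribution` must be a function(n) returning integer gaps",
                 field = "refill_gap_days_distribution")
  }
  ds <- config$days_supply_choices
  if (length(ds) < 1L || anyNA(ds) || any(ds < 0L)) {
    abort_config("`days_supply_choices` must be nonnegative day counts",
                 field = "days_supply_choices")
  }
  if (length(config$days_supply_weights) != length(ds) ||
      any(config$days_supply_weights < 0) || sum(config$days_supply_weights) <= 0) {
    abort_config("`days_supply_weights` must be nonnegative weights matching `days_supply_choices`",
                 field = "days_supply_weights")
  }
  if (length(config$age_distribution) != 65L ||
      any(config$age_distribution < 0) || sum(config$age_distribution) <= 0) {
    abort_config("`age_distribution` must be 65 nonnegative weights (ages 0-64)",
                 field = "age_distribution")
  }
  lag <- config$treatment_start_lag_range
  if (length(lag) != 2L || anyNA(lag) || lag[1] > lag[2]) {
    abort_config("`treatment_start_lag_range` must be two ordered integers",
                 field = "treatment_start_lag_range")
  }
  sg <- config$switch_gap_days_range
  if (length(sg) != 2L || anyNA(sg) || sg[1] < 0L || sg[1] > sg[2]) {
    abort_config("`switch_gap_days_range` must be two ordered nonnegative integers",
                 field = "switch_gap_days_range")
  }
  if (!is.numeric(config$mean_line_duration_days) || config$mean_line_duration_days <= 0) {
    abort_config("`mean_line_duration_days` must be positive",
                 field = "mean_line_duration_days")
  }
  if (config$session_interval_days < 1L) {
    abort_config("`session_interval_days` must be >= 1", field = "session_interval_days")
  }
  if (!is_count(config$max_transitions) || config$max_transitions < 0) {
    abort_config("`max_transitions` must be a nonnegative integer",
                 field = "max_transitions")
  }
  invisible(config)
}
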