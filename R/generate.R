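#' Generate a synthetic claims bundle
#'
#' Simulates an OMOP-style claims dataset under the process described in
#' [sim_config()]: per-patient enrollment spans; one or two dated ASD
#' diagnoses for true-ASD patients, aimed at the study entry window;
#' comorbidity occurrences with a guaranteed baseline-window occurrence for
#' condition-positive patients; and a regimen process for treatment — an
#' initial category drawn from `treatment_init_probs` at a lag after index,
#' then stop/switch/add actions drawn from `line_transition_matrix` at
#' exponentially distributed dwell times. Drug-modality categories emit
#' dispensings (days' supply plus configurable refill gaps) across their
#' active span; procedure-modality categories emit visits at a fixed cadence.
#'
#' Every emitted event is clamped inside its patient's observation period.
#' Output is deterministic for a fixed `config$seed`.
#'
#' @param config A validated [sim_config()].
#' @return A [claims_bundle()].
#' @export
#' @examples
#' b <- generate_claims(sim_config(n_patients = 50, seed = 42))
#' b
generate_claims <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- as.integer(config$n_patients)

  ## --- persons and enrollment -------------------------------------------
  start_lo <- config$enrollment_start_range[1]
  start_hi <- config$enrollment_start_range[2]
  obs_start <- start_lo + sample_int_range(n, 0L, as.integer(start_hi - start_lo))
  span <- sample_int_range(n, config$enrollment_span_days_range[1],
                           config$enrollment_span_days_range[2])
  obs_end <- obs_start + span

  age <- sample(0:64, n, replace = TRUE, prob = config$age_distribution)
  sex <- ifelse(stats::runif(n) < config$p_male, "male", "female")
  race <- sample(c("white", "black", "other", "unknown"), n, replace = TRUE,
                 prob = c(0.50, 0.23, 0.08, 0.19))

  is_asd <- stats::runif(n) < config$p_asd

  ## --- index (first ASD diagnosis) placement ----------------------------
  # Aim the index at the study entry window while keeping room for washout
  # and follow-up; patients whose enrollment cannot host an eligible index
  # get one anyway (they become attrition downstream).
  index_date <- rep(as.Date(NA), n)
  lo <- pmax(obs_start + 180L, config$dx_date_range[1])
  hi <- pmin(obs_end - 1095L, config$dx_date_range[2])
  feasible <- is_asd & lo <= hi
  if (any(feasible)) {
    index_date[feasible] <- lo[feasible] +
      sample_int_range(sum(feasible), 0L, as.integer(hi[feasible] - lo[feasible]))
  }
  fallback <- is_asd & !feasible
  if (any(fallback)) {
    fb <- pmin(pmax(lo[fallback], obs_start[fallback]), obs_end[fallback] - 366L)
    index_date[fallback] <- pmax(fb, obs_start[fallback])
  }

  # Reference age: age at index for diagnosed patients, at enrollment start
  # otherwise. Birth year follows from it.
  ref_year <- ifelse(is_asd, as.integer(format(index_date, "%Y")),
                     as.integer(format(obs_start, "%Y")))
  birth_year <- ref_year - age

  persons <- tibble::tibble(
    person_id = seq_len(n), birth_year = as.integer(birth_year),
    sex = sex, race = race)
  observation_periods <- tibble::tibble(
    person_id = seq_len(n), start_date = obs_start, end_date = obs_end)

  ## --- ASD condition occurrences ----------------------------------------
  asd_ids <- which(is_asd)
  n_asd <- length(asd_ids)
  cond_pid <- list(); cond_date <- list(); cond_cat <- list(); cond_code <- list()
  if (n_asd > 0) {
    codes <- sample(asd_diagnosis_codes(), n_asd, replace = TRUE,
                    prob = c(0.45, 0.05, 0.40, 0.10))
    within_year <- stats::runif(n_asd) < config$p_second_dx_within_year
    delta <- ifelse(within_year,
                    sample_int_range(n_asd, 1L, 365L),
                    sample_int_range(n_asd, 366L, 730L))
    second <- pmin(index_date[asd_ids] + delta, obs_end[asd_ids])
    keep2 <- second > index_date[asd_ids]
    cond_pid[[1]] <- c(asd_ids, asd_ids[keep2])
    cond_date[[1]] <- c(index_date[asd_ids], second[keep2])
    cond_cat[[1]] <- rep("ASD", n_asd + sum(keep2))
    cond_code[[1]] <- c(codes, codes[keep2])
  }

  ## --- comorbidity occurrences ------------------------------------------
  cp <- config$comorbidity_prevalences
  cond_names <- names(cp)
  coarse <- cut(age, c(-1, 9, 17, Inf), labels = c("0-9", "10-17", "18+"))
  anchor <- as.Date(ifelse(is_asd, index_date, obs_start + span %/% 2),
                    origin = "1970-01-01")
  w <- config$comorbidity_window_days
  for (cc in cond_names) {
    q <- if (is.list(cp)) unname(cp[[cc]][as.character(coarse)]) else rep(cp[[cc]], n)
    has <- stats::runif(n) < q
    ids <- which(has)
    if (length(ids) == 0) next
    # Guaranteed occurrence in [anchor - w, anchor], clamped into enrollment:
    # the effective baseline rate equals the configured prevalence.
    d <- anchor[ids] - sample_int_range(length(ids), 0L, w)
    d <- pmin(pmax(d, obs_start[ids]), obs_end[ids])
    # Extra occurrences anywhere in enrollment (repeat coding of chronic
    # conditions); they never change the at-least-once baseline status.
    n_extra <- stats::rpois(length(ids), 0.4)
    eids <- rep(ids, n_extra)
    ed <- if (length(eids)) {
      obs_start[eids] + sample_int_range(length(eids), 0L,
                                         as.integer(obs_end[eids] - obs_start[eids]))
    } else as.Date(character())
    k <- length(ids) + length(eids)
    cond_pid[[length(cond_pid) + 1L]] <- c(ids, eids)
    cond_date[[length(cond_date) + 1L]] <- c(d, ed)
    cond_cat[[length(cond_cat) + 1L]] <- rep(cc, k)
    cond_code[[length(cond_code) + 1L]] <- rep(paste0("SNOMED:", cc), k)
  }

  condition_occurrences <- tibble::tibble(
    person_id = as.integer(unlist(cond_pid)),
    condition_date = as.Date(as.integer(unlist(lapply(cond_date, as.integer)) %||% integer()),
                             origin = "1970-01-01"),
    condition_category = unlist(cond_cat) %||% character(),
    source_code = unlist(cond_code) %||% character())
  condition_occurrences <- dplyr::arrange(condition_occurrences,
                                          .data$person_id, .data$condition_date,
                                          .data$condition_category)

  ## --- treatment process -------------------------------------------------
  treated <- is_asd & stats::runif(n) < config$p_treated
  modality <- stats::setNames(treatment_categories()$modality,
                              treatment_categories()$label)
  dr_pid <- list(); dr_start <- list(); dr_supply <- list(); dr_cat <- list()
  pr_pid <- list(); pr_date <- list(); pr_cat <- list()
  for (i in which(treated)) {
    spans <- sim_regimen_spans(as.integer(index_date[i]), as.integer(obs_start[i]),
                               as.integer(obs_end[i]), config)
    if (is.null(spans)) next
    for (k in seq_along(spans$cat)) {
      cat_k <- spans$cat[k]; join <- spans$join[k]; leave <- spans$leave[k]
      if (modality[[cat_k]] == "drug") {
        t <- join; starts <- integer(); supplies <- integer()
        while (t <= leave) {
          s <- config$days_supply_choices[
            sample.int(length(config$days_supply_choices), 1L,
                       prob = config$days_supply_weights)]
          starts <- c(starts, t); supplies <- c(supplies, s)
          g <- as.integer(config$refill_gap_days_distribution(1L))
          t <- t + s + max(g, 0L) + if (s == 0L) 1L else 0L
        }
        if (length(starts)) {
          dr_pid[[length(dr_pid) + 1L]] <- rep(i, length(starts))
          dr_start[[length(dr_start) + 1L]] <- starts
          dr_supply[[length(dr_supply) + 1L]] <- supplies
          dr_cat[[length(dr_cat) + 1L]] <- rep(cat_k, length(starts))
        }
      } else {
        visits <- seq(join, leave, by = config$session_interval_days)
        pr_pid[[length(pr_pid) + 1L]] <- rep(i, length(visits))
        pr_date[[length(pr_date) + 1L]] <- visits
        pr_cat[[length(pr_cat) + 1L]] <- rep(cat_k, length(visits))
      }
    }
  }

  drug_exposures <- tibble::tibble(
    person_id = as.integer(unlist(dr_pid)),
    start_date = as.Date(as.integer(unlist(dr_start) %||% integer()),
                         origin = "1970-01-01"),
    days_supply = as.integer(unlist(dr_supply) %||% integer()),
    treatment_category = unlist(dr_cat) %||% character())
  drug_exposures$source_code <- if (nrow(drug_exposures)) {
    paste0("RXNORM:", drug_exposures$treatment_category)
  } else character()
  drug_exposures <- dplyr::arrange(drug_exposures, .data$person_id,
                                   .data$start_date, .data$treatment_category)

  procedure_occurrences <- tibble::tibble(
    person_id = as.integer(unlist(pr_pid)),
    procedure_date = as.Date(as.integer(unlist(pr_date) %||% integer()),
                             origin = "1970-01-01"),
    treatment_category = unlist(pr_cat) %||% character())
  procedure_occurrences$source_code <- if (nrow(procedure_occurrences)) {
    paste0("CPT4:", procedure_occurrences$treatment_category)
  } else character()
  procedure_occurrences <- dplyr::arrange(procedure_occurrences, .data$person_id,
                                          .data$procedure_date,
                                          .data$treatment_category)

  claims_bundle(persons, observation_periods, condition_occurrences,
                drug_exposures, procedure_occurrences)
}

# Regimen process for one treated patient; integer-day arithmetic. Returns
# per-category active spans (join/leave, inclusive) clamped to enrollment,
# or NULL when treatment never starts inside enrollment.
sim_regimen_spans <- function(index, obs_start, obs_end, config) {
  lag <- sample_int_range(1L, config$treatment_start_lag_range[1],
                          config$treatment_start_lag_range[2])
  t <- min(max(index + lag, obs_start), obs_end)
  if (t >= obs_end) return(NULL)

  ip <- config$treatment_init_probs
  key <- sample(names(ip), 1L, prob = ip)
  active_cat <- key
  active_join <- t
  out_cat <- character(); out_join <- integer(); out_leave <- integer()

  close_all <- function(leave) {
    out_cat <<- c(out_cat, active_cat)
    out_join <<- c(out_join, active_join)
    out_leave <<- c(out_leave, rep(leave, length(active_cat)))
  }

  k <- 0L
  repeat {
    dwell <- max(config$min_line_duration_days,
                 round(stats::rexp(1L, 1 / config$mean_line_duration_days)))
    t_end <- t + dwell
    if (t_end >= obs_end || k >= config$max_transitions) {
      close_all(min(t_end, obs_end)); break
    }
    k <- k + 1L
    row <- config$line_transition_matrix[[key]]
    act <- if (is.null(row)) "stop" else sample(names(row), 1L, prob = row)
    if (act == "stop") {
      close_all(t_end); break
    }
    target <- sub("^(switch|add):", "", act)
    if (startsWith(act, "switch:")) {
      close_all(t_end)
      gap <- sample_int_range(1L, config$switch_gap_days_range[1],
                              config$switch_gap_days_range[2])
      t <- t_end + gap
      if (t >= obs_end) break
      active_cat <- target; active_join <- t; key <- target
    } else {  # add
      if (!(target %in% active_cat)) {
        active_cat <- c(active_cat, target)
        active_join <- c(active_join, t_end)
        key <- target
      }
      t <- t_end
    }
  }
  if (length(out_cat) == 0) return(NULL)
  list(cat = out_cat, join = out_join, leave = out_leave)
}
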