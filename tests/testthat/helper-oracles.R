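# Independent oracles used to cross-check the implementation. Each is a
# deliberately naive restatement of the rule it checks, kept free of any
# code shared with the package internals.

# Day-grid era oracle: mark every covered day on a grid, read off maximal
# covered runs, then transitively merge runs whose gap is <= gap_days.
# starts/durations are integer day offsets.
oracle_eras_daygrid <- function(starts, durations, gap_days) {
  stopifnot(length(starts) == length(durations))
  if (length(starts) == 0) {
    return(data.frame(era_start = integer(), era_end = integer(),
                      n_source_events = integer()))
  }
  lo <- min(starts)
  hi <- max(starts + durations)
  grid <- rep(FALSE, hi - lo + 1L)
  for (i in seq_along(starts)) {
    grid[(starts[i] - lo + 1L):(starts[i] + durations[i] - lo + 1L)] <- TRUE
  }
  r <- rle(grid)
  ends_at <- cumsum(r$lengths)
  run_s <- (ends_at - r$lengths + 1L)[r$values] + lo - 1L
  run_e <- ends_at[r$values] + lo - 1L
  # transitively extend coverage across small gaps
  era_s <- run_s[1]; era_e <- run_e[1]
  out_s <- integer(); out_e <- integer()
  if (length(run_s) > 1) {
    for (k in 2:length(run_s)) {
      if (run_s[k] - era_e <= gap_days) {
        era_e <- run_e[k]
      } else {
        out_s <- c(out_s, era_s); out_e <- c(out_e, era_e)
        era_s <- run_s[k]; era_e <- run_e[k]
      }
    }
  }
  out_s <- c(out_s, era_s); out_e <- c(out_e, era_e)
  n_ev <- vapply(seq_along(out_s),
                 function(k) sum(starts >= out_s[k] & starts <= out_e[k]),
                 integer(1))
  data.frame(era_start = out_s, era_end = out_e, n_source_events = n_ev)
}

# Recursive restatement of the line-assignment rules. eras: data.frame with
# treatment_category, era_start, era_end (integer day offsets or Dates).
oracle_assign_lines <- function(eras, index, capture_lead_days = 30,
                                followup_days = 1095, overlap_days = 30,
                                max_lines = Inf) {
  # rule: eligibility window
  e <- eras[eras$era_start >= index - capture_lead_days &
              eras$era_start <= index + followup_days, , drop = FALSE]
  # rule: first-instance capture at era level
  keep <- rep(TRUE, nrow(e))
  for (i in seq_len(nrow(e))) {
    same <- which(e$treatment_category == e$treatment_category[i])
    earlier <- same[e$era_start[same] < e$era_start[i]]
    if (length(earlier)) keep[i] <- FALSE
  }
  e <- e[keep, , drop = FALSE]
  # rule: order by start, ties by label
  e <- e[order(e$era_start, e$treatment_category, method = "radix"), , drop = FALSE]

  place <- function(remaining, lines) {
    if (nrow(remaining) == 0 || length(lines) >= max_lines) return(lines)
    era <- remaining[1, ]
    if (length(lines) == 0) {
      lines <- list(list(era))
    } else {
      cur <- lines[[length(lines)]]
      pair_ok <- vapply(cur, function(m) {
        min(as.numeric(m$era_end), as.numeric(era$era_end)) -
          max(as.numeric(m$era_start), as.numeric(era$era_start)) >= overlap_days
      }, logical(1))
      if (all(pair_ok)) {
        lines[[length(lines)]] <- c(cur, list(era))
      } else {
        lines <- c(lines, list(list(era)))
      }
    }
    place(remaining[-1, , drop = FALSE], lines)
  }
  lines <- place(e, list())
  if (length(lines) == 0) {
    return(data.frame(line_number = integer(), regimen = character(),
                      line_start = numeric(), line_end = numeric()))
  }
  data.frame(
    line_number = seq_along(lines),
    regimen = vapply(lines, function(l) {
      paste(sort(vapply(l, function(m) m$treatment_category, character(1)), method = "radix"),
            collapse = "+")
    }, character(1)),
    line_start = vapply(lines, function(l) {
      max(min(vapply(l, function(m) as.numeric(m$era_start), numeric(1))),
          as.numeric(index) - capture_lead_days)
    }, numeric(1)),
    line_end = vapply(lines, function(l) {
      min(max(vapply(l, function(m) as.numeric(m$era_end), numeric(1))),
          as.numeric(index) + followup_days)
    }, numeric(1)))
}

# Literal per-patient restatement of the four cohort entry criteria.
# Returns data.frame(person_id, index_date) of admitted patients.
oracle_cohort <- function(bundle, criteria) {
  admitted <- integer(); index <- as.Date(character())
  for (pid in bundle$persons$person_id) {
    occ <- bundle$condition_occurrences
    dts <- sort(unique(occ$condition_date[
      occ$person_id == pid & occ$source_code %in% criteria$diagnosis_codes]))
    if (length(dts) == 0) next
    op <- bundle$observation_periods[bundle$observation_periods$person_id == pid, ]
    found <- NULL
    for (idx in as.list(dts)) {
      # (d) incidence: no coded diagnosis before this one, ever observed
      if (any(dts < idx)) next
      # (a) two diagnoses on distinct dates, first in entry window, second
      #     within max_days_between_dx
      if (idx < criteria$study_entry_start || idx > criteria$study_entry_end) next
      if (!any(dts > idx & dts - idx <= criteria$max_days_between_dx)) next
      # (b) one observation period covers the washout continuously
      if (!any(op$start_date <= idx - criteria$min_prior_observation_days &
                 op$end_date >= idx)) next
      # (c) follow-up covered day by day (abutting periods allowed)
      days <- seq(idx, idx + criteria$required_followup_days, by = 1)
      covered <- rep(FALSE, length(days))
      for (j in seq_len(nrow(op))) {
        covered <- covered | (days >= op$start_date[j] & days <= op$end_date[j])
      }
      if (!all(covered)) next
      found <- idx
      break
    }
    if (!is.null(found)) {
      admitted <- c(admitted, pid)
      index <- c(index, found)
    }
  }
  data.frame(person_id = admitted, index_date = index)
}
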