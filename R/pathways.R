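#' Assign treatment lines for one patient
#'
#' Concretizes the line-of-therapy rules applied to one patient's eras:
#'
#' 1. Only eras starting in the capture window
#'    `[index - capture_lead_days, index + followup_days]` are eligible.
#' 2. First-instance capture: for each treatment category only its
#'    earliest-starting eligible era is kept; later returns to the category
#'    are invisible.
#' 3. Remaining eras are ordered by start date, ties broken by category
#'    label; the earliest seeds line 1.
#' 4. An era joins the current line's regimen iff its calendar overlap with
#'    *every* era already in the regimen is at least `overlap_days`
#'    (overlap of eras `[a1,a2]`, `[b1,b2]` is `min(a2,b2) - max(a1,b1)`
#'    days); otherwise it is a switch and opens the next line.
#' 5. When `max_lines` is finite, assignment stops after that many lines;
#'    the default keeps all lines (truncation is left to
#'    [aggregate_pathways()]).
#'
#' A line's span is the min start to max end of its member eras, clipped to
#' the capture window. Lines may overlap in calendar time: a sub-threshold
#' overlap opens the next line even while earlier treatments are ongoing.
#'
#' @param eras Tibble of eras for one patient (`treatment_category`,
#'   `era_start`, `era_end`).
#' @param index_date The patient's index date.
#' @param capture_lead_days Days before index still captured (default 30).
#' @param followup_days Capture horizon after index (default 1095).
#' @param overlap_days Minimum overlap for combination membership
#'   (default 30; an overlap of exactly 30 days is a combination).
#' @param max_lines Maximum number of lines to assign (default `Inf`).
#' @return Tibble with columns `line_number`, `regimen` (sorted labels
#'   joined with `"+"`), `categories` (list of character vectors),
#'   `line_start`, `line_end`. Zero rows when no era is eligible.
#' @export
#' @examples
#' e <- tibble::tibble(
#'   treatment_category = c("behavioral_therapy", "SSRI"),
#'   era_start = as.Date("2015-07-01") + c(0, 40),
#'   era_end = as.Date("2015-07-01") + c(100, 120))
#' assign_lines(e, as.Date("2015-07-01"))  # 60-day overlap: one combination
assign_lines <- function(eras, index_date,
                         capture_lead_days = 30L, followup_days = 1095L,
                         overlap_days = 30L, max_lines = Inf) {
  win_lo <- index_date - as.integer(capture_lead_days)
  win_hi <- index_date + as.integer(followup_days)
  e <- eras[eras$era_start >= win_lo & eras$era_start <= win_hi, ]
  empty <- tibble::tibble(line_number = integer(), regimen = character(),
                          categories = list(), line_start = as.Date(character()),
                          line_end = as.Date(character()))
  if (nrow(e) == 0) return(empty)

  e <- e[order(e$era_start, e$treatment_category, method = "radix"), ]
  e <- e[!duplicated(e$treatment_category), ]   # first-instance capture

  lines <- list()
  cur_cat <- character(); cur_s <- as.Date(character()); cur_e <- as.Date(character())
  flush <- function() {
    lines[[length(lines) + 1L]] <<- list(cat = cur_cat, s = min(cur_s), e = max(cur_e))
  }
  for (i in seq_len(nrow(e))) {
    if (length(cur_cat) == 0) {
      cur_cat <- e$treatment_category[i]; cur_s <- e$era_start[i]; cur_e <- e$era_end[i]
      next
    }
    ov <- as.integer(pmin(cur_e, e$era_end[i]) - pmax(cur_s, e$era_start[i]))
    if (all(ov >= overlap_days)) {
      cur_cat <- c(cur_cat, e$treatment_category[i])
      cur_s <- c(cur_s, e$era_start[i]); cur_e <- c(cur_e, e$era_end[i])
    } else {
      flush()
      if (length(lines) >= max_lines) {
        cur_cat <- character()
        break
      }
      cur_cat <- e$treatment_category[i]; cur_s <- e$era_start[i]; cur_e <- e$era_end[i]
    }
  }
  if (length(cur_cat) > 0 && length(lines) < max_lines) flush()
  tibble::tibble(
    line_number = seq_along(lines),
    regimen = vapply(lines, function(l) paste(sort(l$cat, method = "radix"), collapse = "+"),
                     character(1)),
    categories = lapply(lines, function(l) sort(l$cat, method = "radix")),
    line_start = as.Date(vapply(lines, function(l) max(l$s, win_lo), numeric(1)),
                         origin = "1970-01-01"),
    line_end = as.Date(vapply(lines, function(l) min(l$e, win_hi), numeric(1)),
                       origin = "1970-01-01"))
}

#' Assign treatment lines for every cohort patient
#'
#' Runs [assign_lines()] per cohort patient against the era table. Patients
#' with no eligible eras contribute no rows (untreated).
#'
#' @param eras Era tibble across patients (see [build_all_eras()]).
#' @param cohort Output of [build_cohort()].
#' @inheritParams assign_lines
#' @return Tibble with `person_id` plus the [assign_lines()] columns.
#' @export
build_treatment_lines <- function(eras, cohort,
                                  capture_lead_days = 30L, followup_days = 1095L,
                                  overlap_days = 30L, max_lines = Inf) {
  eras <- eras[eras$person_id %in% cohort$person_id, ]
  era_split <- split(eras[c("treatment_category", "era_start", "era_end")],
                     eras$person_id)
  idx <- stats::setNames(cohort$index_date, as.character(cohort$person_id))
  out <- lapply(names(era_split), function(pid) {
    li <- assign_lines(era_split[[pid]], idx[[pid]],
                       capture_lead_days = capture_lead_days,
                       followup_days = followup_days,
                       overlap_days = overlap_days, max_lines = max_lines)
    if (nrow(li)) li$person_id <- as.integer(pid)
    li
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) {
    return(tibble::tibble(person_id = integer(), line_number = integer(),
                          regimen = character(), categories = list(),
                          line_start = as.Date(character()),
                          line_end = as.Date(character())))
  }
  out <- out[c("person_id", "line_number", "regimen", "categories",
               "line_start", "line_end")]
  out[order(out$person_id, out$line_number), ]
}

check_line_integrity <- function(lines) {
  if (nrow(lines) == 0) return(invisible())
  bad <- lines |>
    dplyr::group_by(.data$person_id) |>
    dplyr::summarise(ok = identical(sort(.data$line_number),
                                    seq_along(.data$line_number)),
                     .groups = "drop")
  if (any(!bad$ok)) {
    abort_integrity(sprintf(
      "line numbers not consecutive from 1 for person_id %s",
      paste(utils::head(bad$person_id[!bad$ok], 5), collapse = ", ")))
  }
  invisible()
}

#' Aggregate per-patient lines into a pathway tree
#'
#' Builds the hierarchical regimen-sequence counts behind a sunburst chart:
#' depth-k nodes are line-k regimens, a node's count is the number of treated
#' patients whose first k regimens match the node's prefix, and sequences are
#' truncated at `max_lines`. At every node,
#' `count = sum(child counts) + patients terminating there`; depth-1 counts
#' sum to the treated-patient total. Untreated cohort patients are excluded
#' from the tree and reported in the object.
#'
#' @param lines Output of [build_treatment_lines()].
#' @param cohort Output of [build_cohort()].
#' @param max_lines Truncation depth (default 4).
#' @return An object of class `"pathway_tree"`: a list with `root` (nested
#'   `list(name, count, children)`), `n_cohort`, `n_treated`, `n_untreated`,
#'   `max_lines`.
#' @export
aggregate_pathways <- function(lines, cohort, max_lines = 4L) {
  check_line_integrity(lines)
  if (!all(lines$person_id %in% cohort$person_id)) {
    abort_integrity("lines reference patients outside the cohort")
  }
  keep <- lines[lines$line_number <= max_lines, ]
  seqs <- split(keep$regimen[order(keep$person_id, keep$line_number)],
                keep$person_id[order(keep$person_id, keep$line_number)])
  n_treated <- length(unique(lines$person_id))

  grow <- function(seqs_at, name) {
    node <- list(name = name, count = length(seqs_at), children = list())
    nonterminal <- seqs_at[lengths(seqs_at) > 0]
    if (length(nonterminal)) {
      first <- vapply(nonterminal, `[[`, character(1), 1L)
      rest <- lapply(nonterminal, `[`, -1L)
      for (reg in sort(unique(first), method = "radix")) {
        node$children[[length(node$children) + 1L]] <-
          grow(rest[first == reg], reg)
      }
    }
    node
  }
  root <- grow(unname(seqs), "treated")
  structure(list(root = root, n_cohort = nrow(cohort), n_treated = n_treated,
                 n_untreated = nrow(cohort) - n_treated,
                 max_lines = as.integer(max_lines)),
            class = "pathway_tree")
}

#' @export
print.pathway_tree <- function(x, ...) {
  cat(sprintf("<pathway_tree> %d treated / %d cohort patients, depth <= %d\n",
              x$n_treated, x$n_cohort, x$max_lines))
  cat(sprintf("  %d first-line regimens\n", length(x$root$children)))
  invisible(x)
}

#' Serialize a pathway tree to sunburst-ready JSON
#'
#' Nested `{name, count, children[]}` objects; leaves simply have no
#' children, so a node's count minus its children's counts is the "no
#' further treatment" mass a renderer shows in gray.
#'
#' @param tree A [aggregate_pathways()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pathway_json <- function(tree, path) {
  jsonlite::write_json(tree$root, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Per-line treatment marginals
#'
#' For each line k and treatment category, the number of patients whose
#' line-k regimen contains the category, its rank within the line, and the
#' percentage of treated patients (the line-1 denominator, as treatment-line
#' tables conventionally report); the number of patients reaching each line
#' is carried in `n_line`.
#'
#' @param lines Output of [build_treatment_lines()].
#' @param max_lines Lines to report (default 4).
#' @return Tibble with columns `line`, `n_line`, `treatment`,
#'   `patient_count`, `rank`, `pct_of_treated`.
#' @export
line_marginals <- function(lines, max_lines = 4L) {
  n_treated <- length(unique(lines$person_id))
  keep <- lines[lines$line_number <= max_lines, ]
  if (nrow(keep) == 0) {
    return(tibble::tibble(line = integer(), n_line = integer(),
                          treatment = character(), patient_count = integer(),
                          rank = integer(), pct_of_treated = numeric()))
  }
  long <- tibble::tibble(
    line = rep(keep$line_number, lengths(keep$categories)),
    treatment = unlist(keep$categories))
  n_line <- keep |> dplyr::count(.data$line_number, name = "n_line") |>
    dplyr::rename(line = "line_number")
  long |>
    dplyr::count(.data$line, .data$treatment, name = "patient_count") |>
    dplyr::left_join(n_line, by = "line") |>
    dplyr::group_by(.data$line) |>
    dplyr::arrange(dplyr::desc(.data$patient_count), .data$treatment,
                   .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number(),
                  pct_of_treated = 100 * .data$patient_count / n_treated) |>
    dplyr::ungroup() |>
    dplyr::select("line", "n_line", "treatment", "patient_count", "rank",
                  "pct_of_treated")
}

#' Regimen (single vs combination) table per line
#'
#' Distinct regimens per line with patient counts, the percentage of
#' patients in that line, and a combination flag; plus an attached
#' per-line combination summary (`attr(., "combination_summary")`).
#'
#' @param lines Output of [build_treatment_lines()].
#' @param max_lines Lines to report (default 4).
#' @return Tibble with columns `line`, `regimen`, `patient_count`,
#'   `pct_of_line`, `is_combination`.
#' @export
regimen_summary <- function(lines, max_lines = 4L) {
  keep <- lines[lines$line_number <= max_lines, ]
  out <- keep |>
    dplyr::count(line = .data$line_number, .data$regimen,
                 name = "patient_count") |>
    dplyr::group_by(.data$line) |>
    dplyr::mutate(pct_of_line = 100 * .data$patient_count /
                    sum(.data$patient_count)) |>
    dplyr::ungroup() |>
    dplyr::mutate(is_combination = grepl("+", .data$regimen, fixed = TRUE)) |>
    dplyr::arrange(.data$line, dplyr::desc(.data$patient_count), .data$regimen)
  comb <- out |>
    dplyr::group_by(.data$line) |>
    dplyr::summarise(n_line = sum(.data$patient_count),
                     n_combination = sum(.data$patient_count[.data$is_combination]),
                     pct_combination = 100 * .data$n_combination / .data$n_line,
                     .groups = "drop")
  attr(out, "combination_summary") <- comb
  out
}

#' Treated fraction and any-time treatment utilization
#'
#' The proportion of cohort patients with at least one treatment line, plus
#' per-category any-time utilization and the roll-ups a cohort table reports:
#' any treatment, behavioral therapy, any pharmacotherapy (any drug-modality
#' category).
#'
#' @param lines Output of [build_treatment_lines()] (all lines, untruncated).
#' @param cohort Output of [build_cohort()]; must be nonempty.
#' @return A list with `n_cohort`, `n_treated`, `treated_fraction`, and
#'   `utilization` (tibble `treatment`, `n`, `pct` over the cohort
#'   denominator, with `any_treatment` / `any_pharmacotherapy` rows).
#' @export
treated_fraction <- function(lines, cohort) {
  if (nrow(cohort) == 0) {
    rlang::abort("cannot compute treated fraction for an empty cohort",
                 class = "txp_empty_cohort_error")
  }
  n_cohort <- nrow(cohort)
  treated_ids <- unique(lines$person_id)
  long <- tibble::tibble(
    person_id = rep(lines$person_id, lengths(lines$categories)),
    treatment = unlist(lines$categories) %||% character())
  long <- dplyr::distinct(long)
  drug_labels <- treatment_category_labels("drug")
  rollup <- tibble::tibble(
    treatment = c("any_treatment", "behavioral_therapy", "any_pharmacotherapy"),
    n = c(length(treated_ids),
          length(unique(long$person_id[long$treatment == "behavioral_therapy"])),
          length(unique(long$person_id[long$treatment %in% drug_labels]))))
  per_cat <- long |>
    dplyr::filter(.data$treatment != "behavioral_therapy") |>
    dplyr::count(.data$treatment, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n), .data$treatment)
  util <- dplyr::bind_rows(rollup, per_cat)
  util$pct <- 100 * util$n / n_cohort
  list(n_cohort = n_cohort, n_treated = length(treated_ids),
       treated_fraction = length(treated_ids) / n_cohort,
       utilization = util)
}
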