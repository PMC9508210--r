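era_tbl <- function(cats, starts, ends) {
  tibble::tibble(treatment_category = cats, era_start = day(starts),
                 era_end = day(ends))
}

test_that("overlap arithmetic separates combinations from switches", {
  # single era: one line
  li <- assign_lines(era_tbl("behavioral_therapy", 0L, 100L), t0)
  expect_identical(li$regimen, "behavioral_therapy")

  # 60-day overlap: combination
  li <- assign_lines(era_tbl(c("SSRI", "anxiolytic"), c(0L, 40L), c(100L, 120L)), t0)
  expect_identical(li$regimen, "SSRI+anxiolytic")

  # 20-day overlap: switch
  li <- assign_lines(era_tbl(c("SSRI", "anxiolytic"), c(0L, 80L), c(100L, 200L)), t0)
  expect_identical(li$regimen, c("SSRI", "anxiolytic"))
  expect_identical(li$line_number, 1:2)

  # exactly 30 days of overlap is a combination; 29 is a switch
  li <- assign_lines(era_tbl(c("SSRI", "anxiolytic"), c(0L, 70L), c(100L, 200L)), t0)
  expect_identical(li$regimen, "SSRI+anxiolytic")
  li <- assign_lines(era_tbl(c("SSRI", "anxiolytic"), c(0L, 71L), c(100L, 200L)), t0)
  expect_identical(li$regimen, c("SSRI", "anxiolytic"))
})

test_that("a return to an earlier class is captured only at its first instance", {
  li <- assign_lines(era_tbl(c("SNRI", "SSRI", "SNRI"),
                             c(0L, 90L, 200L), c(60L, 150L, 260L)), t0)
  expect_identical(li$regimen, c("SNRI", "SSRI"))
})

test_that("simultaneous starts are seeded in label order and regimens print sorted", {
  li <- assign_lines(era_tbl(c("atypical_antipsychotic", "antipsychotic"),
                             c(0L, 0L), c(90L, 30L)), t0)
  expect_identical(li$regimen, "antipsychotic+atypical_antipsychotic")
  expect_identical(li$categories[[1]],
                   c("antipsychotic", "atypical_antipsychotic"))
})

test_that("only eras starting in the capture window are line-eligible", {
  li <- assign_lines(era_tbl("SSRI", -30L, 60L), t0)
  expect_identical(nrow(li), 1L)          # 30 days pre-index: eligible
  li <- assign_lines(era_tbl("SSRI", -31L, 60L), t0)
  expect_identical(nrow(li), 0L)
  li <- assign_lines(era_tbl("SSRI", 1095L, 1200L), t0)
  expect_identical(nrow(li), 1L)
  expect_identical(li$line_end, day(1095L))   # span clipped to the window
  li <- assign_lines(era_tbl("SSRI", 1096L, 1200L), t0)
  expect_identical(nrow(li), 0L)
})

test_that("finite max_lines truncates assignment", {
  e <- era_tbl(c("SSRI", "anxiolytic", "TCA"),
               c(0L, 200L, 400L), c(100L, 300L, 500L))
  expect_identical(assign_lines(e, t0)$line_number, 1:3)
  expect_identical(assign_lines(e, t0, max_lines = 2)$regimen,
                   c("SSRI", "anxiolytic"))
})

test_that("line assignment matches the recursive oracle on random patients", {
  set.seed(23)
  for (k in 1:300) {
    eras <- random_pathway_case()
    e <- tibble::tibble(treatment_category = eras$treatment_category,
                        era_start = day(eras$era_start),
                        era_end = day(eras$era_end))
    got <- assign_lines(e, t0)
    want <- oracle_assign_lines(eras, 0)
    expect_identical(got$regimen, want$regimen)
    expect_identical(as.numeric(got$line_start - t0), want$line_start)
    expect_identical(as.numeric(got$line_end - t0), want$line_end)
  }
})

test_that("no treatment category ever appears in two lines of one patient", {
  res <- shared_sim()
  per <- split(res$lines$categories, res$lines$person_id)
  expect_true(all(vapply(per, function(x) anyDuplicated(unlist(x)) == 0,
                         logical(1))))
})

test_that("multi-category regimens really overlap pairwise by >= 30 days", {
  res <- shared_sim()
  eras <- res$eras
  key <- paste(eras$person_id, eras$treatment_category)
  multi <- res$lines[lengths(res$lines$categories) > 1, ]
  for (i in seq_len(nrow(multi))) {
    cats <- multi$categories[[i]]
    pid <- multi$person_id[i]
    # first-instance: the member era is the earliest captured era per class
    spans <- lapply(cats, function(cc) {
      x <- eras[eras$person_id == pid & eras$treatment_category == cc, ]
      x <- x[order(x$era_start), ][1, ]
      c(as.integer(x$era_start), as.integer(x$era_end))
    })
    for (a in seq_along(spans)) {
      for (b in seq_len(a - 1)) {
        ov <- min(spans[[a]][2], spans[[b]][2]) - max(spans[[a]][1], spans[[b]][1])
        expect_gte(ov, 30)
      }
    }
  }
})

test_that("pathway tree counts are conserved at every node", {
  res <- shared_sim()
  check_node <- function(node) {
    kids <- vapply(node$children, function(n) as.numeric(n$count), numeric(1))
    expect_gte(node$count, sum(kids))
    lapply(node$children, check_node)
    invisible()
  }
  check_node(res$tree$root)
  d1 <- vapply(res$tree$root$children, function(n) as.numeric(n$count), numeric(1))
  expect_identical(sum(d1), as.numeric(res$tree$n_treated))
  expect_identical(res$tree$n_treated + res$tree$n_untreated, res$tree$n_cohort)
})

test_that("a degenerate transition matrix forces the depth-2 regimen", {
  tm <- list(
    behavioral_therapy = c("switch:centrally_acting_sympathomimetic" = 1),
    centrally_acting_sympathomimetic = c("stop" = 1))
  cfg <- pipeline_config(
    simulation = sim_config(
      n_patients = 300,
      treatment_init_probs = c(behavioral_therapy = 1),
      line_transition_matrix = tm,
      days_supply_choices = 30L, days_supply_weights = 1,
      max_transitions = 1L),
    seed = 31, out_dir = withr::local_tempdir())
  res <- run_pipeline(cfg)
  bt <- Filter(function(n) n$name == "behavioral_therapy", res$tree$root$children)
  expect_length(bt, 1)
  kids <- vapply(bt[[1]]$children, `[[`, character(1), "name")
  expect_identical(unique(kids), "centrally_acting_sympathomimetic")
  expect_gt(length(bt[[1]]$children), 0)
})

test_that("first-line combinations grow as the overlap threshold shrinks", {
  res <- shared_sim()
  frac_combo <- vapply(c(45L, 30L, 15L, 5L), function(ov) {
    li <- build_treatment_lines(res$eras, res$cohort, overlap_days = ov)
    l1 <- li[li$line_number == 1, ]
    mean(lengths(l1$categories) > 1)
  }, numeric(1))
  expect_true(all(diff(frac_combo) >= 0))
})

test_that("treated fraction and utilization handle edge cohorts", {
  b <- make_bundle(list(
    list(dx = c(0L, 10L), drugs = data.frame(cat = "SSRI", off = 0L, supply = 30L)),
    list(dx = c(0L, 10L), procs = data.frame(cat = "behavioral_therapy", off = 0L)),
    list(dx = c(0L, 10L), drugs = data.frame(cat = "TCA", off = 40L, supply = 30L)),
    list(dx = c(0L, 10L))))
  co <- build_cohort(b)
  eras <- build_all_eras(b)
  li <- build_treatment_lines(eras, co)
  tf <- treated_fraction(li, co)
  expect_equal(tf$treated_fraction, 0.75)
  u <- tf$utilization
  expect_identical(u$n[u$treatment == "any_treatment"], 3L)
  expect_identical(u$n[u$treatment == "any_pharmacotherapy"], 2L)
  expect_identical(u$n[u$treatment == "behavioral_therapy"], 1L)

  # all untreated: zero treated fraction, empty tree
  li0 <- build_treatment_lines(eras[0, ], co)
  expect_equal(treated_fraction(li0, co)$treated_fraction, 0)
  tree0 <- aggregate_pathways(li0, co)
  expect_identical(tree0$n_treated, 0L)
  expect_error(treated_fraction(li, co[0, ]), class = "txp_empty_cohort_error")
})

test_that("inconsistent line numbering is an integrity error", {
  li <- tibble::tibble(person_id = c(1L, 1L), line_number = c(1L, 3L),
                       regimen = c("SSRI", "TCA"),
                       categories = list("SSRI", "TCA"),
                       line_start = day(c(0L, 10L)), line_end = day(c(5L, 20L)))
  co <- build_cohort(make_bundle(list(list(dx = c(0L, 10L)))))
  expect_error(aggregate_pathways(li, co), class = "txp_integrity_error")
})
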