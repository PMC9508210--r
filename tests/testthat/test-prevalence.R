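prev_row <- function(pr, cond, type = "overall", stratum = "overall") {
  pr[pr$condition == cond & pr$stratum_type == type & pr$stratum == stratum, ]
}

test_that("baseline prevalence counts patients once, with inclusive window boundaries", {
  b <- make_bundle(list(
    list(dx = c(0L, 10L), conditions = data.frame(cat = "anxiety", off = -10L)),
    list(dx = c(0L, 10L),
         conditions = data.frame(cat = c("anxiety", "anxiety"), off = c(-20L, -40L))),
    list(dx = c(0L, 10L), conditions = data.frame(cat = "ADHD", off = 0L)),
    list(dx = c(0L, 10L), conditions = data.frame(cat = "ADHD", off = -181L))))
  co <- build_cohort(b)
  pr <- baseline_prevalence(b, co, window_days = 180)

  anx <- prev_row(pr, "anxiety")
  expect_identical(anx$n_patients, 2L)       # repeat coding counts once
  expect_identical(anx$denominator, 4L)
  expect_equal(anx$proportion, 0.5)

  adhd <- prev_row(pr, "ADHD")
  expect_identical(adhd$n_patients, 1L)      # on-index counted, -181 not
  expect_equal(adhd$proportion, 0.25)

  # day -181 enters once the window stretches to 181 days
  pr2 <- baseline_prevalence(b, co, window_days = 181)
  expect_identical(prev_row(pr2, "ADHD")$n_patients, 2L)
})

test_that("prevalence is monotone in window length and consistent across strata", {
  res <- shared_sim()
  widths <- c(30L, 90L, 180L)
  prs <- lapply(widths, function(w) {
    baseline_prevalence(res$bundle, res$cohort, window_days = w)
  })
  for (cond in setdiff(condition_categories(), "ASD")) {
    n <- vapply(prs, function(p) prev_row(p, cond)$n_patients, integer(1))
    expect_true(all(diff(n) >= 0))
  }
  pr <- prs[[3]]
  for (cond in unique(pr$condition)) {
    overall <- prev_row(pr, cond)
    for (type in c("age_group", "sex")) {
      rows <- pr[pr$condition == cond & pr$stratum_type == type, ]
      expect_identical(sum(rows$n_patients), overall$n_patients)
      expect_identical(sum(rows$denominator), overall$denominator)
    }
  }
  expect_true(all(pr$proportion == pr$n_patients / pr$denominator))
})

test_that("unknown condition labels and empty cohorts are rejected", {
  b <- make_bundle(list(list(dx = c(0L, 10L))))
  co <- build_cohort(b)
  expect_error(baseline_prevalence(b, co, conditions = "gout"),
               class = "txp_config_error")
  expect_error(baseline_prevalence(b, co[0, ]),
               class = "txp_empty_cohort_error")
})

test_that("the configured comorbidity baseline rate is recovered within 3 SE", {
  res <- shared_sim()   # ADHD configured at 0.48
  pr <- baseline_prevalence(res$bundle, res$cohort)
  adhd <- prev_row(pr, "ADHD")
  expect_lt(abs(adhd$proportion - 0.48),
            3 * sqrt(0.48 * 0.52 / adhd$denominator))
})
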