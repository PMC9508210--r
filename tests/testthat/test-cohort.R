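test_that("entry criteria admit and exclude at the documented boundaries", {
  # two diagnoses 400 days apart: excluded
  b <- make_bundle(list(list(dx = c(0L, 400L), obs = list(c(-180L, 1095L)))))
  expect_identical(nrow(build_cohort(b)), 0L)

  # diagnoses 200 days apart, observation exactly -180..1095: admitted, index day 0
  b <- make_bundle(list(list(dx = c(0L, 200L), obs = list(c(-180L, 1095L)))))
  co <- build_cohort(b)
  expect_identical(nrow(co), 1L)
  expect_identical(co$index_date, day(0))
  expect_identical(co$followup_end, day(1095))
})

test_that("the eight crafted patients yield exactly the one eligible admission", {
  b <- criteria_fixture_bundle()
  co <- build_cohort(b)
  expect_identical(co$person_id, 1L)  # the boundary-eligible patient
  expect_identical(co$index_date, day(0))
  attrition <- attr(co, "attrition")
  expect_identical(sum(attrition), 7L)
  expect_identical(unname(attrition["no_coded_diagnosis"]), 0L)
})

test_that("admission is invariant to input row order", {
  set.seed(41)
  pats <- replicate(30, random_cohort_patient(), simplify = FALSE)
  b <- make_bundle(pats, validate = FALSE)
  shuffle <- function(df) df[sample(nrow(df)), ]
  b2 <- b
  b2$condition_occurrences <- shuffle(b$condition_occurrences)
  b2$observation_periods <- shuffle(b$observation_periods)
  expect_identical(build_cohort(b2), build_cohort(b))
})

test_that("tightening any criterion never admits additional patients", {
  set.seed(42)
  pats <- replicate(120, random_cohort_patient(), simplify = FALSE)
  b <- make_bundle(pats, validate = FALSE)
  base <- build_cohort(b, cohort_criteria())$person_id
  tighter <- list(
    cohort_criteria(min_prior_observation_days = 365),
    cohort_criteria(max_days_between_dx = 120),
    cohort_criteria(required_followup_days = 1460),
    cohort_criteria(allow_abutting_followup = FALSE))
  for (crit in tighter) {
    expect_true(all(build_cohort(b, crit)$person_id %in% base))
  }
})

test_that("build_cohort matches the literal per-patient checker on 1000 random patients", {
  set.seed(7)
  pats <- replicate(1000, random_cohort_patient(), simplify = FALSE)
  b <- make_bundle(pats, validate = FALSE)
  crit <- cohort_criteria()
  got <- build_cohort(b, crit)
  want <- oracle_cohort(b, crit)
  expect_identical(got$person_id, as.integer(want$person_id))
  expect_identical(got$index_date, want$index_date)
})

test_that("demographic summary reports counts and closed percentages", {
  b <- make_bundle(list(
    list(dx = c(0L, 10L), birth_year = 2010L, sex = "male"),
    list(dx = c(0L, 10L), birth_year = 2011L, sex = "male"),
    list(dx = c(0L, 10L), birth_year = 1990L, sex = "male"),
    list(dx = c(0L, 10L), birth_year = 1995L, sex = "female")))
  co <- build_cohort(b)
  dem <- demographic_summary(co)
  expect_equal(dem$pct[dem$variable == "sex" & dem$level == "male"], 75)
  expect_equal(sum(dem$n[dem$variable == "age_group_fine"]), 4)
  adults <- co$age_group_fine[co$age_at_index >= 18]
  expect_true(all(adults == "18+"))
  for (v in unique(dem$variable)) {
    expect_equal(sum(dem$pct[dem$variable == v]), 100)
  }
  expect_error(demographic_summary(co[0, ]), class = "txp_empty_cohort_error")
})

test_that("the simulated cohort recovers the configured sex ratio within 3 SE", {
  res <- shared_sim()   # p_male = 0.76
  p_hat <- mean(res$cohort$sex == "male")
  expect_lt(abs(p_hat - 0.76), 3 * sqrt(0.76 * 0.24 / nrow(res$cohort)))
})
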