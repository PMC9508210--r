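drug_tbl <- function(offs, supplies, cat = "SSRI", pid = 1L) {
  tibble::tibble(person_id = pid, start_date = day(offs),
                 days_supply = as.integer(supplies), treatment_category = cat)
}

era_offsets <- function(eras) {
  data.frame(era_start = as.integer(eras$era_start - t0),
             era_end = as.integer(eras$era_end - t0),
             n_source_events = eras$n_source_events)
}

test_that("dispensings merge across gaps of up to 30 days beyond the supply", {
  # single fill covers start..start+supply
  e <- build_drug_eras(drug_tbl(0L, 30L))
  expect_identical(era_offsets(e), data.frame(era_start = 0L, era_end = 30L,
                                              n_source_events = 1L))
  # 15-day gap merges
  e <- build_drug_eras(drug_tbl(c(0L, 45L), c(30L, 30L)))
  expect_identical(era_offsets(e), data.frame(era_start = 0L, era_end = 75L,
                                              n_source_events = 2L))
  # 31-day gap splits
  e <- build_drug_eras(drug_tbl(c(0L, 61L), c(30L, 30L)))
  expect_identical(era_offsets(e),
                   data.frame(era_start = c(0L, 61L), era_end = c(30L, 91L),
                              n_source_events = c(1L, 1L)))
  # a gap of exactly 30 days still merges
  e <- build_drug_eras(drug_tbl(c(0L, 60L), c(30L, 30L)))
  expect_identical(era_offsets(e), data.frame(era_start = 0L, era_end = 90L,
                                              n_source_events = 2L))
})

test_that("procedure visits persist 30 days and merge under the same gap rule", {
  visits <- function(offs) tibble::tibble(
    person_id = 1L, procedure_date = day(offs),
    treatment_category = "behavioral_therapy")
  e <- build_procedure_eras(visits(seq(0L, 77L, 7L)))  # 12 weekly sessions
  expect_identical(era_offsets(e), data.frame(era_start = 0L, era_end = 107L,
                                              n_source_events = 12L))
  e <- build_procedure_eras(visits(0L))
  expect_identical(era_offsets(e), data.frame(era_start = 0L, era_end = 30L,
                                              n_source_events = 1L))
  e <- build_procedure_eras(visits(c(0L, 100L)))       # gap 70 > 30: split
  expect_identical(era_offsets(e),
                   data.frame(era_start = c(0L, 100L), era_end = c(30L, 130L),
                              n_source_events = c(1L, 1L)))
})

test_that("era building is idempotent and order-invariant", {
  set.seed(11)
  for (k in 1:50) {
    case <- random_era_case()
    x <- drug_tbl(case$starts, case$durations)
    e1 <- build_drug_eras(x, gap_days = case$gap)
    # rebuild from the eras' own spans
    spans <- tibble::tibble(person_id = e1$person_id,
                            start_date = e1$era_start,
                            days_supply = as.integer(e1$era_end - e1$era_start),
                            treatment_category = e1$treatment_category)
    e2 <- build_drug_eras(spans, gap_days = case$gap)
    expect_identical(e2[c("era_start", "era_end")], e1[c("era_start", "era_end")])
    # permutation invariance
    perm <- x[sample(nrow(x)), ]
    expect_identical(build_drug_eras(perm, gap_days = case$gap), e1)
  }
})

test_that("era count is monotone nonincreasing in the persistence gap", {
  set.seed(12)
  for (k in 1:30) {
    case <- random_era_case()
    x <- drug_tbl(case$starts, case$durations)
    counts <- vapply(c(0L, 15L, 30L, 60L, 120L),
                     function(g) nrow(build_drug_eras(x, gap_days = g)),
                     integer(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("era construction agrees with the day-grid oracle on random instances", {
  set.seed(13)
  for (k in 1:300) {
    case <- random_era_case()
    got <- era_offsets(build_drug_eras(drug_tbl(case$starts, case$durations),
                                       gap_days = case$gap))
    want <- oracle_eras_daygrid(case$starts, case$durations, case$gap)
    expect_identical(got, want)
  }
})

test_that("negative supplies fail; missing supplies are imputed with the default", {
  expect_error(build_drug_eras(drug_tbl(0L, -1L)), class = "txp_data_error")
  e <- build_drug_eras(drug_tbl(0L, NA_integer_), default_days_supply = 30L)
  expect_identical(era_offsets(e), data.frame(era_start = 0L, era_end = 30L,
                                              n_source_events = 1L))
  expect_identical(attr(e, "n_imputed_supply"), 1L)
})
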