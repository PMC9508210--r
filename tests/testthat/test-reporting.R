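test_that("identical configuration and seed give byte-identical outputs", {
  mk <- function(out) pipeline_config(
    simulation = sim_config(n_patients = 250), seed = 77, out_dir = out)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  run_pipeline(mk(d1))
  run_pipeline(mk(d2))
  files <- list.files(d1)
  expect_identical(sort(files), sort(list.files(d2)))
  for (f in files) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))),
                     label = f)
  }
})

test_that("an empty simulated cohort is handled gracefully", {
  cfg <- pipeline_config(simulation = sim_config(n_patients = 30, p_asd = 0),
                         seed = 5, out_dir = withr::local_tempdir())
  expect_warning(res <- run_pipeline(cfg), "empty cohort")
  expect_false(res$ok)
  log <- readLines(file.path(cfg$out_dir, "run_log.txt"))
  expect_true(any(grepl("EMPTY COHORT", log)))
  expect_false(file.exists(file.path(cfg$out_dir, "cohort.csv")))
})

test_that("the hand-crafted 20-patient bundle reproduces its golden outputs", {
  gdir <- system.file("extdata", "golden", package = "txpathways")
  cfg <- pipeline_config(input_dir = file.path(gdir, "bundle"),
                         seed = 1, out_dir = withr::local_tempdir())
  res <- run_pipeline(cfg)
  expect_true(res$ok)
  for (f in c("cohort.csv", "prevalence.csv", "lines.csv", "utilization.csv")) {
    got <- readr::read_csv(file.path(cfg$out_dir, f), show_col_types = FALSE)
    want <- readr::read_csv(file.path(gdir, "expected", f), show_col_types = FALSE)
    expect_equal(as.data.frame(got), as.data.frame(want), label = f)
  }
  got_tree <- jsonlite::fromJSON(file.path(cfg$out_dir, "pathway_tree.json"),
                                 simplifyVector = FALSE)
  want_tree <- jsonlite::fromJSON(file.path(gdir, "expected", "pathway_tree.json"),
                                  simplifyVector = FALSE)
  expect_identical(got_tree, want_tree)
})

test_that("reported percentages are recomputable and files are mutually consistent", {
  res <- shared_sim()
  out <- res$out_dir
  cohort <- readr::read_csv(file.path(out, "cohort.csv"), show_col_types = FALSE)
  dem <- readr::read_csv(file.path(out, "demographics.csv"), show_col_types = FALSE)
  prev <- readr::read_csv(file.path(out, "prevalence.csv"), show_col_types = FALSE)
  marg <- readr::read_csv(file.path(out, "line_marginals.csv"), show_col_types = FALSE)
  util <- readr::read_csv(file.path(out, "utilization.csv"), show_col_types = FALSE)

  n <- nrow(cohort)
  expect_equal(sum(dem$n[dem$variable == "sex"]), n)
  expect_equal(unique(prev$denominator[prev$stratum_type == "overall"]), n)
  expect_equal(dem$pct, round(100 * dem$n / n, 2))
  expect_equal(prev$pct, round(100 * prev$n_patients / prev$denominator, 2))
  expect_equal(util$pct, round(100 * util$n / n, 2))
  n_treated <- util$n[util$treatment == "any_treatment"]
  expect_equal(marg$pct_of_treated,
               round(100 * marg$patient_count / n_treated, 2))
  # line-1 marginal denominator is the treated count
  expect_equal(unique(marg$n_line[marg$line == 1]), n_treated)
})

test_that("pipeline configuration demands exactly one input source", {
  expect_error(pipeline_config(), class = "txp_config_error")
  expect_error(pipeline_config(input_dir = "x",
                               simulation = sim_config(n_patients = 5)),
               class = "txp_config_error")
})

test_that("YAML configs round-trip through the constructors", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "simulation:",
    "  n_patients: 40",
    "  p_asd: 0.9",
    "cohort:",
    "  max_days_between_dx: 200",
    "gap_days: 45",
    "seed: 9",
    sprintf("out_dir: %s", withr::local_tempdir())), path)
  cfg <- read_pipeline_config(path)
  expect_s3_class(cfg, "pipeline_config")
  expect_identical(cfg$simulation$n_patients, 40L)
  expect_identical(cfg$cohort$max_days_between_dx, 200L)
  expect_identical(cfg$gap_days, 45L)

  writeLines(c("seed: 1", "frobnicate: yes"), path)
  expect_error(read_pipeline_config(path), class = "txp_config_error")
})
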