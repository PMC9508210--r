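#!/usr/bin/env Rscript
# Stage 2: apply the incident-cohort entry algorithm (two coded diagnoses
# within a year, 180-day washout, 3-year follow-up, incident diagnosis) and
# report demographics and attrition.
suppressMessages({library(optparse); library(txpathways)})
o <- parse_args(OptionParser(option_list = list(
  make_option("--bundle", type = "character", default = "results/bundle"),
  make_option("--out", type = "character", default = "results"))))

bundle <- read_bundle(o$bundle)
cohort <- build_cohort(bundle, cohort_criteria())
if (nrow(cohort) == 0) { message("empty cohort"); quit(status = 1) }
dir.create(o$out, showWarnings = FALSE, recursive = TRUE)
readr::write_csv(cohort, file.path(o$out, "cohort.csv"), na = "")
dem <- demographic_summary(cohort)
dem$pct <- round(dem$pct, 2)
readr::write_csv(dem, file.path(o$out, "demographics.csv"), na = "")

att <- attr(cohort, "attrition")
cat(sprintf("cohort: %d of %d patients\n", nrow(cohort), nrow(bundle$persons)))
cat("exclusions:\n")
for (k in names(att)) cat(sprintf("  %-28s %d\n", k, att[[k]]))
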