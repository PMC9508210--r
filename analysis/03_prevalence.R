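#!/usr/bin/env Rscript
# Stage 3: baseline comorbidity prevalence in the six months up to and
# including the index date, stratified by coarse age group and sex.
suppressMessages({library(optparse); library(txpathways)})
o <- parse_args(OptionParser(option_list = list(
  make_option("--bundle", type = "character", default = "results/bundle"),
  make_option("--cohort", type = "character", default = "results/cohort.csv"),
  make_option("--out", type = "character", default = "results"))))

bundle <- read_bundle(o$bundle)
cohort <- readr::read_csv(o$cohort, show_col_types = FALSE)
prev <- baseline_prevalence(bundle, cohort, window_days = 180)
prev$pct <- round(100 * prev$proportion, 2)
readr::write_csv(prev[c("condition", "stratum_type", "stratum", "n_patients",
                        "denominator", "pct")],
                 file.path(o$out, "prevalence.csv"), na = "")
top <- prev[prev$stratum_type == "overall", ]
top <- top[order(-top$proportion), ]
cat("baseline prevalence (overall):\n")
for (i in seq_len(nrow(top))) {
  cat(sprintf("  %-22s %5.2f%%\n", top$condition[i], top$pct[i]))
}
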