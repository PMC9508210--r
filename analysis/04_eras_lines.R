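#!/usr/bin/env Rscript
# Stage 4: collapse dispensings and therapy visits into treatment eras
# (30-day persistence gap) and sequence each patient's eras into lines of
# therapy (30-day combination overlap, first-instance capture, 30-day
# pre-index lead, 3-year horizon).
suppressMessages({library(optparse); library(txpathways)})
o <- parse_args(OptionParser(option_list = list(
  make_option("--bundle", type = "character", default = "results/bundle"),
  make_option("--cohort", type = "character", default = "results/cohort.csv"),
  make_option("--out", type = "character", default = "results"))))

bundle <- read_bundle(o$bundle)
cohort <- readr::read_csv(o$cohort, show_col_types = FALSE)
eras <- build_all_eras(bundle)
lines <- build_treatment_lines(eras, cohort)
readr::write_csv(eras, file.path(o$out, "eras.csv"), na = "")
readr::write_csv(lines[c("person_id", "line_number", "regimen", "line_start",
                         "line_end")],
                 file.path(o$out, "lines.csv"), na = "")
cat(sprintf("%d eras -> %d lines across %d treated patients\n",
            nrow(eras), nrow(lines), length(unique(lines$person_id))))
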