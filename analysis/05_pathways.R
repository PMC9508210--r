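#!/usr/bin/env Rscript
# Stage 5: aggregate treatment lines into the sunburst pathway tree, the
# per-line treatment marginals, the single-vs-combination regimen table, and
# any-time utilization.
suppressMessages({library(optparse); library(txpathways)})
o <- parse_args(OptionParser(option_list = list(
  make_option("--bundle", type = "character", default = "results/bundle"),
  make_option("--cohort", type = "character", default = "results/cohort.csv"),
  make_option("--out", type = "character", default = "results"))))

bundle <- read_bundle(o$bundle)
cohort <- readr::read_csv(o$cohort, show_col_types = FALSE)
eras <- build_all_eras(bundle)
lines <- build_treatment_lines(eras, cohort)

tree <- aggregate_pathways(lines, cohort, max_lines = 4)
write_pathway_json(tree, file.path(o$out, "pathway_tree.json"))
marg <- line_marginals(lines, max_lines = 4)
marg$pct_of_treated <- round(marg$pct_of_treated, 2)
readr::write_csv(marg, file.path(o$out, "line_marginals.csv"), na = "")
reg <- regimen_summary(lines, max_lines = 4)
comb <- attr(reg, "combination_summary")
reg$pct_of_line <- round(reg$pct_of_line, 2)
readr::write_csv(reg, file.path(o$out, "regimen_table.csv"), na = "")
util <- treated_fraction(lines, cohort)
u <- util$utilization; u$pct <- round(u$pct, 2)
readr::write_csv(u, file.path(o$out, "utilization.csv"), na = "")

cat(sprintf("treated: %d/%d (%.2f%%)\n", util$n_treated, util$n_cohort,
            100 * util$treated_fraction))
cat("top first-line treatments (% of treated):\n")
m1 <- marg[marg$line == 1, ][1:5, ]
for (i in seq_len(nrow(m1))) {
  cat(sprintf("  %d. %-34s %6d  %5.2f%%\n", m1$rank[i], m1$treatment[i],
              m1$patient_count[i], m1$pct_of_treated[i]))
}
cat("combination therapy by line (% of patients in line):\n")
for (i in seq_len(nrow(comb))) {
  cat(sprintf("  line %d (n=%d): %.2f%%\n", comb$line[i], comb$n_line[i],
              comb$pct_combination[i]))
}
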