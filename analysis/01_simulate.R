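#!/usr/bin/env Rscript
# Stage 1: generate the synthetic claims bundle and write its five CSV
# tables. The generator emulates the structure the analysis assumes:
# enrollment spans, coded ASD diagnoses aimed at the 2015-2016 entry window,
# baseline comorbidity, and a regimen process producing dispensings and
# therapy visits.
suppressMessages({library(optparse); library(txpathways)})
o <- parse_args(OptionParser(option_list = list(
  make_option("--n", type = "integer", default = 5000L),
  make_option("--seed", type = "integer", default = 20150101L),
  make_option("--out", type = "character", default = "results/bundle"))))

bundle <- generate_claims(sim_config(n_patients = o$n, seed = o$seed))
write_bundle(bundle, o$out)
print(bundle)
cat(sprintf("bundle written to %s\n", o$out))
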