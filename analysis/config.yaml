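# Study configuration: a synthetic claims population exercised end-to-end.
# Edit `simulation:` to change the data-generating conditions, or replace it
# with `input_dir: <path>` to analyze an existing bundle of claims CSVs.
simulation:
  n_patients: 5000
seed: 20150101
out_dir: results/run
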