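# Example pipeline configuration for `pgxpipe run-all --config <file>`
# or read_run_config(). A small, fast demonstration run; raise
# n_patients, n_perm and repeats for a study-scale analysis.
seed: 1
outcomes:
  - cognitive_dysfunction
folds: 5
repeats: 2
n_perm: 0
gmdr_orders:
  - 1
gmdr_n_perm: 0
generator:
  n_patients: 250
  seed: 1
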