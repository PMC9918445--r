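# End-to-end pipeline configuration: Nottingham (UK) gFOBT trial validation.
counts: nottingham_counts.csv
design: nottingham_design.yaml
mortality:
  rate: 0.01
model: progressive_3state
fit:
  method: mcmc
  n_iter: 3000
  n_burnin: 1000
  n_chains: 2
twin:
  cohort_size: 74998
  followup: 8.5
  control_count: 856
seed: 1
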