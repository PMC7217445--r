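# Ewe counterpart of ram_table6.yaml: 7 attributes, 16-run
# resolution-IV fraction, truth from the published ewe G-MNL estimates
# (significant scale heterogeneity, tau = 0.7565).
scenario: ewe_table6
design:
  runs: 16
  blocks: 4
  resolution: 4
  seed: 2020
simulate:
  n_respondents: 370
  opt_out_rate: 0.004
  seed: 101
estimate:
  random: [body_size, growth_rate, lambing_interval]
  draws: 500
  scheme: halton
  gamma: 0
  iia_drop: 2
  seed: 7
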