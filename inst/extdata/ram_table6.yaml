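# End-to-end run emulating the ram choice experiment: 16-profile
# resolution-IV fraction in 4 blocks with opt-outs, 370 respondents
# simulated from the published ram G-MNL estimates, G-MNL refit with
# body size and tail type random, 500 Halton draws, gamma fixed at 0.
scenario: ram_table6
design:
  runs: 16
  blocks: 4
  resolution: 4
  seed: 2020
simulate:
  n_respondents: 370
  opt_out_rate: 0.0047
  seed: 101
estimate:
  random: [body_size, tail_type]
  draws: 500
  scheme: halton
  gamma: 0
  iia_drop: 2
  seed: 7
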