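# Demo run: the default synthetic world, default constants.
# Reproduces the walkthrough in the package vignette and README.
seed: 1
world: synthetic
strict: true
moving_average_window: 5
gwp:
  CH4: 28
  N2O: 265
gwp_horizon: AR5-100yr
cluster_thresholds:
  footprint: [5, 50]
  land: [0.15, 0.5]
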