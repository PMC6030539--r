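# Frequency-dependent lifespan sweep exhibiting an evolutionary-suicide gap
# (maturation trade-off; beta_A is the density-dependent reference used for
# per-point calibration)
params:
  preset: fig4m
  transmission_mode: frequency_dependent
axis: lifespan
axis_values: [2.1, 2.2, 2.3, 2.5, 2.8, 3.2, 4, 6, 10, 20]
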