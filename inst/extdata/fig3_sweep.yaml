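# Maturation-probability sweep, maturation trade-off, diminishing returns
params:
  preset: fig3
axis: maturation_probability
axis_values: [0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 0.95, 0.99]
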