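# Qualitative outcome map over trade-off space (reproduction trade-off)
params:
  preset: fig1
strength_grid: [0.05, 0.1, 0.2, 0.3, 0.4, 0.6, 0.9, 1.3, 2.0]
shape_grid: [-5, -3, -2, -1.5, -1, -0.6, -0.3, 0.3, 1, 2, 5]
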