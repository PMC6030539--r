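# Lifespan sweep, reproduction trade-off, diminishing returns
params:
  preset: fig2
axis: lifespan
axis_values: [1.5, 2, 2.5, 3, 4, 5, 7, 10, 15, 25, 40, 60, 100]
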