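# Evolutionary simulation in a CSS cell
params:
  preset: fig1c
epochs: 2000
lattice_n: 31
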