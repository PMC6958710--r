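# Five-genotype mutation regime: genotype conversion to cyclic neighbours
# revives extinct genotypes; oscillations and selective sweeps alternate.
name: fig4
"n": 5
N_H: 300
N_P: 900
params:
  b_H: 6.0
  d_P: 1.0
  K: 600.0
  lam0: 10.0
  mut_H: 0.005
  mut_P: 0.01
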