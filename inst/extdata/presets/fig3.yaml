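# Population-size sweep: extinction time against the target equilibrium
# parasite population size. The host birth-rate grids give the ecological
# models the same equilibrium N_P values; mu = b_H / K in EcoEvoPlus and 0
# in EcoEvo.
name: fig3
"n": 2
N_H: 250
params:
  w_H: 0.5
  w_P: 1.0
  alpha: 1.0
  beta: 0.0
  d_P: 1.0
  K: 500.0
  lam0: 4.0
b_H_grid:
  EcoEvoPlus: {from: 0.24, to: 1.6, by: 0.08}
  EcoEvo: {from: 0.12, to: 0.8, by: 0.04}
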