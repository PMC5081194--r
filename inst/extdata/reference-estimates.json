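{
  "k_exc": 1.35,
  "k_inh": 0.001,
  "p": 5.52,
  "c50": 9.65,
  "r0": 4.55,
  "r_max": 100,
  "t": 0.0308,
  "zeta": 1.9,
  "epsilon": 0.67,
  "alpha": 1.17,
  "beta": 1.51,
  "gamma": 0.644,
  "k_exc_AM": 1.35,
  "k_inh_AM": 0.001,
  "inducer_orientation": 0,
  "n_neurons": 36
}
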