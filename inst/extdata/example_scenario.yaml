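# synthetic recurrent-selection scenario: a base population whose rainfed
# yield collapses (RF:RI = 0.53) and a selected half-sib population that
# maintains it (RF:RI = 1.09), one cycle of 5% truncation selection
n_base: 157
n_progeny: 75
n_cycles: 1
selection_fraction: 0.05
stress_yield_ratio_base: 0.53
stress_yield_ratio_selected: 1.09
spec:
  mu: 600
  sigma2_G: 1200
  sigma2_GT: 1200
  sigma2_GY: 1200
  sigma2_GTY: 800
  sigma2_e: 10000
dims:
  t: 2
  y: 2
  r: 2
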