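species_name: highland_host
stages:
  egg:
    dev_rate:
      psi: 0.0280870988663
      rho: 0.12
      t_base: 6.0
      t_max: 33.0
      delta: 5.0
    mortality:
      b0: 1.074589283239963
      b1: -0.432
      b2: 0.012
    dev_var:
      family: logit
      beta: 8.0
  larva:
    dev_rate:
      psi: 0.006419908312297
      rho: 0.12
      t_base: 6.0
      t_max: 33.0
      delta: 5.0
    mortality:
      b0: 1.480054391348128
      b1: -0.432
      b2: 0.012
    dev_var:
      family: logit
      beta: 8.0
  pupa:
    dev_rate:
      psi: 0.018724732577533
      rho: 0.12
      t_base: 6.0
      t_max: 33.0
      delta: 5.0
    mortality:
      b0: 1.074589283239963
      b1: -0.432
      b2: 0.012
    dev_var:
      family: cloglog
      beta: 10.0
adult_longevity:
  family: stinner
  params:
    c_max: 35.0
    k1: -2.45
    k2: 0.11
fecundity:
  c0: -268.399999999999977
  c1: 43.200000000000003
  c2: -0.9
  gamma_shape: 3.0
  gamma_scale: 0.12
sex_ratio: 0.5
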