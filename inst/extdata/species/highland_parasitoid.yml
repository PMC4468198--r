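species_name: highland_parasitoid
stages:
  egg:
    dev_rate:
      psi: 0.06226088087825
      rho: 0.13
      t_base: 7.0
      t_max: 34.0
      delta: 5.0
    mortality:
      b0: 0.614267726446009
      b1: -0.38
      b2: 0.01
    dev_var:
      family: logit
      beta: 8.0
  larva:
    dev_rate:
      psi: 0.024212564785986
      rho: 0.13
      t_base: 7.0
      t_max: 34.0
      delta: 5.0
    mortality:
      b0: 0.950739963067222
      b1: -0.38
      b2: 0.01
    dev_var:
      family: logit
      beta: 8.0
  pupa:
    dev_rate:
      psi: 0.048425129571972
      rho: 0.13
      t_base: 7.0
      t_max: 34.0
      delta: 5.0
    mortality:
      b0: 0.614267726446009
      b1: -0.38
      b2: 0.01
    dev_var:
      family: cloglog
      beta: 10.0
adult_longevity:
  family: stinner
  params:
    c_max: 25.0
    k1: -1.347
    k2: 0.1
fecundity:
  c0: -186.800000000000011
  c1: 26.400000000000002
  c2: -0.55
  gamma_shape: 2.0
  gamma_scale: 0.15
sex_ratio: 0.5
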