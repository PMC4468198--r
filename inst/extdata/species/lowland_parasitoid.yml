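species_name: lowland_parasitoid
stages:
  egg:
    dev_rate:
      psi: 0.058485328148575
      rho: 0.15
      t_base: 11.0
      t_max: 38.0
      delta: 5.0
    mortality:
      b0: 2.6681241751318
      b1: -0.406
      b2: 0.007
    dev_var:
      family: logit
      beta: 8.0
  larva:
    dev_rate:
      psi: 0.021931998055716
      rho: 0.15
      t_base: 11.0
      t_max: 38.0
      delta: 5.0
    mortality:
      b0: 2.653089283239964
      b1: -0.377
      b2: 0.0065
    dev_var:
      family: logit
      beta: 8.0
  pupa:
    dev_rate:
      psi: 0.043863996111431
      rho: 0.15
      t_base: 11.0
      t_max: 38.0
      delta: 5.0
    mortality:
      b0: 2.6681241751318
      b1: -0.406
      b2: 0.007
    dev_var:
      family: cloglog
      beta: 10.0
adult_longevity:
  family: hilbert_logan
  params:
    psi: 0.297
    d: 8.0
    t_base: 10.0
    t_max: 40.0
    delta: 6.0
fecundity:
  c0: -330.0
  c1: 30.0
  c2: -0.5
  gamma_shape: 2.0
  gamma_scale: 0.15
sex_ratio: 0.5
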