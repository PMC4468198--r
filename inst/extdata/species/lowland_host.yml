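species_name: lowland_host
stages:
  egg:
    dev_rate:
      psi: 0.025169394220658
      rho: 0.15
      t_base: 10.0
      t_max: 38.0
      delta: 5.0
    mortality:
      b0: 3.311767726446009
      b1: -0.435
      b2: 0.0075
    dev_var:
      family: logit
      beta: 8.0
  larva:
    dev_rate:
      psi: 0.005393441618712
      rho: 0.15
      t_base: 10.0
      t_max: 38.0
      delta: 5.0
    mortality:
      b0: 3.361271355691745
      b1: -0.406
      b2: 0.007
    dev_var:
      family: logit
      beta: 8.0
  pupa:
    dev_rate:
      psi: 0.016779596147105
      rho: 0.15
      t_base: 10.0
      t_max: 38.0
      delta: 5.0
    mortality:
      b0: 3.732267726446009
      b1: -0.464
      b2: 0.008
    dev_var:
      family: cloglog
      beta: 10.0
adult_longevity:
  family: stinner
  params:
    c_max: 30.0
    k1: -3.195
    k2: 0.12
fecundity:
  c0: -600.0
  c1: 60.0
  c2: -1.0
  gamma_shape: 3.0
  gamma_scale: 0.12
sex_ratio: 0.5
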