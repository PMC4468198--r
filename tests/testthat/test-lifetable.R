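# Stochastic cohort simulation and the Euler-Lotka machinery.

test_that("rate summation gives exact stage durations without variability or mortality", {
  sp <- ideal_species()            # rate 0.1/day at 25, no mortality
  cfg <- cohort_config(n_individuals = 50, seed = 2, driver = "hourly")
  res <- lifetable_at_constant(sp, 25, cfg)
  # every individual completes each stage in 10 days (within one hourly step)
  for (stg in c("egg", "larva", "pupa")) {
    d <- res$dev_durations[[stg]]
    expect_true(all(!is.na(d)))
    expect_true(all(abs(d - 10) <= 1 / 24 + 1e-9))
  }
  expect_true(all(res$stage_survival == 1))
})

test_that("net reproduction matches its closed-form expectation", {
  # no mortality, sex ratio 0.5, lifetime fecundity 100 -> R0 = 50
  sp <- ideal_species(fecundity = 100, sex_ratio = 0.5)
  cfg <- cohort_config(n_individuals = 200, seed = 5, driver = "hourly")
  res <- lifetable_at_constant(sp, 25, cfg)
  expect_lt(abs(res$net_reproduction - 50) / 50, 0.02)
  expect_false(res$extinct)
  # generation time assembles from stage durations plus mean oviposition age:
  # adult life is 10 days starting on day 31 (ages 30..39)
  frac <- oviposition_fraction(seq(0, 0.9, 0.1), seq(0.1, 1, 0.1),
                               sp$fecundity)
  expect_lt(abs(res$generation_time - sum((30:39) * frac)), 1.1)
})

test_that("demographic identities hold to numerical precision", {
  sp <- make_species("lowland_host")
  cfg <- cohort_config(n_individuals = 300, seed = 9, driver = "hourly")
  w <- make_transect(transect_spec(seed = 3))$stations[[1]]
  res <- simulate_cohort(sp, w, cfg)
  expect_false(res$extinct)
  lxmx <- res$lx_mx$lx * res$lx_mx$mx
  expect_equal(res$net_reproduction, sum(lxmx), tolerance = 1e-9)
  expect_equal(res$finite_rate, exp(res$intrinsic_rate), tolerance = 1e-12)
  expect_equal(res$doubling_time, log(2) / res$intrinsic_rate,
               tolerance = 1e-12)
  expect_equal(res$generation_time,
               sum(res$lx_mx$age * lxmx) / sum(lxmx), tolerance = 1e-9)
  # survivorship is a proper non-increasing curve
  expect_true(all(res$lx_mx$lx >= 0 & res$lx_mx$lx <= 1))
  expect_true(all(diff(res$lx_mx$lx) <= 1e-12))
  # rm refitted from the tabulated schedule reproduces the stored rm
  expect_equal(solve_euler_lotka(res$lx_mx$age, lxmx), res$intrinsic_rate,
               tolerance = 1e-10)
  # and satisfies the renewal equation
  r <- res$intrinsic_rate
  expect_lt(abs(sum(exp(-r * res$lx_mx$age) * lxmx) - 1), 1e-10)
})

test_that("same seed and inputs give a bit-identical result", {
  sp <- make_species("highland_host")
  w <- make_transect(transect_spec(seed = 8))$stations[[3]]
  cfg <- cohort_config(n_individuals = 120, seed = 77, driver = "hourly")
  expect_identical(simulate_cohort(sp, w, cfg), simulate_cohort(sp, w, cfg))
  cfg2 <- cfg; cfg2$seed <- 78L
  expect_false(identical(simulate_cohort(sp, w, cfg),
                         simulate_cohort(sp, w, cfg2)))
})

test_that("median stage duration matches 1/rate within Monte-Carlo error", {
  sp <- ideal_species(beta = 8)    # realistic development-time spread
  cfg <- cohort_config(n_individuals = 2000, seed = 13, driver = "hourly")
  res <- lifetable_at_constant(sp, 25, cfg)
  # multiplier is exp(Logistic(0, 1/8)); density of the multiplier at its
  # median 1 is beta/4, so se(median) = 1/(2 f sqrt(n)) in multiplier units
  se_med <- 10 / (2 * (8 / 4) * sqrt(2000))
  # the logit family has median multiplier exactly 1; the cloglog family
  # used for pupae has analytic median (ln 2)^(1/beta)
  expected <- c(egg = 10, larva = 10, pupa = 10 * log(2)^(1 / 8))
  for (stg in c("egg", "larva", "pupa")) {
    med <- stats::median(res$dev_durations[[stg]], na.rm = TRUE)
    expect_lt(abs(med - expected[[stg]]), 3 * se_med + 1 / 24)
  }
})

test_that("lethal conditions produce an extinct flag, not an error", {
  sp <- ideal_species()
  cfg <- cohort_config(n_individuals = 20, seed = 1, driver = "daily_mean",
                       max_days = 200)
  res <- lifetable_at_constant(sp, 50, cfg)   # above t_max: all rates 0
  expect_true(res$extinct)
  expect_equal(res$net_reproduction, 0)
  expect_true(is.na(res$intrinsic_rate))
  expect_true(is.na(res$finite_rate))
})

test_that("Euler-Lotka solver agrees with closed forms and a bisection oracle", {
  # point schedule: all reproduction at age 40 with R0 = 50
  expect_equal(solve_euler_lotka(40, 50), log(50) / 40, tolerance = 1e-10)
  # R0 = 1 gives rm = 0
  expect_equal(solve_euler_lotka(c(20, 30), c(0.5, 0.5)), 0, tolerance = 1e-10)
  # two-point schedule vs an independent bisection
  age <- c(30, 50); lxmx <- c(10, 10)
  expect_equal(solve_euler_lotka(age, lxmx),
               bisect_euler_lotka(age, lxmx), tolerance = 1e-8)
  # a schedule with rm outside the initial bracket still solves
  expect_equal(solve_euler_lotka(1, 50), log(50), tolerance = 1e-8)
  expect_warning(r <- solve_euler_lotka(c(10, 20), c(0, 0)), "R0")
  expect_true(is.na(r))
})

test_that("rm profiles interpolate exactly at nodes and clamp outside the hull", {
  sp <- make_species("lowland_host")
  cfg <- cohort_config(n_individuals = 150, seed = 21, driver = "daily_mean")
  prof <- rm_profile(sp, seq(12, 40, by = 4), cfg)
  expect_equal(rm_lookup(prof, prof$t), prof$rm, tolerance = 1e-12)
  # continuity at midpoints: linear interpolation of the neighbours
  mids <- (prof$t[-1] + prof$t[-length(prof$t)]) / 2
  expect_equal(rm_lookup(prof, mids),
               (prof$rm[-1] + prof$rm[-length(prof$rm)]) / 2,
               tolerance = 1e-12)
  expect_warning(v <- rm_lookup(prof, 44), "clamped")
  expect_equal(v, prof$rm[length(prof$rm)])
  # lethal upper node carries the extinct sentinel floor
  expect_equal(prof$rm[length(prof$rm)], prof$rm_floor)
  # the lowland profile is unimodal in temperature
  dr <- diff(prof$rm)
  expect_lte(sum(diff(sign(dr[dr != 0])) != 0), 1)
})
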