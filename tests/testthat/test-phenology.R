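# Closed-form temperature-response functions and their parameter containers.

test_that("Logan development rate matches direct evaluation and clamps at the limits", {
  p <- logan_params(psi = 0.03, rho = 0.15, t_base = 10, t_max = 40, delta = 5)
  # frozen from independent evaluation of the closed form
  expect_equal(development_rate(25, p), 0.1501814, tolerance = 1e-6)
  expect_equal(development_rate(40, p), 0)          # exponentials cancel
  expect_equal(development_rate(45, p), 0)          # clamped above t_max
  expect_equal(development_rate(10, p), 0)          # zero at t_base
  expect_equal(development_rate(5, p), 0)
  expect_error(development_rate(NaN, p), "finite")
  expect_error(logan_params(0.03, 0.15, 40, 10, 5), "t_max")
  expect_error(logan_params(-1, 0.15, 10, 40, 5), "psi")
})

test_that("stage mortality is the clamped exponential quadratic", {
  p <- mortality_params(-8, 0.45, -0.0105)
  expect_equal(stage_mortality(20, p), exp(-3.2), tolerance = 1e-12)
  expect_equal(stage_mortality(20, p), 0.0408, tolerance = 1e-3)
  # exponent >= 0 clamps at 1
  expect_equal(stage_mortality(0, mortality_params(2, 0, 0)), 1)
  # vertex of the quadratic is the mortality minimum when b2 < 0... b2 > 0
  p2 <- mortality_params(-3 + 0.01 * 25^2, -2 * 0.01 * 25, 0.01)
  tt <- seq(0, 50, by = 0.5)
  expect_equal(tt[which.min(stage_mortality(tt, p2))], 25)
  expect_error(stage_mortality(Inf, p), "finite")
})

test_that("development-time multiplier quantile function behaves per family", {
  lg <- dev_var_params("logit", 8)
  expect_equal(sample_dev_multiplier(0.5, lg), 1)                 # median
  expect_equal(sample_dev_multiplier(0.75, lg), exp(log(3) / 8),
               tolerance = 1e-12)
  cl <- dev_var_params("cloglog", 8)
  expect_equal(sample_dev_multiplier(1 - exp(-1), cl), 1, tolerance = 1e-12)
  # strictly increasing in u
  u <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(diff(sample_dev_multiplier(u, lg)) > 0))
  expect_true(all(diff(sample_dev_multiplier(u, cl)) > 0))
  expect_error(sample_dev_multiplier(0, lg), "\\(0, 1\\)")
  expect_error(sample_dev_multiplier(1, cl), "\\(0, 1\\)")
  # empirical median of logit draws is 1 within 1%
  med <- withr::with_seed(11, {
    stats::median(sample_dev_multiplier(stats::runif(1e5), lg))
  })
  expect_lt(abs(med - 1), 0.01)
})

test_that("adult longevity models match their closed forms", {
  st <- stinner_params(40, -6, 0.28)
  expect_equal(adult_longevity(20, st), 40 / (1 + exp(-0.4)), tolerance = 1e-12)
  expect_equal(adult_longevity(20, st), 23.95, tolerance = 1e-3)
  # k2 = 0 gives a temperature-independent longevity
  st0 <- stinner_params(40, -6, 0)
  expect_equal(adult_longevity(0, st0), adult_longevity(45, st0))
  # longevity -> 0 as t grows with k2 > 0
  expect_lt(adult_longevity(200, st), 1e-6)

  hl <- hilbert_logan_params(0.1, 8, 10, 40, 6)
  expect_equal(senescence_rate(30, hl),
               0.1 * (400 / 464 - exp(-10 / 6)), tolerance = 1e-12)
  expect_equal(senescence_rate(30, hl), 0.06732, tolerance = 1e-4)
  expect_equal(senescence_rate(10, hl), 0)   # negative bracket clamps to 0
  expect_equal(senescence_rate(40, hl),
               max(0, 0.1 * (30^2 / (30^2 + 64) - 1)))
})

test_that("fecundity quadratic and gamma oviposition profile are consistent", {
  p <- fecundity_params(-300, 40, -0.8, 2, 0.15)
  expect_equal(total_fecundity(25, p), 200)
  expect_equal(total_fecundity(60, p), 0)    # beyond the roots, clamped
  expect_equal(total_fecundity(5, fecundity_params(50, 0, 0, 2, 0.15)), 50)

  expect_equal(oviposition_fraction(0, 1, p), 1, tolerance = 1e-12)
  expect_equal(oviposition_fraction(0, 0.5, p) + oviposition_fraction(0.5, 1, p),
               1, tolerance = 1e-12)
  # frozen from pgamma: (1 - e^-2 * 3) / pgamma(1, 2, scale = 0.15)
  expect_equal(oviposition_fraction(0, 0.3, p), 0.5998468, tolerance = 1e-6)
  # any partition sums to 1
  cuts <- c(0, sort(withr::with_seed(3, stats::runif(7))), 1)
  expect_equal(sum(oviposition_fraction(cuts[-9], cuts[-1], p)), 1,
               tolerance = 1e-12)
  expect_error(oviposition_fraction(0.5, 0.5, p), "a0 < a1")
})

test_that("rates and mortalities are finite and non-negative over a broad sweep", {
  tt <- seq(-20, 60, by = 0.5)
  for (prof in c("lowland_host", "highland_host", "lowland_parasitoid",
                 "highland_parasitoid")) {
    sp <- make_species(prof)
    for (stg in sp$stages) {
      r <- development_rate(tt, stg$dev_rate)
      m <- stage_mortality(tt, stg$mortality)
      expect_true(all(is.finite(r)) && all(r >= 0))
      expect_true(all(is.finite(m)) && all(m >= 0) && all(m <= 1))
    }
    expect_true(all(total_fecundity(tt, sp$fecundity) >= 0))
    if (inherits(sp$adult_longevity, "stinner_params")) {
      expect_true(all(adult_longevity(tt, sp$adult_longevity) > 0))
    } else {
      expect_true(all(senescence_rate(tt, sp$adult_longevity) >= 0))
    }
  }
})

test_that("shipped development-rate curves are unimodal between the thermal limits", {
  for (prof in c("lowland_host", "highland_host", "lowland_parasitoid",
                 "highland_parasitoid")) {
    sp <- make_species(prof)
    for (stg in sp$stages) {
      p <- stg$dev_rate
      tt <- seq(p$t_base + 0.1, p$t_max - 0.1, by = 0.1)
      dr <- diff(development_rate(tt, p))
      sign_changes <- sum(diff(sign(dr[dr != 0])) != 0)
      expect_lte(sign_changes, 1)
    }
  }
})

test_that("species models validate structure and survive a file round trip", {
  sp <- make_species("lowland_host")
  expect_s3_class(sp, "species_model")
  expect_named(sp$stages, c("egg", "larva", "pupa"))
  expect_error(species_model("x", egg = sp$stages$larva,
                             larva = sp$stages$larva, pupa = sp$stages$pupa,
                             adult_longevity = sp$adult_longevity,
                             fecundity = sp$fecundity),
               "stage_model named 'egg'")
  expect_error(species_model("x", egg = sp$stages$egg,
                             larva = sp$stages$larva, pupa = sp$stages$pupa,
                             adult_longevity = list(a = 1),
                             fecundity = sp$fecundity),
               "adult_longevity")

  tmp <- withr::local_tempfile(fileext = ".yml")
  write_species(sp, tmp)
  expect_equal(read_species(tmp), sp, tolerance = 1e-9)
  # schema validation rejects a file with a missing stage
  doc <- yaml::read_yaml(tmp)
  doc$stages$larva <- NULL
  tmp2 <- withr::local_tempfile(fileext = ".yml")
  yaml::write_yaml(doc, tmp2)
  expect_error(read_species(tmp2), "larva")
})

test_that("shipped species fixtures load and match the generators", {
  dir <- system.file("extdata", "species", package = "phenorisk")
  for (prof in c("lowland_host", "highland_host", "lowland_parasitoid",
                 "highland_parasitoid")) {
    sp <- read_species(file.path(dir, paste0(prof, ".yml")))
    expect_equal(sp, make_species(prof), tolerance = 1e-9)
  }
})
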