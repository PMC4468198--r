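# Shared fixtures: analytically tractable species and weather built in code.

# Logan parameters whose rate at 25 degC is exactly `rate25`
logan_rate25 <- function(rate25 = 0.1, rho = 0.15, t_base = 10, t_max = 40,
                         delta = 5) {
  shape <- exp(rho * (25 - t_base)) -
    exp(rho * (t_max - t_base) - (t_max - 25) / delta)
  logan_params(psi = rate25 / shape, rho = rho, t_base = t_base,
               t_max = t_max, delta = delta)
}

# temperature-independent stage mortality m
const_mortality <- function(m) {
  mortality_params(b0 = if (m <= 0) -50 else log(m), b1 = 0, b2 = 0)
}

# near-degenerate development-time variability (multiplier ~ 1)
no_var <- function() dev_var_params("logit", 1e6)

# analytically tractable species: rate 0.1/day at 25 in every stage,
# constant mortalities, constant adult longevity, constant fecundity
ideal_species <- function(mort = c(0, 0, 0), fecundity = 100,
                          longevity_days = 10, beta = 1e6,
                          sex_ratio = 0.5, gshape = 3, gscale = 0.12) {
  dv <- dev_var_params("logit", beta)
  k1 <- log(30 / longevity_days - 1)   # Stinner with k2 = 0, c_max = 30
  species_model("ideal",
    egg = stage_model("egg", logan_rate25(), const_mortality(mort[1]), dv),
    larva = stage_model("larva", logan_rate25(), const_mortality(mort[2]), dv),
    pupa = stage_model("pupa", logan_rate25(), const_mortality(mort[3]),
                       dev_var_params("cloglog", beta)),
    adult_longevity = stinner_params(30, k1, 0),
    fecundity = fecundity_params(fecundity, 0, 0, gshape, gscale),
    sex_ratio = sex_ratio)
}

const_weather <- function(t, id = "const", alt = 0) {
  weather_series(id, 0, 0, alt, rep(t, 365), rep(t, 365))
}

# small non-collinear station set on a synthetic slope
demo_stations <- function() {
  tr <- make_transect(transect_spec(seed = 1))
  tr
}

# independent bisection root-finder for the Euler-Lotka equation
bisect_euler_lotka <- function(age, lxmx, lo = -1, hi = 1, tol = 1e-12) {
  f <- function(r) sum(exp(-r * age) * lxmx) - 1
  while (f(lo) < 0) lo <- lo * 2
  while (f(hi) > 0) hi <- hi * 2
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
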