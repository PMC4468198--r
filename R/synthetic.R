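## Seeded generators for every input the pipeline needs: altitudinal
## weather transects with a one-sided mountain DEM, species parameter
## profiles, monthly warming scenarios and per-zone observed losses.

#' Transect generation specification
#'
#' Describes a synthetic altitudinal weather transect: stations evenly
#' spaced in altitude, a single annual temperature harmonic, a fixed
#' diurnal range and i.i.d. daily noise.  Defaults emulate a 6-station
#' East African mountain transect spanning 700-1800 m with a standard
#' -6.5 degC/km lapse rate; passing `lapse_rate = -4.55` reproduces the
#' design in which adjacent stations differ by about 1 degC in annual
#' mean.
#'
#' @param n_stations Number of stations (>= 2).
#' @param alt_range Altitude span (m), low to high.
#' @param lapse_rate Temperature lapse, degC per km of altitude (negative).
#' @param base_tmean Annual mean temperature at sea level, degC.
#' @param seasonal_amplitude Annual harmonic amplitude, degC (peak around
#'   mid February, day 45).
#' @param diurnal_range tmax - tmin, degC (constant).
#' @param noise_sd SD of i.i.d. daily noise on the mean, degC.
#' @param seed Integer seed.
#' @return An object of class `transect_spec`.
#' @export
transect_spec <- function(n_stations = 6, alt_range = c(700, 1800),
                          lapse_rate = -6.5, base_tmean = 28,
                          seasonal_amplitude = 2, diurnal_range = 10,
                          noise_sd = 1, seed = 1) {
  if (n_stations < 2) stop("n_stations must be >= 2")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (length(alt_range) != 2 || alt_range[1] >= alt_range[2])
    stop("alt_range must be (low, high)")
  structure(list(n_stations = as.integer(n_stations),
                 alt_range = as.numeric(alt_range),
                 lapse_rate = lapse_rate, base_tmean = base_tmean,
                 seasonal_amplitude = seasonal_amplitude,
                 diurnal_range = diurnal_range, noise_sd = noise_sd,
                 seed = as.integer(seed)), class = "transect_spec")
}

## One-sided mountain slope: monotone, deliberately non-affine in x so the
## elevation covariate is not collinear with the trend coordinates.
demo_elevation <- function(x, xmax, e_lo, e_hi) {
  e_lo + (e_hi - e_lo) * (x / xmax)^1.3
}

#' Generate a synthetic altitudinal transect
#'
#' Builds `n_stations` weather series evenly spaced in altitude, a DEM
#' `ascii_grid` forming a one-sided mountain slope that contains every
#' station at a cell of matching elevation, and the station coordinates.
#' Daily mean temperature is
#' `base_tmean + lapse_rate * alt/1000 + seasonal_amplitude *
#' cos(2 pi (day - 45)/365) + noise`, and tmin/tmax are the mean -/+ half
#' the diurnal range.  Fully reproducible from the seed in `spec`.
#'
#' @param spec A [transect_spec()].
#' @return List with elements `stations` (named list of
#'   [weather_series()]), `dem` (an [ascii_grid()] of elevations) and
#'   `coords` (data.frame station_id, x, y, alt).
#' @export
make_transect <- function(spec) {
  stopifnot(inherits(spec, "transect_spec"))
  n <- spec$n_stations
  alts <- seq(spec$alt_range[1], spec$alt_range[2], length.out = n)
  ## DEM geometry: 60 x 40 cells of 500 m, slope rising eastwards
  nc <- 60L; nr <- 40L; cs <- 500
  xmax <- nc * cs
  e_lo <- spec$alt_range[1] - 100; e_hi <- spec$alt_range[2] + 100
  xc <- (seq_len(nc) - 0.5) * cs
  elev_row <- demo_elevation(xc, xmax, e_lo, e_hi)
  dem <- ascii_grid(matrix(elev_row, nr, nc, byrow = TRUE), 0, 0, cs)
  ## station x from inverting the slope; y staggered so stations are not
  ## collinear (the TPS trend needs full rank)
  sx <- xmax * ((alts - e_lo) / (e_hi - e_lo))^(1 / 1.3)
  sy <- nr * cs * (0.5 + 0.15 * rep_len(c(-1, 1), n))
  ids <- sprintf("st%02d_%04dm", seq_len(n), round(alts))
  day <- 1:365
  seasonal <- spec$seasonal_amplitude * cos(2 * pi * (day - 45) / 365)
  stations <- withr::with_seed(spec$seed, {
    lapply(seq_len(n), function(i) {
      tmean <- spec$base_tmean + spec$lapse_rate * alts[i] / 1000 +
        seasonal + stats::rnorm(365, 0, spec$noise_sd)
      weather_series(ids[i], lon = sx[i], lat = sy[i], alt = alts[i],
                     tmin = tmean - spec$diurnal_range / 2,
                     tmax = tmean + spec$diurnal_range / 2)
    })
  })
  names(stations) <- ids
  list(stations = stations, dem = dem,
       coords = data.frame(station_id = ids, x = sx, y = sy, alt = alts))
}

## Canonical synthetic species profiles ---------------------------------------

## psi such that the Logan rate at t_ref equals 1/duration days
logan_for <- function(duration, t_ref, rho, t_base, t_max, delta) {
  shape <- exp(rho * (t_ref - t_base)) -
    exp(rho * (t_max - t_base) - (t_max - t_ref) / delta)
  logan_params(psi = (1 / duration) / shape, rho = rho, t_base = t_base,
               t_max = t_max, delta = delta)
}

## mortality with minimum m_min at t_opt and curvature k
mortality_for <- function(m_min, t_opt, k) {
  mortality_params(b0 = log(m_min) + k * t_opt^2, b1 = -2 * k * t_opt,
                   b2 = k)
}

## fecundity peaking at f_peak at t_opt with downward curvature c
fecundity_for <- function(f_peak, t_opt, c, gamma_shape, gamma_scale) {
  fecundity_params(c0 = f_peak - c * t_opt^2, c1 = 2 * c * t_opt, c2 = -c,
                   gamma_shape = gamma_shape, gamma_scale = gamma_scale)
}

SPECIES_PROFILES <- c("lowland_host", "highland_host",
                      "lowland_parasitoid", "highland_parasitoid")

#' Generate a canonical synthetic species profile
#'
#' Four qualitative profiles mirroring the ecological contrast between a
#' warm-adapted lowland stem borer, a cool-adapted highland stem borer and
#' their respective larval parasitoids: the lowland profiles have thermal
#' optima near 30 degC and the highland ones in the mid 20s (development
#' tuned at 24 degC), at least 4 degC apart, and parasitoids develop
#' markedly faster (more generations per year) than their hosts.
#' The lowland parasitoid uses the Hilbert-Logan senescence family, the
#' other three the Stinner longevity family.  Parameters are fixed
#' canonical values, so the output is deterministic (the seed is part of
#' the generator interface but introduces no variation).
#'
#' @param profile One of `"lowland_host"`, `"highland_host"`,
#'   `"lowland_parasitoid"`, `"highland_parasitoid"`.
#' @param seed Integer seed (kept for interface symmetry).
#' @return A [species_model()].
#' @export
make_species <- function(profile, seed = 1) {
  profile <- match.arg(profile, SPECIES_PROFILES)
  ## m_opt: temperature of minimum immature mortality.  For the lowland
  ## profiles it sits just below the development optimum; the cool-adapted
  ## highland profiles are warm-sensitive, with lowest mortality well below
  ## their development optimum, which is what reverses their establishment
  ## gradient along the transect.
  mk <- function(t_opt, m_opt, durs, m_mins, ks, f_peak, f_curv, longevity,
                 rho, t_base, t_max, delta, gshape, gscale) {
    species_model(profile,
      egg = stage_model("egg",
        logan_for(durs[1], t_opt, rho, t_base, t_max, delta),
        mortality_for(m_mins[1], m_opt, ks[1]),
        dev_var_params("logit", 8)),
      larva = stage_model("larva",
        logan_for(durs[2], t_opt, rho, t_base, t_max, delta),
        mortality_for(m_mins[2], m_opt, ks[2]),
        dev_var_params("logit", 8)),
      pupa = stage_model("pupa",
        logan_for(durs[3], t_opt, rho, t_base, t_max, delta),
        mortality_for(m_mins[3], m_opt, ks[3]),
        dev_var_params("cloglog", 10)),
      adult_longevity = longevity,
      fecundity = fecundity_for(f_peak, t_opt, f_curv, gshape, gscale),
      sex_ratio = 0.5)
  }
  switch(profile,
    lowland_host = mk(
      t_opt = 30, m_opt = 29, durs = c(6, 28, 9),
      m_mins = c(0.05, 0.08, 0.05), ks = c(0.0075, 0.007, 0.008), f_peak = 300, f_curv = 1.0,
      longevity = stinner_params(30, -3.195, 0.12),
      rho = 0.15, t_base = 10, t_max = 38, delta = 5,
      gshape = 3, gscale = 0.12),
    highland_host = mk(
      t_opt = 24, m_opt = 18, durs = c(8, 35, 12),
      m_mins = c(0.06, 0.09, 0.06), ks = c(0.012, 0.012, 0.012), f_peak = 250, f_curv = 0.9,
      longevity = stinner_params(35, -2.45, 0.11),
      rho = 0.12, t_base = 6, t_max = 33, delta = 5,
      gshape = 3, gscale = 0.12),
    lowland_parasitoid = mk(
      t_opt = 30, m_opt = 29, durs = c(3, 8, 4),
      m_mins = c(0.04, 0.06, 0.04), ks = c(0.007, 0.0065, 0.007), f_peak = 120, f_curv = 0.5,
      longevity = hilbert_logan_params(psi = 0.297, d = 8, t_base = 10,
                                       t_max = 40, delta = 6),
      rho = 0.15, t_base = 11, t_max = 38, delta = 5,
      gshape = 2, gscale = 0.15),
    highland_parasitoid = mk(
      t_opt = 24, m_opt = 19, durs = c(3.5, 9, 4.5),
      m_mins = c(0.05, 0.07, 0.05), ks = c(0.010, 0.010, 0.010), f_peak = 130, f_curv = 0.55,
      longevity = stinner_params(25, -1.347, 0.10),
      rho = 0.13, t_base = 7, t_max = 34, delta = 5,
      gshape = 2, gscale = 0.15))
}

#' Generate a monthly warming scenario
#'
#' Twelve monthly tmin/tmax deltas with annual mean `warming_c` and a
#' seasonal cosine modulation of half-range `seasonal_skew`; the defaults
#' (1.45 +/- 0.45 degC) span a 1.0-1.9 degC monthly warming range.
#' Deterministic given the arguments (the seed introduces no variation).
#'
#' @param warming_c Mean annual warming, degC.
#' @param seasonal_skew Half-range of the seasonal modulation, degC.
#' @param seed Integer seed (interface symmetry).
#' @return A [scenario_delta()] with equal tmin and tmax deltas.
#' @export
make_scenario <- function(warming_c = 1.45, seasonal_skew = 0.45, seed = 1) {
  if (!is.finite(warming_c)) stop("warming_c must be finite")
  d <- warming_c + seasonal_skew * cos(2 * pi * (0:11) / 12)
  scenario_delta(d, d)
}

#' Generate observed per-zone losses from a known linear relation
#'
#' `loss = true_beta0 + true_beta1 * ai + Normal(0, noise_sd)` per zone,
#' clamped at >= 0 (losses are percentages).  Used to fabricate the
#' exogenous observed-loss inputs of the yield-loss regression with a
#' known ground truth.
#'
#' @param true_beta0,true_beta1 Ground-truth intercept and slope.
#' @param ai_per_zone Activity index per zone (>= 3 zones).
#' @param noise_sd SD of the additive noise.
#' @param seed Integer seed.
#' @return Numeric vector of percent losses.
#' @export
make_observed_losses <- function(true_beta0, true_beta1, ai_per_zone,
                                 noise_sd, seed) {
  if (length(ai_per_zone) < 3) stop("need >= 3 zones")
  withr::with_seed(seed, pmax(0, true_beta0 + true_beta1 * ai_per_zone +
                                   stats::rnorm(length(ai_per_zone), 0,
                                                noise_sd)))
}

#' Write the full demo fixture to a directory
#'
#' Writes the complete synthetic input set: `weather.csv` (all stations),
#' `dem.asc`, one YAML file per species profile, `scenario.csv` and
#' `observed_losses.csv` (fabricated from the default ground-truth
#' relation against the station-altitude zones).
#'
#' @param dir Target directory (created if missing).
#' @param seed Integer seed controlling every stochastic component.
#' @return `dir`, invisibly.
#' @export
write_demo_fixture <- function(dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tr <- make_transect(transect_spec(seed = seed))
  write_weather(tr$stations, file.path(dir, "weather.csv"))
  write_asc(tr$dem, file.path(dir, "dem.asc"))
  for (p in SPECIES_PROFILES)
    write_species(make_species(p, seed), file.path(dir, paste0(p, ".yml")))
  write_scenario(make_scenario(seed = seed), file.path(dir, "scenario.csv"))
  zones <- default_zones()
  ai_guess <- seq(8, 2, length.out = nrow(zones))  # placeholder zone AI
  losses <- make_observed_losses(-2, 3, ai_guess, 1, seed)
  utils::write.csv(data.frame(zone = zones$zone, observed_pct = losses),
                   file.path(dir, "observed_losses.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(dir)
}
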