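#' @keywords internal
"_PACKAGE"

## Parameter constructors -----------------------------------------------------

check_num <- function(x, name, len = 1L) {
  if (!is.numeric(x) || length(x) != len || any(!is.finite(x)))
    stop("'", name, "' must be ", len, " finite numeric value(s)", call. = FALSE)
  as.numeric(x)
}

#' Logan development-rate parameters
#'
#' Parameters of the Logan (type-I) temperature-dependent development-rate
#' curve used for the immature stages (egg, larva, pupa).
#'
#' @param psi Scale parameter (1/day), > 0.
#' @param rho Rate coefficient (1/degree C), > 0.
#' @param t_base Lower reference temperature (degree C).
#' @param t_max Lethal maximum temperature (degree C), > `t_base`.
#' @param delta Width of the high-temperature decay (degree C), > 0.
#' @return An object of class `logan_params`.
#' @seealso [development_rate()]
#' @export
logan_params <- function(psi, rho, t_base, t_max, delta) {
  psi <- check_num(psi, "psi"); rho <- check_num(rho, "rho")
  t_base <- check_num(t_base, "t_base"); t_max <- check_num(t_max, "t_max")
  delta <- check_num(delta, "delta")
  if (psi <= 0) stop("psi must be > 0")
  if (rho <= 0) stop("rho must be > 0")
  if (delta <= 0) stop("delta must be > 0")
  if (t_max <= t_base) stop("t_max must exceed t_base")
  structure(list(psi = psi, rho = rho, t_base = t_base, t_max = t_max,
                 delta = delta), class = "logan_params")
}

#' Exponential-polynomial stage-mortality parameters
#'
#' Coefficients of the second-order exponential polynomial describing
#' whole-stage mortality of an immature stage at constant temperature:
#' m(t) = min(1, exp(b0 + b1 t + b2 t^2)).
#'
#' @param b0,b1,b2 Polynomial coefficients (dimensionless, 1/degree C,
#'   1/degree C^2). `b2` may have any sign.
#' @return An object of class `mortality_params`.
#' @seealso [stage_mortality()]
#' @export
mortality_params <- function(b0, b1, b2) {
  structure(list(b0 = check_num(b0, "b0"), b1 = check_num(b1, "b1"),
                 b2 = check_num(b2, "b2")), class = "mortality_params")
}

#' Development-time variability parameters
#'
#' Family and slope of the distribution of individual development-time
#' multipliers on log-normalised time.  The intercept is fixed at zero, so
#' for the logit family the median multiplier is exactly 1 and `beta` alone
#' controls the spread (larger `beta` = less variability).
#'
#' @param family `"logit"` (eggs, larvae) or `"cloglog"` (pupae).
#' @param beta Positive slope on log-normalised time (dimensionless).
#' @return An object of class `dev_var_params`.
#' @seealso [sample_dev_multiplier()]
#' @export
dev_var_params <- function(family = c("logit", "cloglog"), beta) {
  family <- match.arg(family)
  beta <- check_num(beta, "beta")
  if (beta <= 0) stop("beta must be > 0")
  structure(list(family = family, beta = beta), class = "dev_var_params")
}

#' Stinner adult-longevity parameters
#'
#' Three-parameter logistic relationship between adult female longevity and
#' temperature: L(t) = c_max / (1 + exp(k1 + k2 t)).
#'
#' @param c_max Asymptotic longevity (days), > 0.
#' @param k1 Intercept (dimensionless).
#' @param k2 Slope (1/degree C); positive values give longevity decreasing
#'   with temperature.
#' @return An object of class `stinner_params`.
#' @seealso [adult_longevity()]
#' @export
stinner_params <- function(c_max, k1, k2) {
  c_max <- check_num(c_max, "c_max")
  if (c_max <= 0) stop("c_max must be > 0")
  structure(list(c_max = c_max, k1 = check_num(k1, "k1"),
                 k2 = check_num(k2, "k2")), class = "stinner_params")
}

#' Hilbert-Logan senescence-rate parameters
#'
#' Sigmoid-minus-exponential senescence rate for adults; under constant
#' temperature the adult lifespan is 1/rate.
#'
#' @param psi Scale (1/day), > 0.
#' @param d Half-saturation width (degree C), > 0.
#' @param t_base,t_max Lower reference and lethal maximum temperatures
#'   (degree C), `t_max > t_base`.
#' @param delta High-temperature decay width (degree C), > 0.
#' @return An object of class `hilbert_logan_params`.
#' @seealso [senescence_rate()]
#' @export
hilbert_logan_params <- function(psi, d, t_base, t_max, delta) {
  psi <- check_num(psi, "psi"); d <- check_num(d, "d")
  t_base <- check_num(t_base, "t_base"); t_max <- check_num(t_max, "t_max")
  delta <- check_num(delta, "delta")
  if (psi <= 0) stop("psi must be > 0")
  if (d <= 0) stop("d must be > 0")
  if (delta <= 0) stop("delta must be > 0")
  if (t_max <= t_base) stop("t_max must exceed t_base")
  structure(list(psi = psi, d = d, t_base = t_base, t_max = t_max,
                 delta = delta), class = "hilbert_logan_params")
}

#' Fecundity parameters
#'
#' Quadratic lifetime total fecundity in temperature,
#' F(t) = max(0, c0 + c1 t + c2 t^2), combined with a gamma-distribution
#' profile over normalised adult age (0 = emergence, 1 = death) that
#' allocates the lifetime total across adult life.
#'
#' @param c0,c1,c2 Quadratic coefficients (eggs/female scale).
#' @param gamma_shape,gamma_scale Positive parameters of the normalised-age
#'   oviposition profile.
#' @return An object of class `fecundity_params`.
#' @seealso [total_fecundity()], [oviposition_fraction()]
#' @export
fecundity_params <- function(c0, c1, c2, gamma_shape, gamma_scale) {
  gamma_shape <- check_num(gamma_shape, "gamma_shape")
  gamma_scale <- check_num(gamma_scale, "gamma_scale")
  if (gamma_shape <= 0 || gamma_scale <= 0)
    stop("gamma_shape and gamma_scale must be > 0")
  structure(list(c0 = check_num(c0, "c0"), c1 = check_num(c1, "c1"),
                 c2 = check_num(c2, "c2"), gamma_shape = gamma_shape,
                 gamma_scale = gamma_scale), class = "fecundity_params")
}

## Temperature-response functions ---------------------------------------------

check_temp <- function(t) {
  if (!is.numeric(t) || length(t) == 0 || any(!is.finite(t)))
    stop("temperature must be finite numeric", call. = FALSE)
  as.numeric(t)
}

#' Logan development rate
#'
#' Evaluates the Logan development-rate curve
#' r(t) = psi * (exp(rho (t - t_base)) - exp(rho (t_max - t_base) -
#' (t_max - t)/delta)), clamped below at zero.  The rate is zero at and
#' beyond the lethal limits.
#'
#' @param t Temperature(s), degree C.  Must be finite.
#' @param p A [logan_params()] object.
#' @return Development rate(s), 1/day (vectorised over `t`).
#' @examples
#' p <- logan_params(psi = 0.03, rho = 0.15, t_base = 10, t_max = 40, delta = 5)
#' development_rate(25, p)
#' @export
development_rate <- function(t, p) {
  stopifnot(inherits(p, "logan_params"))
  t <- check_temp(t)
  r <- p$psi * (exp(p$rho * (t - p$t_base)) -
                exp(p$rho * (p$t_max - p$t_base) - (p$t_max - t) / p$delta))
  r[t <= p$t_base | t >= p$t_max] <- 0
  pmax(0, r)
}

#' Whole-stage mortality at constant temperature
#'
#' m(t) = min(1, exp(b0 + b1 t + b2 t^2)); always in \[0, 1\].
#'
#' @param t Temperature(s), degree C.
#' @param p A [mortality_params()] object.
#' @return Mortality fraction(s) in \[0, 1\].
#' @export
stage_mortality <- function(t, p) {
  stopifnot(inherits(p, "mortality_params"))
  t <- check_temp(t)
  pmin(1, exp(p$b0 + p$b1 * t + p$b2 * t^2))
}

#' Sample a development-time multiplier
#'
#' Inverse CDF of the chosen family on log-normalised development time.
#' For the logit family the multiplier is exp(logit(u)/beta) with median
#' exactly 1; for the cloglog family it is exp(log(-log(1-u))/beta).
#'
#' @param u Uniform quantile(s) strictly inside (0, 1).
#' @param p A [dev_var_params()] object.
#' @return Positive multiplier(s); individual stage duration is the
#'   multiplier divided by the accumulated development rate.
#' @export
sample_dev_multiplier <- function(u, p) {
  stopifnot(inherits(p, "dev_var_params"))
  if (!is.numeric(u) || any(!is.finite(u)) || any(u <= 0) || any(u >= 1))
    stop("u must lie strictly in (0, 1)")
  z <- switch(p$family,
    logit   = log(u / (1 - u)),
    cloglog = log(-log(1 - u)))
  exp(z / p$beta)
}

#' Stinner adult longevity
#'
#' L(t) = c_max / (1 + exp(k1 + k2 t)); strictly positive and monotone in
#' temperature whenever k2 is non-zero.
#'
#' @param t Temperature(s), degree C.
#' @param p A [stinner_params()] object.
#' @return Longevity in days.
#' @export
adult_longevity <- function(t, p) {
  stopifnot(inherits(p, "stinner_params"))
  t <- check_temp(t)
  p$c_max / (1 + exp(p$k1 + p$k2 * t))
}

#' Hilbert-Logan senescence rate
#'
#' With t' = max(0, t - t_base):
#' rate = max(0, psi * (t'^2/(t'^2 + d^2) - exp(-(t_max - t)/delta))).
#' Under constant temperature the adult lifespan is 1/rate.
#'
#' @param t Temperature(s), degree C.
#' @param p A [hilbert_logan_params()] object.
#' @return Senescence rate(s), 1/day.
#' @export
senescence_rate <- function(t, p) {
  stopifnot(inherits(p, "hilbert_logan_params"))
  t <- check_temp(t)
  tp <- pmax(0, t - p$t_base)
  pmax(0, p$psi * (tp^2 / (tp^2 + p$d^2) - exp(-(p$t_max - t) / p$delta)))
}

#' Lifetime total fecundity
#'
#' F(t) = max(0, c0 + c1 t + c2 t^2), eggs per female over her whole life.
#'
#' @param t Temperature(s), degree C.
#' @param p A [fecundity_params()] object.
#' @return Eggs per female (non-negative).
#' @export
total_fecundity <- function(t, p) {
  stopifnot(inherits(p, "fecundity_params"))
  t <- check_temp(t)
  pmax(0, p$c0 + p$c1 * t + p$c2 * t^2)
}

#' Fraction of lifetime eggs laid in a normalised-age interval
#'
#' The oviposition profile is a gamma CDF on normalised adult age,
#' renormalised by its mass on \[0, 1\] so the whole lifespan integrates to 1.
#'
#' @param a0,a1 Normalised-age interval bounds, 0 <= a0 < a1 <= 1
#'   (vectorised elementwise).
#' @param p A [fecundity_params()] object.
#' @return Fraction(s) of lifetime eggs laid in (a0, a1].
#' @export
oviposition_fraction <- function(a0, a1, p) {
  stopifnot(inherits(p, "fecundity_params"))
  if (any(!is.finite(a0)) || any(!is.finite(a1)) ||
      any(a0 < 0) || any(a1 > 1) || any(a0 >= a1))
    stop("need 0 <= a0 < a1 <= 1")
  z <- stats::pgamma(1, shape = p$gamma_shape, scale = p$gamma_scale)
  (stats::pgamma(a1, shape = p$gamma_shape, scale = p$gamma_scale) -
   stats::pgamma(a0, shape = p$gamma_shape, scale = p$gamma_scale)) / z
}

## Stage and species containers ------------------------------------------------

STAGE_NAMES <- c("egg", "larva", "pupa")

#' Immature-stage model
#'
#' Bundles the three temperature responses of one immature stage.
#'
#' @param name One of `"egg"`, `"larva"`, `"pupa"`.
#' @param dev_rate A [logan_params()] object.
#' @param mortality A [mortality_params()] object.
#' @param dev_var A [dev_var_params()] object.
#' @return An object of class `stage_model`.
#' @export
stage_model <- function(name, dev_rate, mortality, dev_var) {
  name <- match.arg(name, STAGE_NAMES)
  stopifnot(inherits(dev_rate, "logan_params"),
            inherits(mortality, "mortality_params"),
            inherits(dev_var, "dev_var_params"))
  structure(list(name = name, dev_rate = dev_rate, mortality = mortality,
                 dev_var = dev_var), class = "stage_model")
}

#' Full species phenology model
#'
#' A complete thermal phenology parameterisation: the three immature stages
#' in egg -> larva -> pupa order, one adult-longevity family (Stinner
#' logistic or Hilbert-Logan senescence), fecundity, and the fraction of
#' eggs that are female.
#'
#' @param species_name Label.
#' @param egg,larva,pupa [stage_model()] objects with matching names.
#' @param adult_longevity A [stinner_params()] or [hilbert_logan_params()]
#'   object (exactly one family).
#' @param fecundity A [fecundity_params()] object.
#' @param sex_ratio Fraction of eggs that are female, in \[0, 1\].
#' @return An object of class `species_model`.
#' @export
species_model <- function(species_name, egg, larva, pupa, adult_longevity,
                          fecundity, sex_ratio = 0.5) {
  stopifnot(is.character(species_name), length(species_name) == 1)
  stages <- list(egg = egg, larva = larva, pupa = pupa)
  for (s in STAGE_NAMES) {
    if (!inherits(stages[[s]], "stage_model") || stages[[s]]$name != s)
      stop("'", s, "' must be a stage_model named '", s, "'")
  }
  if (!inherits(adult_longevity, "stinner_params") &&
      !inherits(adult_longevity, "hilbert_logan_params"))
    stop("adult_longevity must be stinner_params or hilbert_logan_params")
  stopifnot(inherits(fecundity, "fecundity_params"))
  sex_ratio <- check_num(sex_ratio, "sex_ratio")
  if (sex_ratio < 0 || sex_ratio > 1) stop("sex_ratio must be in [0, 1]")
  structure(list(species_name = species_name, stages = stages,
                 adult_longevity = adult_longevity, fecundity = fecundity,
                 sex_ratio = sex_ratio), class = "species_model")
}

#' @export
print.species_model <- function(x, ...) {
  fam <- if (inherits(x$adult_longevity, "stinner_params"))
    "Stinner logistic" else "Hilbert-Logan senescence"
  cat("<species_model> ", x$species_name, "\n",
      "  stages: egg, larva, pupa (Logan rate + exp-polynomial mortality)\n",
      "  adult longevity: ", fam, "\n",
      "  sex ratio (female): ", x$sex_ratio, "\n", sep = "")
  invisible(x)
}

## Species parameter files -----------------------------------------------------

#' Read or write a species parameter file
#'
#' Species models are stored as one YAML document per species listing every
#' parameter record.  `read_species()` validates the file through the type
#' constructors and rejects documents with missing stages or malformed
#' parameter blocks.
#'
#' @param path File path.
#' @param sp A [species_model()] object (for writing).
#' @return `read_species()` returns a [species_model()];
#'   `write_species()` returns `path` invisibly.
#' @export
read_species <- function(path) {
  doc <- yaml::read_yaml(path)
  need <- c("species_name", "stages", "adult_longevity", "fecundity")
  miss <- setdiff(need, names(doc))
  if (length(miss))
    stop("species file missing field(s): ", paste(miss, collapse = ", "))
  mk_stage <- function(s) {
    st <- doc$stages[[s]]
    if (is.null(st)) stop("species file missing stage '", s, "'")
    stage_model(s,
      dev_rate = do.call(logan_params, st$dev_rate),
      mortality = do.call(mortality_params, st$mortality),
      dev_var = do.call(dev_var_params, st$dev_var))
  }
  al <- doc$adult_longevity
  longevity <- switch(al$family,
    stinner = do.call(stinner_params, al$params),
    hilbert_logan = do.call(hilbert_logan_params, al$params),
    stop("unknown adult_longevity family: ", al$family))
  species_model(doc$species_name,
                egg = mk_stage("egg"), larva = mk_stage("larva"),
                pupa = mk_stage("pupa"),
                adult_longevity = longevity,
                fecundity = do.call(fecundity_params, doc$fecundity),
                sex_ratio = if (is.null(doc$sex_ratio)) 0.5 else doc$sex_ratio)
}

#' @rdname read_species
#' @export
write_species <- function(sp, path) {
  stopifnot(inherits(sp, "species_model"))
  strip <- function(p) lapply(unclass(p), identity)
  doc <- list(
    species_name = sp$species_name,
    stages = lapply(sp$stages, function(st)
      list(dev_rate = strip(st$dev_rate), mortality = strip(st$mortality),
           dev_var = strip(st$dev_var))),
    adult_longevity = list(
      family = if (inherits(sp$adult_longevity, "stinner_params"))
        "stinner" else "hilbert_logan",
      params = strip(sp$adult_longevity)),
    fecundity = strip(sp$fecundity),
    sex_ratio = sp$sex_ratio)
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}
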