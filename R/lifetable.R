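## Stochastic individual-based cohort simulation under fluctuating
## temperature, and the classical life-table parameters extracted from it.

#' Cohort simulation configuration
#'
#' @param n_individuals Cohort size (>= 2).  The cohort is a cohort of
#'   female eggs; the species' `sex_ratio` converts lifetime eggs to female
#'   eggs, so the lx/mx schedule is the standard female-on-female table.
#' @param seed Integer RNG seed (mandatory: same seed + same inputs gives a
#'   bit-identical result).
#' @param start_day Day of year on which the cohort's eggs are laid; the
#'   weather series wraps cyclically past day 365.
#' @param driver `"hourly"` (24 cosine-interpolated steps per day, the
#'   default) or `"daily_mean"` (one step per day at (tmin+tmax)/2).
#' @param max_days Simulation horizon in days; individuals still immature
#'   at the horizon are scored as deaths.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_individuals = 2000, seed, start_day = 1,
                          driver = c("hourly", "daily_mean"),
                          max_days = 1095) {
  driver <- match.arg(driver)
  if (missing(seed)) stop("an explicit integer 'seed' is required")
  n_individuals <- as.integer(n_individuals)
  if (n_individuals < 2) stop("n_individuals must be >= 2")
  if (start_day < 1 || start_day > 365) stop("start_day must be in 1..365")
  structure(list(n_individuals = n_individuals, seed = as.integer(seed),
                 start_day = as.integer(start_day), driver = driver,
                 max_days = as.integer(max_days)),
            class = "cohort_config")
}

## Step temperatures from start_day, wrapping the 365-day year.
step_temperatures <- function(w, cfg) {
  days <- ((cfg$start_day - 1 + seq_len(cfg$max_days) - 1) %% 365) + 1
  tmin <- w$records$tmin[days]; tmax <- w$records$tmax[days]
  if (cfg$driver == "daily_mean") {
    list(temps = daily_mean(tmin, tmax), dt = 1,
         dmeans = daily_mean(tmin, tmax))
  } else {
    h <- 0:23
    cosw <- cos(2 * pi * (h - 14) / 24)
    temps <- as.vector(vapply(seq_along(days), function(i)
      (tmax[i] + tmin[i]) / 2 + (tmax[i] - tmin[i]) / 2 * cosw,
      numeric(24)))
    list(temps = temps, dt = 1 / 24, dmeans = daily_mean(tmin, tmax))
  }
}

#' Simulate a cohort and tabulate its life table
#'
#' Individual-based stochastic simulation.  Each individual draws one
#' development-time multiplier per immature stage; development accumulates
#' by rate summation (sum of rate(T) * dt / multiplier) until it reaches 1.
#' Whole-stage mortality evaluated at the running mean stage temperature is
#' converted to per-step survival `(1 - m)^ddev` (ddev = fraction of the
#' stage completed that step), so cumulative stage survival at constant
#' temperature is exactly `1 - m`.  Surviving females live out the adult
#' longevity model (Stinner longevity, re-evaluated at the running mean
#' adult temperature, or Hilbert-Logan senescence-rate summation) and lay
#' `total_fecundity(mean adult temperature) * sex_ratio` female eggs spread
#' over adult life by the gamma oviposition profile.
#'
#' From the daily lx/mx schedule the five demographic parameters are
#' extracted: R0 = sum lx mx, T = sum x lx mx / R0, rm solving the
#' Euler-Lotka renewal equation, lambda = exp(rm), DT = ln 2 / rm.
#' An extinct cohort (no reproduction) is flagged, not an error.
#'
#' @param sp A [species_model()].
#' @param w A [weather_series()].
#' @param cfg A [cohort_config()].
#' @return An object of class `lifetable_result`: a list with elements
#'   `generation_time`, `net_reproduction`, `intrinsic_rate`,
#'   `finite_rate`, `doubling_time`, `stage_dev_time`, `stage_survival`,
#'   `lx_mx` (data.frame age/lx/mx), `dev_durations` (per-individual stage
#'   durations in days, `NA` where the stage was not completed),
#'   `extinct`.
#' @export
simulate_cohort <- function(sp, w, cfg) {
  stopifnot(inherits(sp, "species_model"), inherits(w, "weather_series"),
            inherits(cfg, "cohort_config"))
  st <- step_temperatures(w, cfg)
  temps <- st$temps; dt <- st$dt
  S <- length(temps)
  n <- cfg$n_individuals

  ## per-stage step rates and global cumulative sums (shared by individuals)
  cumR <- lapply(sp$stages, function(stg)
    c(0, cumsum(development_rate(temps, stg$dev_rate) * dt)))
  rates <- lapply(sp$stages, function(stg)
    development_rate(temps, stg$dev_rate))
  cumT <- c(0, cumsum(temps))

  ## all randomness drawn up-front in fixed order (seeded contract)
  draws <- withr::with_seed(cfg$seed, {
    list(mult = vapply(sp$stages, function(stg)
           sample_dev_multiplier(stats::runif(n), stg$dev_var), numeric(n)),
         usurv = matrix(stats::runif(n * 3), n, 3))
  })
  mult <- draws$mult; usurv <- draws$usurv

  death_day <- integer(n)       # 1-based day containing death; 0 = survived
  adult_start_step <- integer(n)
  dur_steps <- matrix(NA_real_, n, 3)
  entered <- c(n, 0L, 0L); survived <- c(0L, 0L, 0L)

  for (i in seq_len(n)) {
    s0 <- 1L
    dead <- FALSE
    for (j in 1:3) {
      target <- mult[i, j]
      base <- cumR[[j]][s0]
      s1 <- findInterval(base + target, cumR[[j]], left.open = TRUE) + 1L
      ## s1 is now the index (in cumR, 1-based incl. leading 0) of the first
      ## step whose cumulative rate reaches the target; convert to step index
      s1 <- s1 - 1L
      if (s1 > S) { death_day[i] <- cfg$max_days; dead <- TRUE; break }
      wnd <- s0:s1
      ddev <- rates[[j]][wnd] * dt / target
      trun <- (cumT[wnd + 1L] - cumT[s0]) / seq_along(wnd)
      m <- stage_mortality(trun, sp$stages[[j]]$mortality)
      logS <- cumsum(ddev * log1p(-pmin(m, 1 - 1e-15)) -
                       ifelse(m >= 1, Inf, 0))
      u <- usurv[i, j]
      endS <- logS[length(logS)]
      if (log(u) > endS) {
        k <- which(logS < log(u))[1]
        death_day[i] <- ceiling(wnd[k] * dt)
        dead <- TRUE
      } else {
        dur_steps[i, j] <- length(wnd)
        survived[j] <- survived[j] + 1L
        if (j < 3) entered[j + 1] <- entered[j + 1] + 1L
        s0 <- s1 + 1L
        if (s0 > S) { death_day[i] <- cfg$max_days; dead <- TRUE }
      }
      if (dead) break
    }
    if (!dead) adult_start_step[i] <- s0
  }

  ## adults: deterministic lifespan given temperatures, daily resolution
  dmeans <- st$dmeans
  nd <- length(dmeans)
  ages <- 0:(cfg$max_days - 1)
  E <- numeric(cfg$max_days)            # female eggs laid at each age
  adults <- which(adult_start_step > 0L)
  for (i in adults) {
    d0 <- as.integer(ceiling(adult_start_step[i] * dt - 1e-9))
    d0 <- max(1L, min(d0, nd))
    K <- nd - d0 + 1L
    dw <- dmeans[d0:nd]
    tbar_run <- cumsum(dw) / seq_len(K)
    if (inherits(sp$adult_longevity, "stinner_params")) {
      Lk <- adult_longevity(tbar_run, sp$adult_longevity)
      L <- which(seq_len(K) >= Lk)[1]
    } else {
      sen <- cumsum(senescence_rate(dw, sp$adult_longevity))
      L <- which(sen >= 1)[1]
    }
    if (is.na(L)) L <- K                   # horizon cap
    tbar <- tbar_run[L]
    Fi <- total_fecundity(tbar, sp$fecundity) * sp$sex_ratio
    if (Fi > 0 && L >= 1) {
      frac <- oviposition_fraction(seq(0, 1, length.out = L + 1)[-(L + 1)],
                                   seq(0, 1, length.out = L + 1)[-1],
                                   sp$fecundity)
      adays <- d0 + seq_len(L) - 1L          # calendar days of adult life
      E[adays] <- E[adays] + Fi * frac       # age = day - 1
    }
    death_day[i] <- d0 + L - 1L
  }

  ## daily lx / mx schedule (age x = day - 1); alive at start of day d
  ## iff death_day >= d
  Nx <- vapply(seq_len(cfg$max_days), function(d) sum(death_day >= d),
               integer(1))
  last <- max(c(which(Nx > 0), which(E > 0), 1L))
  Nx <- Nx[seq_len(last)]; E <- E[seq_len(last)]; ages <- ages[seq_len(last)]
  lx <- Nx / n
  mx <- ifelse(Nx > 0, E / Nx, 0)
  lxmx <- lx * mx
  R0 <- sum(lxmx)
  extinct <- !(R0 > 0)
  rm <- if (extinct) NA_real_ else solve_euler_lotka(ages, lxmx)
  Tg <- if (extinct) NA_real_ else sum(ages * lxmx) / R0
  res <- list(
    generation_time = Tg,
    net_reproduction = R0,
    intrinsic_rate = rm,
    finite_rate = if (is.na(rm)) NA_real_ else exp(rm),
    doubling_time = if (is.na(rm) || rm <= 0) NA_real_ else log(2) / rm,
    stage_dev_time = stats::setNames(colMeans(dur_steps * dt, na.rm = TRUE),
                                     STAGE_NAMES),
    stage_survival = stats::setNames(ifelse(entered > 0, survived / entered,
                                            NA_real_), STAGE_NAMES),
    lx_mx = data.frame(age = ages, lx = lx, mx = mx),
    dev_durations = stats::setNames(as.data.frame(dur_steps * dt),
                                    STAGE_NAMES),
    extinct = extinct,
    config = cfg)
  class(res) <- "lifetable_result"
  res
}

#' @export
print.lifetable_result <- function(x, ...) {
  cat("<lifetable_result>", if (x$extinct) " (extinct cohort)", "\n", sep = "")
  cat(sprintf("  R0 = %.4g  T = %.4g d  rm = %.5g /d  lambda = %.5g  DT = %.4g d\n",
              x$net_reproduction, x$generation_time, x$intrinsic_rate,
              x$finite_rate, x$doubling_time))
  invisible(x)
}

#' Solve the Euler-Lotka renewal equation
#'
#' Finds the intrinsic rate of increase r with
#' `sum(exp(-r * age) * lxmx) = 1` by safeguarded Newton iteration (Newton
#' steps with a maintained bisection bracket, initial bracket \[-1, 1\],
#' expanded if needed), converged to |renewal - 1| < 1e-10.
#'
#' @param age Ages in days (non-negative, increasing).
#' @param lxmx Schedule of lx * mx values at those ages.
#' @return The intrinsic rate of increase rm (1/day), or `NA` with a
#'   warning if the schedule has no reproduction (R0 <= 0).
#' @export
solve_euler_lotka <- function(age, lxmx) {
  keep <- lxmx > 0
  if (!any(keep)) { warning("R0 <= 0: no Euler-Lotka solution"); return(NA_real_) }
  age <- age[keep]; lxmx <- lxmx[keep]
  f <- function(r) sum(exp(-r * age) * lxmx) - 1
  lo <- -1; hi <- 1
  while (f(lo) < 0) lo <- lo * 2     # f decreasing in r
  while (f(hi) > 0) hi <- hi * 2
  r <- log(sum(lxmx)) / max(sum(age * lxmx) / sum(lxmx), 1e-9)  # start guess
  if (r < lo || r > hi) r <- (lo + hi) / 2
  for (it in 1:200) {
    fr <- f(r)
    if (abs(fr) < 1e-12) break
    if (fr > 0) lo <- r else hi <- r
    fp <- -sum(age * exp(-r * age) * lxmx)
    rn <- if (fp != 0) r - fr / fp else NA_real_
    r <- if (!is.na(rn) && rn > lo && rn < hi) rn else (lo + hi) / 2
  }
  r
}

#' Life table at constant temperature
#'
#' Runs [simulate_cohort()] on a synthetic constant series with
#' tmin = tmax = t (any driver then yields the same temperatures).
#'
#' @param sp A [species_model()].
#' @param t Constant temperature, degree C.
#' @param cfg A [cohort_config()].
#' @return A `lifetable_result`.
#' @export
lifetable_at_constant <- function(sp, t, cfg) {
  t <- check_num(t, "t")
  w <- weather_series("constant", 0, 0, 0, rep(t, 365), rep(t, 365))
  simulate_cohort(sp, w, cfg)
}

#' Intrinsic-rate profile over a temperature grid
#'
#' Evaluates rm by [lifetable_at_constant()] at each grid node and returns a
#' piecewise-linear map from temperature to rm.  Nodes where the cohort is
#' extinct (or rm is below the floor) take the sentinel floor value.
#'
#' @param sp A [species_model()].
#' @param t_grid Strictly increasing temperature grid covering the weather
#'   range of interest.
#' @param cfg A [cohort_config()]; each node is seeded as
#'   `cfg$seed + node index` so the profile is deterministic.
#' @param rm_floor Sentinel rm for extinct nodes (1/day, default -0.5).
#' @return An object of class `rm_profile` (query it with [rm_lookup()]).
#' @export
rm_profile <- function(sp, t_grid, cfg, rm_floor = -0.5) {
  if (any(diff(t_grid) <= 0)) stop("t_grid must be strictly increasing")
  rmv <- vapply(seq_along(t_grid), function(k) {
    cfgk <- cfg; cfgk$seed <- cfg$seed + k
    res <- lifetable_at_constant(sp, t_grid[k], cfgk)
    if (res$extinct || !is.finite(res$intrinsic_rate)) rm_floor
    else max(rm_floor, res$intrinsic_rate)
  }, numeric(1))
  structure(list(t = as.numeric(t_grid), rm = rmv, rm_floor = rm_floor),
            class = "rm_profile")
}

#' Query an intrinsic-rate profile
#'
#' Linear interpolation between grid nodes; queries outside the grid hull
#' are clamped to the nearest node with a warning.
#'
#' @param profile An [rm_profile()] object.
#' @param t Temperature(s), degree C.
#' @return rm value(s), 1/day.
#' @export
rm_lookup <- function(profile, t) {
  stopifnot(inherits(profile, "rm_profile"))
  t <- check_temp(t)
  if (any(t < min(profile$t) | t > max(profile$t)))
    warning("query outside rm_profile grid; clamped to hull")
  stats::approx(profile$t, profile$rm, xout = pmin(pmax(t, min(profile$t)),
                                                   max(profile$t)))$y
}

#' @export
print.rm_profile <- function(x, ...) {
  cat("<rm_profile> ", length(x$t), " nodes over [",
      min(x$t), ", ", max(x$t), "] degC; peak rm ",
      sprintf("%.4g", max(x$rm)), " /day at ",
      x$t[which.max(x$rm)], " degC\n", sep = "")
  invisible(x)
}
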