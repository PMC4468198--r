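## Annual risk indices: establishment (ERI), generation (GI) and activity
## (AI) indices, daily finite-rate series, and host-parasitoid synchrony.

#' Establishment risk index
#'
#' ERI is the annual mean, over the 365 days, of the product across the
#' three immature stages of daily stage survival evaluated at the daily
#' mean temperature:
#' `ERI = (1/365) * sum_d prod_j (1 - m_j(daily mean(d)))`.
#' It lies in \[0, 1\]; high values mean the immature stages can survive the
#' local temperature regime year-round.
#'
#' @param sp A [species_model()].
#' @param w A [weather_series()].
#' @return ERI in \[0, 1\].
#' @export
establishment_index <- function(sp, w) {
  stopifnot(inherits(sp, "species_model"), inherits(w, "weather_series"))
  tm <- daily_means(w)
  surv <- rep(1, 365)
  for (stg in sp$stages)
    surv <- surv * (1 - stage_mortality(tm, stg$mortality))
  mean(surv)
}

#' Generation index
#'
#' Mean number of generations per year, estimated by launching one cohort
#' on the first day of each of the 12 months (weather wrapping cyclically)
#' and taking `GI = 365 / mean(generation time)` over the non-extinct
#' launches.  Returns 0 if every launch goes extinct.  Launch k is seeded
#' as `cfg$seed + k`, so the index is deterministic given the seed.
#'
#' @param sp A [species_model()].
#' @param w A [weather_series()].
#' @param cfg A [cohort_config()]; its `start_day` is ignored (replaced by
#'   each month's first day).
#' @return Generations per year (>= 0).
#' @export
generation_index <- function(sp, w, cfg) {
  gts <- vapply(1:12, function(k) {
    cfgk <- cfg
    cfgk$start_day <- MONTH_FIRST_DAY[k]
    cfgk$seed <- cfg$seed + k
    res <- simulate_cohort(sp, w, cfgk)
    if (res$extinct) NA_real_ else res$generation_time
  }, numeric(1))
  if (all(is.na(gts))) return(0)
  365 / mean(gts, na.rm = TRUE)
}

#' Activity index
#'
#' AI is the base-10 logarithm of the factor by which the population would
#' multiply over one year:
#' `AI = (1/ln 10) * sum_d max(rm_floor, rm(daily mean(d)))`,
#' with rm looked up in a precomputed temperature profile.  The floor stops
#' a few lethal days from sending the annual sum to -Inf.
#'
#' @param sp A [species_model()] (metadata only; the thermal response is in
#'   `rm_map`).
#' @param w A [weather_series()].
#' @param rm_map An [rm_profile()] for the same species covering the
#'   weather's daily-mean range.
#' @param rm_floor Daily floor on rm (1/day, default -0.1).
#' @return AI (decimal orders of annual increase; may be negative).
#' @export
activity_index <- function(sp, w, rm_map, rm_floor = -0.1) {
  sum(pmax(rm_floor, rm_lookup(rm_map, daily_means(w)))) / log(10)
}

#' Daily finite-rate-of-increase series
#'
#' `lambda_day = exp(max(rm_floor, rm(daily mean(d))))` for each calendar
#' day; `sum(log10(lambda_day))` equals [activity_index()] by construction.
#'
#' @inheritParams activity_index
#' @return A data.frame with columns `day` (1..365) and `lambda`.
#' @export
finite_rate_series <- function(sp, w, rm_map, rm_floor = -0.1) {
  lam <- exp(pmax(rm_floor, rm_lookup(rm_map, daily_means(w))))
  data.frame(day = 1:365, lambda = lam)
}

#' Risk-index set at one station
#'
#' Convenience wrapper computing ERI, GI and AI at a station.
#'
#' @inheritParams generation_index
#' @param rm_map An [rm_profile()] for the species.
#' @param rm_floor Floor used by the activity index.
#' @return A one-row data.frame: station_id, lon, lat, alt, eri, gi, ai.
#' @export
risk_indices <- function(sp, w, cfg, rm_map, rm_floor = -0.1) {
  data.frame(station_id = w$station_id, lon = w$lon, lat = w$lat,
             alt = w$alt,
             eri = establishment_index(sp, w),
             gi = generation_index(sp, w, cfg),
             ai = activity_index(sp, w, rm_map, rm_floor))
}

#' Host-parasitoid synchrony
#'
#' Elementwise signed difference `host - parasitoid` of an index (in the
#' source analysis, the establishment index).  Negative values mean the
#' parasitoid's establishment exceeds the host's.  Accepts numeric
#' vectors/matrices of matching shape or two [ascii_grid()]s of identical
#' geometry.
#'
#' @param host,parasitoid Matching numeric objects or grids.
#' @return Same shape as the inputs.
#' @export
synchrony <- function(host, parasitoid) {
  if (inherits(host, "ascii_grid") || inherits(parasitoid, "ascii_grid")) {
    stopifnot(inherits(host, "ascii_grid"), inherits(parasitoid, "ascii_grid"))
    return(grid_difference(host, parasitoid))
  }
  if (!identical(dim(host), dim(parasitoid)) ||
      length(host) != length(parasitoid))
    stop("host and parasitoid indices must have matching shape")
  host - parasitoid
}
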