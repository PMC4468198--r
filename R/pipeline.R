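## End-to-end demo pipeline: synthetic transect -> cohort simulation ->
## risk indices -> spline mapping -> scenario differencing -> yield loss.

#' Run the full demo-transect analysis
#'
#' Executes the whole pipeline on the synthetic demo transect:
#' generates the transect (6 stations, one-sided mountain DEM), the four
#' species profiles and the warming scenario; builds an rm-temperature
#' profile per species; computes station-level ERI and AI under current
#' and warmed climates (plus GI for every species at the lowest station);
#' interpolates ERI and AI over the DEM by exact thin-plate splines with
#' elevation as covariate; differences the AI grids between scenarios and
#' profiles the change against altitude; and, for each host species,
#' averages AI per agro-climatic zone, fabricates observed losses from a
#' known ground-truth relation, refits the loss regression and tabulates
#' current/future/change losses per zone.
#'
#' @param seed Integer seed driving every stochastic component.
#' @param n_individuals Cohort size used throughout (kept moderate so the
#'   full pipeline runs in a few minutes on one CPU).
#' @param driver Temperature driver for the cohort simulations.
#' @param warming_c,seasonal_skew Scenario parameters (degC).
#' @param true_beta0,true_beta1,loss_noise_sd Ground truth for the
#'   fabricated observed losses.
#' @param with_gi Also compute the generation index at the lowest station
#'   for every species (adds 12 cohort launches per species).
#' @return A list: `transect`, `species`, `scenario`, `rm_maps`,
#'   `station_indices` (data.frame), `gi_lowest` (named vector or NULL),
#'   `grids` (per species: eri_current, ai_current, ai_future, ai_change),
#'   `alt_profiles`, `yield` (per host: zone AI tables, observed losses,
#'   fit, change table, true coefficients).
#' @export
run_demo_transect <- function(seed = 1, n_individuals = 250,
                              driver = "daily_mean", warming_c = 1.45,
                              seasonal_skew = 0.45, true_beta0 = -2,
                              true_beta1 = 3, loss_noise_sd = 1,
                              with_gi = TRUE) {
  tr <- make_transect(transect_spec(seed = seed))
  scen <- make_scenario(warming_c, seasonal_skew, seed)
  stations_fut <- lapply(tr$stations, apply_scenario, s = scen)
  species <- lapply(stats::setNames(SPECIES_PROFILES, SPECIES_PROFILES),
                    make_species, seed = seed)
  cfg <- cohort_config(n_individuals = n_individuals, seed = seed,
                       driver = driver)

  ## rm profile per species over a grid covering both climates
  all_t <- unlist(lapply(c(tr$stations, stations_fut), daily_means))
  t_grid <- seq(floor(min(all_t)) - 1, ceiling(max(all_t)) + 1, by = 2)
  rm_maps <- lapply(species, rm_profile, t_grid = t_grid, cfg = cfg)

  ## station-level indices under both climates
  rows <- list()
  for (spn in names(species)) {
    for (scn in c("current", "future")) {
      sts <- if (scn == "current") tr$stations else stations_fut
      for (w in sts) {
        rows[[length(rows) + 1]] <- data.frame(
          species = spn, scenario = scn, station_id = w$station_id,
          alt = w$alt,
          eri = establishment_index(species[[spn]], w),
          ai = activity_index(species[[spn]], w, rm_maps[[spn]]))
      }
    }
  }
  station_indices <- do.call(rbind, rows)

  gi_lowest <- NULL
  if (with_gi) {
    w_low <- tr$stations[[1]]
    gi_lowest <- vapply(species, generation_index, numeric(1),
                        w = w_low, cfg = cfg)
  }

  ## spline mapping over the DEM
  grids <- list(); alt_profiles <- list()
  for (spn in names(species)) {
    idx <- function(scn, col) {
      d <- station_indices[station_indices$species == spn &
                             station_indices$scenario == scn, ]
      d <- d[match(tr$coords$station_id, d$station_id), ]
      d[[col]]
    }
    fit_grid <- function(vals) {
      m <- fit_tps(tr$coords$x, tr$coords$y, tr$coords$alt, vals)
      predict_grid(m, tr$dem)
    }
    g <- list(eri_current = fit_grid(idx("current", "eri")),
              ai_current = fit_grid(idx("current", "ai")),
              ai_future = fit_grid(idx("future", "ai")))
    g$ai_change <- grid_difference(g$ai_future, g$ai_current)
    grids[[spn]] <- g
    alt_profiles[[spn]] <- altitude_profile(g$ai_change, tr$dem, n_bins = 10)
  }

  ## yield loss per host species
  zones <- default_zones()
  yield <- list()
  hosts <- c("lowland_host", "highland_host")
  for (k in seq_along(hosts)) {
    spn <- hosts[k]
    zcur <- zone_mean_index(grids[[spn]]$ai_current, tr$dem, zones)
    zfut <- zone_mean_index(grids[[spn]]$ai_future, tr$dem, zones)
    observed <- make_observed_losses(true_beta0, true_beta1, zcur$mean_ai,
                                     loss_noise_sd, seed + 100 * k)
    fit <- fit_loss_model(observed, zcur$mean_ai)
    cur <- data.frame(zone = zones$zone,
                      loss = predict_losses(fit, zcur$mean_ai))
    fut <- data.frame(zone = zones$zone,
                      loss = predict_losses(fit, zfut$mean_ai))
    yield[[spn]] <- list(zone_ai_current = zcur, zone_ai_future = zfut,
                         observed = observed, fit = fit,
                         change_table = loss_change_table(cur, fut),
                         true_beta0 = true_beta0, true_beta1 = true_beta1)
  }

  list(transect = tr, species = species, scenario = scen,
       rm_maps = rm_maps, station_indices = station_indices,
       gi_lowest = gi_lowest, grids = grids, alt_profiles = alt_profiles,
       yield = yield)
}
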