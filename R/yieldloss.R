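## Linking the activity index to maize yield loss per agro-climatic
## altitude zone: zone means, OLS fit Y = beta0 + beta1 * A, projections
## and current/future change tables.

#' Default agro-climatic altitude zones
#'
#' The four maize agro-climatic zones by altitude: lowland tropical
#' (< 1000 m), dry mid altitude (1000-1300 m), moist transitional
#' (1300-1600 m) and highland tropics (> 1600 m).  Bands are
#' lower-inclusive, upper-exclusive; the top zone is unbounded above.
#'
#' @return data.frame with columns `zone`, `alt_lo`, `alt_hi` (ordered
#'   bottom to top).
#' @export
default_zones <- function() {
  data.frame(zone = c("lowland tropical", "dry mid altitude",
                      "moist transitional", "highland tropics"),
             alt_lo = c(-Inf, 1000, 1300, 1600),
             alt_hi = c(1000, 1300, 1600, Inf))
}

check_zones <- function(zones) {
  need <- c("zone", "alt_lo", "alt_hi")
  if (!is.data.frame(zones) || length(setdiff(need, names(zones))))
    stop("zones must be a data.frame with columns zone, alt_lo, alt_hi")
  if (any(zones$alt_lo >= zones$alt_hi)) stop("zone bands must have alt_lo < alt_hi")
  if (is.unsorted(zones$alt_lo) || any(zones$alt_hi[-nrow(zones)] >
                                       zones$alt_lo[-1]))
    stop("zone bands must be ordered and non-overlapping")
  zones
}

#' Mean activity index per agro-climatic zone
#'
#' Averages an index grid over the valid cells whose DEM elevation falls in
#' each zone's `[alt_lo, alt_hi)` band.  Zones with no cells get `NA`.
#'
#' @param ai An [ascii_grid()] of activity-index values.
#' @param dem An [ascii_grid()] of elevations, same geometry.
#' @param zones Zone table as from [default_zones()].
#' @return data.frame `zone`, `mean_ai`, `n_cells`.
#' @export
zone_mean_index <- function(ai, dem, zones = default_zones()) {
  stopifnot(inherits(ai, "ascii_grid"), inherits(dem, "ascii_grid"))
  if (!same_geometry(ai, dem)) stop("grid geometry mismatch")
  zones <- check_zones(zones)
  ok <- !is.na(ai$values) & !is.na(dem$values)
  if (!any(ok)) stop("no valid cells in the index/DEM overlay")
  e <- dem$values[ok]; v <- ai$values[ok]
  means <- vapply(seq_len(nrow(zones)), function(z) {
    inz <- e >= zones$alt_lo[z] & e < zones$alt_hi[z]
    if (any(inz)) mean(v[inz]) else NA_real_
  }, numeric(1))
  ncell <- vapply(seq_len(nrow(zones)), function(z)
    sum(e >= zones$alt_lo[z] & e < zones$alt_hi[z]), integer(1))
  data.frame(zone = zones$zone, mean_ai = means, n_cells = ncell)
}

#' Fit the linear yield-loss model Y = beta0 + beta1 * A
#'
#' Ordinary least squares of observed percent yield loss on the zone-mean
#' activity index, with the usual inference statistics.  With the default
#' four zones the fit has only 2 residual degrees of freedom, so a low-n
#' message is always emitted.
#'
#' @param observed Observed percent losses, one per zone (>= 3 values).
#' @param ai Matching activity-index values with positive variance.
#' @return An object of class `yield_loss_fit`: beta0, beta1, se_beta0,
#'   se_beta1, df (= n - 2), f_stat, t_stat (slope), p_value (two-sided,
#'   slope), r2, fitted, and the underlying `lm` object.
#' @export
fit_loss_model <- function(observed, ai) {
  if (length(observed) != length(ai) || length(observed) < 3)
    stop("need >= 3 paired (observed, ai) points")
  if (stats::var(ai) <= 0) stop("degenerate fit: zero variance in ai")
  message("yield-loss fit on n = ", length(observed),
          " zones: interpret inference statistics with caution")
  fit <- stats::lm(observed ~ ai)
  sm <- summary(fit)
  co <- sm$coefficients
  structure(list(beta0 = co[1, 1], beta1 = co[2, 1],
                 se_beta0 = co[1, 2], se_beta1 = co[2, 2],
                 df = fit$df.residual,
                 f_stat = unname(sm$fstatistic[1]),
                 t_stat = co[2, 3], p_value = co[2, 4],
                 r2 = sm$r.squared, fitted = unname(stats::fitted(fit)),
                 lm = fit), class = "yield_loss_fit")
}

#' @export
print.yield_loss_fit <- function(x, ...) {
  cat(sprintf("<yield_loss_fit> loss%% = %.3f + %.3f * AI  (se %.3f, %.3f)\n",
              x$beta0, x$beta1, x$se_beta0, x$se_beta1))
  cat(sprintf("  df = %d  F = %.3f  t = %.3f  p = %.3g  R2 = %.3f\n",
              x$df, x$f_stat, x$t_stat, x$p_value, x$r2))
  invisible(x)
}

#' Predict percent losses from activity indices
#'
#' `beta0 + beta1 * ai`; predictions are not clamped, and negative values
#' are reported as-is (with a message flagging them).
#'
#' @param fit A [fit_loss_model()] object.
#' @param ai Activity-index values.
#' @return Predicted percent losses.
#' @export
predict_losses <- function(fit, ai) {
  stopifnot(inherits(fit, "yield_loss_fit"))
  out <- fit$beta0 + fit$beta1 * ai
  if (any(out < 0, na.rm = TRUE))
    message("some predicted losses are negative; reported unclamped")
  out
}

#' Coefficient of determination
#'
#' Squared Pearson correlation between observed and predicted values; for
#' an OLS fit evaluated at its own fitted values this equals the
#' regression R^2.
#'
#' @param observed,predicted Numeric vectors of equal length >= 3 with
#'   positive variance.
#' @return R^2 in \[0, 1\].
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 3)
    stop("need equal lengths >= 3")
  if (stats::var(observed) <= 0 || stats::var(predicted) <= 0)
    stop("zero variance")
  stats::cor(observed, predicted)^2
}

#' Current/future loss-change table
#'
#' Joins per-zone current and future predicted losses, computes the
#' `future - current` difference, and appends an `Average` row holding the
#' unweighted column means across zones.
#'
#' @param current,future data.frames with columns `zone` and `loss`
#'   (percent), same zones in the same order.
#' @return data.frame `zone`, `loss_current`, `loss_future`,
#'   `loss_change`, with a final `Average` row.
#' @export
loss_change_table <- function(current, future) {
  need <- c("zone", "loss")
  if (length(setdiff(need, names(current))) ||
      length(setdiff(need, names(future))))
    stop("current and future need columns zone, loss")
  if (!identical(as.character(current$zone), as.character(future$zone)))
    stop("zone mismatch between current and future tables")
  out <- data.frame(zone = as.character(current$zone),
                    loss_current = current$loss,
                    loss_future = future$loss,
                    loss_change = future$loss - current$loss)
  rbind(out, data.frame(zone = "Average",
                        loss_current = mean(out$loss_current),
                        loss_future = mean(out$loss_future),
                        loss_change = mean(out$loss_change)))
}

#' Published reference yield-loss tables for the two East African transects
#'
#' Per-zone observed maize losses, current/future predicted losses
#' (Mount Kilimanjaro and Taita Hills transects; Chilo partellus and
#' Busseola fusca), and the reference regression coefficients relating
#' activity index to percent loss.  These published values ship with the
#' package as plain-text CSVs and serve as desk-check anchors for the
#' regression machinery.
#'
#' @return A list with elements `losses` (data.frame: transect, species,
#'   zone, observed_pct, current_pct, future_pct) and `coefficients`
#'   (data.frame: transect, species, beta0, beta1, se_beta0, se_beta1, df,
#'   f_stat, t_stat, p_value, r2).
#' @export
reference_loss_tables <- function() {
  dir <- system.file("extdata", "reference", package = "phenorisk")
  list(losses = utils::read.csv(file.path(dir, "transect_loss_tables.csv"),
                                stringsAsFactors = FALSE),
       coefficients = utils::read.csv(
         file.path(dir, "loss_regression_coefficients.csv"),
         stringsAsFactors = FALSE))
}
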