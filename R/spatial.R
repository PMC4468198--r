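## ESRI ASCII grids, exact thin-plate-spline interpolation with an
## elevation covariate, raster differencing and altitude profiling.

#' ESRI ASCII grid
#'
#' A row-major raster whose first matrix row is the northernmost.  Values
#' equal to `nodata` are held as `NA` internally and written back as the
#' sentinel.
#'
#' @param values Numeric matrix (`nrows x ncols`), `NA` = nodata.
#' @param xllcorner,yllcorner Lower-left corner, map units.
#' @param cellsize Cell size, map units (> 0).
#' @param nodata Sentinel written to file for `NA` cells.
#' @return An object of class `ascii_grid`.
#' @export
ascii_grid <- function(values, xllcorner, yllcorner, cellsize,
                       nodata = -9999) {
  if (!is.matrix(values) || nrow(values) < 1 || ncol(values) < 1)
    stop("values must be a non-empty matrix")
  cellsize <- check_num(cellsize, "cellsize")
  if (cellsize <= 0) stop("cellsize must be > 0")
  structure(list(values = values,
                 xllcorner = check_num(xllcorner, "xllcorner"),
                 yllcorner = check_num(yllcorner, "yllcorner"),
                 cellsize = cellsize, nodata = check_num(nodata, "nodata")),
            class = "ascii_grid")
}

#' @export
print.ascii_grid <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<ascii_grid> %d x %d cells of %g, llcorner (%g, %g)\n",
              nrow(x$values), ncol(x$values), x$cellsize,
              x$xllcorner, x$yllcorner))
  if (length(v))
    cat(sprintf("  values %.6g .. %.6g (%d nodata)\n", min(v), max(v),
                sum(is.na(x$values))))
  invisible(x)
}

same_geometry <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(c(a$xllcorner, a$yllcorner, a$cellsize),
                     c(b$xllcorner, b$yllcorner, b$cellsize)))
}

## Cell-centre coordinates (row 1 = northernmost).
grid_centres <- function(g) {
  nr <- nrow(g$values); nc <- ncol(g$values)
  x <- g$xllcorner + (seq_len(nc) - 0.5) * g$cellsize
  y <- g$yllcorner + (nr - seq_len(nr) + 0.5) * g$cellsize
  list(x = x, y = y)
}

#' Read or write an ESRI ASCII grid
#'
#' Dialect: header keywords `ncols nrows xllcorner yllcorner cellsize
#' NODATA_value` (case-insensitive on read, canonical lower-case
#' `nodata_value` spelling is accepted too), then `nrows` lines of `ncols`
#' values, north row first.  Values are written with 6 significant digits,
#' so a read -> write -> read round trip is lossless at that precision.
#'
#' @param path File path.
#' @param g An [ascii_grid()] (for writing).
#' @param digits Significant digits used on write.
#' @return `read_asc()`: an [ascii_grid()]; `write_asc()`: `path`,
#'   invisibly.
#' @export
read_asc <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (length(setdiff(need, names(hdr))))
    stop("ASCII grid header incomplete: need ", paste(need, collapse = " "))
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("ASCII grid: expected ", hdr$ncols * hdr$nrows, " values, got ",
         length(vals))
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA
  ascii_grid(m, hdr$xllcorner, hdr$yllcorner, hdr$cellsize, nodata)
}

#' @rdname read_asc
#' @export
write_asc <- function(g, path, digits = 6) {
  stopifnot(inherits(g, "ascii_grid"))
  m <- g$values
  m[is.na(m)] <- g$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", ncol(g$values)),
               paste("nrows", nrow(g$values)),
               paste("xllcorner", format(g$xllcorner, digits = 15)),
               paste("yllcorner", format(g$yllcorner, digits = 15)),
               paste("cellsize", format(g$cellsize, digits = 15)),
               paste("nodata_value", format(g$nodata, digits = 15))), con)
  writeLines(apply(m, 1, function(r)
    paste(formatC(signif(r, digits), format = "g", digits = digits),
          collapse = " ")), con)
  invisible(path)
}

## Thin-plate spline ----------------------------------------------------------

tps_kernel <- function(r) ifelse(r > 0, r^2 * log(r), 0)

#' Fit an exact thin-plate spline with an elevation covariate
#'
#' Minimum-bending-energy interpolant in (x, y) with kernel
#' U(r) = r^2 log r and an affine trend `a0 + ax x + ay y + az elev`; the
#' station elevations (and, at prediction time, the DEM) enter as a linear
#' covariate of the trend.  With `smoothing = 0` the surface passes through
#' the observations exactly; positive smoothing adds a ridge penalty on the
#' kernel weights.  Kernel weights satisfy the usual orthogonality
#' constraints (sum w = sum w x = sum w y = sum w elev = 0).
#'
#' @param x,y Station map coordinates (pairwise distinct points).
#' @param elev Station elevations, m.
#' @param value Observed index values.
#' @param smoothing Non-negative smoothing parameter (0 = exact
#'   interpolation, the default).
#' @return An object of class `tps_model`.
#' @export
fit_tps <- function(x, y, elev, value, smoothing = 0) {
  n <- length(x)
  if (length(y) != n || length(elev) != n || length(value) != n)
    stop("x, y, elev, value must have equal length")
  if (n < 4) stop("need at least 4 stations")
  if (anyDuplicated(cbind(x, y))) stop("stations must be pairwise distinct in (x, y)")
  if (smoothing < 0) stop("smoothing must be >= 0")
  ## centre and rescale internally: the raw (n+4) system is numerically
  ## singular for map-unit coordinates; the spline is fitted in scaled
  ## coordinates (kernel r^2 log r there), which keeps exact interpolation,
  ## affine reproduction and translation invariance
  ctr <- c(mean(x), mean(y), mean(elev))
  sxy <- max(max(abs(x - ctr[1])), max(abs(y - ctr[2])), 1)
  selv <- max(abs(elev - ctr[3]), 1)
  xs <- (x - ctr[1]) / sxy; ys <- (y - ctr[2]) / sxy
  es <- (elev - ctr[3]) / selv
  D <- as.matrix(stats::dist(cbind(xs, ys)))
  K <- tps_kernel(D) + diag(smoothing, n)
  P <- cbind(1, xs, ys, es)
  if (qr(P)$rank < 4)
    stop("singular system: stations are collinear/degenerate in (x, y, elev)")
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4, 4)))
  rhs <- c(value, rep(0, 4))
  sol <- tryCatch(solve(A, rhs),
                  error = function(e) stop("singular TPS system: ",
                                           conditionMessage(e)))
  sol <- unname(sol)
  structure(list(w = sol[1:n], a = sol[n + 1:4], x = xs, y = ys, elev = es,
                 centre = ctr, scale_xy = sxy, scale_elev = selv,
                 smoothing = smoothing), class = "tps_model")
}

#' Evaluate a thin-plate spline at points
#'
#' @param m A [fit_tps()] model.
#' @param x,y Map coordinates of prediction points.
#' @param elev Elevation covariate at those points, m.
#' @return Predicted values.
#' @export
predict_tps <- function(m, x, y, elev) {
  stopifnot(inherits(m, "tps_model"))
  xs <- (x - m$centre[1]) / m$scale_xy
  ys <- (y - m$centre[2]) / m$scale_xy
  es <- (elev - m$centre[3]) / m$scale_elev
  out <- m$a[1] + m$a[2] * xs + m$a[3] * ys + m$a[4] * es
  for (i in seq_along(m$w)) {
    r <- sqrt((xs - m$x[i])^2 + (ys - m$y[i])^2)
    out <- out + m$w[i] * tps_kernel(r)
  }
  out
}

#' Interpolate a fitted surface over a DEM
#'
#' Evaluates the spline at every cell centre of the DEM, with the cell's
#' elevation as the covariate.  Nodata DEM cells propagate to nodata.
#'
#' @param m A [fit_tps()] model.
#' @param dem An [ascii_grid()] of elevations.
#' @return An [ascii_grid()] with the DEM's geometry.
#' @export
predict_grid <- function(m, dem) {
  stopifnot(inherits(m, "tps_model"), inherits(dem, "ascii_grid"))
  cc <- grid_centres(dem)
  nr <- nrow(dem$values); nc <- ncol(dem$values)
  X <- matrix(cc$x, nr, nc, byrow = TRUE)
  Y <- matrix(cc$y, nr, nc)
  out <- matrix(predict_tps(m, as.vector(X), as.vector(Y),
                            as.vector(dem$values)), nr, nc)
  out[is.na(dem$values)] <- NA
  ascii_grid(out, dem$xllcorner, dem$yllcorner, dem$cellsize, dem$nodata)
}

#' Cellwise difference of two grids (future - current)
#'
#' @param future,current [ascii_grid()]s of identical geometry.
#' @return An [ascii_grid()]; nodata in either operand propagates.
#' @export
grid_difference <- function(future, current) {
  stopifnot(inherits(future, "ascii_grid"), inherits(current, "ascii_grid"))
  if (!same_geometry(future, current)) stop("grid geometry mismatch")
  ascii_grid(future$values - current$values, future$xllcorner,
             future$yllcorner, future$cellsize, future$nodata)
}

#' Sample grid values at points (nearest cell)
#'
#' Nearest-cell lookup under the cell-centre convention.  A point exactly
#' on a cell boundary is resolved by round-half-up on the fractional cell
#' index along each axis, i.e. ties go to the eastern/northern cell.
#' Out-of-bounds points yield `NA` with attribute flagging, not an error.
#'
#' @param g An [ascii_grid()].
#' @param x,y Point coordinates.
#' @return Numeric values (`NA` for nodata or out-of-bounds points), with
#'   a logical attribute `"oob"` marking out-of-bounds points.
#' @export
sample_points <- function(g, x, y) {
  stopifnot(inherits(g, "ascii_grid"))
  nr <- nrow(g$values); nc <- ncol(g$values)
  col <- floor((x - g$xllcorner) / g$cellsize + 0.5 + 0.5)
  row_s <- floor((y - g$yllcorner) / g$cellsize + 0.5 + 0.5) # from south
  oob <- col < 1 | col > nc | row_s < 1 | row_s > nr |
    x < g$xllcorner | x > g$xllcorner + nc * g$cellsize |
    y < g$yllcorner | y > g$yllcorner + nr * g$cellsize
  ## points exactly on the outer east/north boundary round outward; clamp
  col <- pmin(pmax(col, 1), nc)
  row_s <- pmin(pmax(row_s, 1), nr)
  row <- nr - row_s + 1
  out <- rep(NA_real_, length(x))
  ok <- !oob
  out[ok] <- g$values[cbind(row[ok], col[ok])]
  attr(out, "oob") <- oob
  out
}

#' Mean change by altitude band
#'
#' Partitions valid cells into `n_bins` equal-width elevation bins over the
#' DEM's \[min, max\] and averages the change grid in each bin (the top bin
#' is closed above).  Empty bins are reported with `NA` means.
#'
#' @param change An [ascii_grid()] of index changes.
#' @param dem An [ascii_grid()] of elevations, same geometry.
#' @param n_bins Number of altitude bins (>= 1).
#' @return data.frame with `bin_mid_alt_m`, `mean_change`, `n_cells`.
#' @export
altitude_profile <- function(change, dem, n_bins) {
  stopifnot(inherits(change, "ascii_grid"), inherits(dem, "ascii_grid"))
  if (!same_geometry(change, dem)) stop("grid geometry mismatch")
  if (n_bins < 1) stop("n_bins must be >= 1")
  ok <- !is.na(change$values) & !is.na(dem$values)
  if (!any(ok)) stop("no valid (non-nodata) cells")
  e <- dem$values[ok]; v <- change$values[ok]
  lo <- min(e); hi <- max(e)
  edges <- seq(lo, hi, length.out = n_bins + 1)
  bin <- if (hi > lo)
    pmin(findInterval(e, edges, rightmost.closed = TRUE), n_bins)
  else rep(1L, length(e))
  mid <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  data.frame(
    bin_mid_alt_m = mid,
    mean_change = vapply(seq_len(n_bins), function(b)
      if (any(bin == b)) mean(v[bin == b]) else NA_real_, numeric(1)),
    n_cells = vapply(seq_len(n_bins), function(b) sum(bin == b), integer(1)))
}
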