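# Grids, thin-plate splines, differencing, point sampling, profiling.

toy_grid <- function(values = matrix(as.numeric(1:12), 3, 4), xll = 100,
                     yll = 200,
                     cs = 10) {
  ascii_grid(values, xll, yll, cs)
}

test_that("ESRI ASCII grids round-trip losslessly at the written precision", {
  g <- toy_grid(matrix(c(1.234567, -2.5, NA, 0, 1e6, 3.1), 2, 3))
  tmp <- withr::local_tempfile(fileext = ".asc")
  write_asc(g, tmp)
  back <- read_asc(tmp)
  expect_equal(back$values, signif(g$values, 6))
  expect_equal(back$xllcorner, g$xllcorner)
  expect_equal(back$cellsize, g$cellsize)
  # write -> read -> write -> read is the identity
  tmp2 <- withr::local_tempfile(fileext = ".asc")
  write_asc(back, tmp2)
  expect_equal(read_asc(tmp2), back)
  # header casing is accepted on read
  lines <- readLines(tmp)
  lines[6] <- sub("nodata_value", "NODATA_value", lines[6])
  writeLines(lines, tmp)
  expect_equal(read_asc(tmp)$values, back$values)
})

test_that("TPS interpolates exactly at stations and reproduces affine fields", {
  tr <- demo_stations()
  co <- tr$coords
  # an arbitrary smooth field sampled at the stations
  v <- 0.5 + 0.3 * sin(co$x / 7000) + 1e-4 * co$alt
  m <- fit_tps(co$x, co$y, co$alt, v)
  expect_lt(max(abs(predict_tps(m, co$x, co$y, co$alt) - v)), 1e-8)
  # kernel weight orthogonality constraints
  expect_lt(abs(sum(m$w)), 1e-8)
  expect_lt(abs(sum(m$w * m$x)), 1e-8)
  expect_lt(abs(sum(m$w * m$y)), 1e-8)

  # constant field: trend absorbs it, all other coefficients vanish
  mc <- fit_tps(co$x, co$y, co$alt, rep(7, 6))
  expect_equal(mc$a[1], 7, tolerance = 1e-8)
  expect_lt(max(abs(c(mc$a[-1], mc$w))), 1e-8)
  expect_equal(predict_tps(mc, c(0, 12345), c(0, 9999), c(800, 1500)),
               c(7, 7), tolerance = 1e-8)

  # exactly affine data in (x, y, elev): zero kernel weights, exact fit
  va <- 2 + 3e-4 * co$x - 1e-4 * co$y + 5e-3 * co$alt
  ma <- fit_tps(co$x, co$y, co$alt, va)
  expect_lt(max(abs(ma$w)), 1e-8)
  px <- c(4000, 21000); py <- c(8000, 14000); pe <- c(900, 1600)
  expect_equal(predict_tps(ma, px, py, pe),
               2 + 3e-4 * px - 1e-4 * py + 5e-3 * pe, tolerance = 1e-6)

  # leave-one-out refits stay finite (refit oracle)
  loo <- vapply(seq_len(6), function(i) {
    mi <- fit_tps(co$x[-i], co$y[-i], co$alt[-i], v[-i])
    predict_tps(mi, co$x[i], co$y[i], co$alt[i]) - v[i]
  }, numeric(1))
  expect_true(all(is.finite(loo)))

  # translation invariance of predictions
  m2 <- fit_tps(co$x + 5e4, co$y - 3e4, co$alt, v)
  q <- predict_tps(m, c(2000, 18000), c(5000, 15000), c(750, 1700))
  q2 <- predict_tps(m2, c(2000, 18000) + 5e4, c(5000, 15000) - 3e4,
                    c(750, 1700))
  expect_equal(q, q2, tolerance = 1e-8)

  expect_error(fit_tps(co$x[1:3], co$y[1:3], co$alt[1:3], v[1:3]),
               "at least 4")
  expect_error(fit_tps(rep(1, 5), rep(2, 5), 1:5, 1:5), "distinct")
  # collinear stations are rejected with a clear message
  expect_error(fit_tps(1:5, rep(0, 5), 1:5, 1:5), "collinear|singular")
})

test_that("grid prediction honours geometry and nodata, and differencing is exact", {
  tr <- demo_stations()
  co <- tr$coords
  v <- 1 + 1e-3 * co$alt
  m <- fit_tps(co$x, co$y, co$alt, v)
  dem <- tr$dem
  dem$values[5, 7] <- NA
  g <- predict_grid(m, dem)
  expect_equal(dim(g$values), dim(dem$values))
  expect_true(is.na(g$values[5, 7]))
  expect_equal(g$cellsize, dem$cellsize)

  # a station placed exactly at a cell centre is reproduced there
  cs <- dem$cellsize
  ic <- 12; ir <- 20
  xc <- dem$xllcorner + (ic - 0.5) * cs
  yc <- dem$yllcorner + (nrow(dem$values) - ir + 0.5) * cs
  x2 <- co$x; y2 <- co$y
  x2[3] <- xc; y2[3] <- yc
  elev3 <- dem$values[ir, ic]
  alt2 <- co$alt; alt2[3] <- elev3
  m2 <- fit_tps(x2, y2, alt2, v)
  g2 <- predict_grid(m2, dem)
  expect_equal(g2$values[ir, ic], v[3], tolerance = 1e-8)

  d <- grid_difference(g, g)
  expect_true(all(d$values[!is.na(d$values)] == 0))
  gp <- g; gp$values <- gp$values + 0.05
  dv <- grid_difference(gp, g)$values
  expect_true(all(abs(dv[!is.na(dv)] - 0.05) < 1e-12))
  expect_equal(grid_difference(gp, g)$values,
               -grid_difference(g, gp)$values)
  g3 <- ascii_grid(matrix(1, 2, 2), 0, 0, 1)
  expect_error(grid_difference(g, g3), "geometry")
})

test_that("point sampling uses nearest cell with a round-half-up tie-break", {
  m <- matrix(as.numeric(1:12), 3, 4)   # 3 rows (north first) x 4 cols
  g <- toy_grid(m, xll = 0, yll = 0, cs = 10)
  # exact centre of column 2, row 2 (from north)
  expect_equal(sample_points(g, 15, 15)[1], m[2, 2])
  # corner between cells: ties go east and north
  expect_equal(sample_points(g, 10, 10)[1], m[2, 2])
  # out-of-bounds is flagged per point, not an error
  v <- sample_points(g, c(-5, 15), c(15, 15))
  expect_true(is.na(v[1]) && attr(v, "oob")[1])
  expect_false(attr(v, "oob")[2])
  # nodata passes through without an oob flag
  m2 <- m; m2[2, 2] <- NA
  g2 <- toy_grid(m2, xll = 0, yll = 0, cs = 10)
  v2 <- sample_points(g2, 15, 15)
  expect_true(is.na(v2[1]) && !attr(v2, "oob")[1])
})

test_that("altitude profiling bins by elevation and averages changes", {
  dem <- toy_grid(matrix(seq(700, 1800, length.out = 12), 3, 4))
  const <- toy_grid(matrix(2.5, 3, 4))
  pr <- altitude_profile(const, dem, n_bins = 4)
  expect_equal(pr$mean_change, rep(2.5, 4))
  expect_equal(sum(pr$n_cells), 12)
  # identity test: change equals elevation -> bin means near bin midpoints
  ident <- toy_grid(dem$values)
  pr2 <- altitude_profile(ident, dem, n_bins = 5)
  bw <- (1800 - 700) / 5
  ok <- !is.na(pr2$mean_change)
  expect_true(all(abs(pr2$mean_change[ok] - pr2$bin_mid_alt_m[ok]) <= bw / 2))
  # a single bin is the overall mean of valid cells
  pr3 <- altitude_profile(ident, dem, n_bins = 1)
  expect_equal(pr3$mean_change, mean(dem$values))
  allna <- toy_grid(matrix(NA_real_, 3, 4))
  expect_error(altitude_profile(allna, dem, 3), "valid")
})
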