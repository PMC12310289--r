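# Grid data model, ASCII raster IO, bilinear resampling and spherical
# geometry.

test_that("ASCII raster round-trip preserves values, mask and georeference", {
  set.seed(7)
  m <- matrix(rnorm(12 * 15), 12, 15)
  mask <- matrix(FALSE, 12, 15)
  mask[c(3, 40, 100)] <- TRUE
  m[mask] <- NA_real_
  g <- env_grid(list(tmin = m), origin_lon = -8.25, origin_lat = 43.5,
                res_arcmin = 5, nodata_mask = mask)
  path <- withr::local_tempfile(fileext = ".asc")
  write_layer(g, "tmin", path)
  g2 <- read_layer(path, "tmin")
  expect_equal(g2$origin_lon, g$origin_lon, tolerance = 1e-9)
  expect_equal(g2$origin_lat, g$origin_lat, tolerance = 1e-9)
  expect_equal(g2$res_arcmin, g$res_arcmin, tolerance = 1e-9)
  expect_identical(g2$nodata_mask, mask)
  ok <- !mask
  expect_equal(g2$layers$tmin[ok], m[ok], tolerance = 1e-6)
})

test_that("read_layer handles constant grids, nodata counts and bad files", {
  g <- flat_grid(10, 10, value = 5)
  path <- withr::local_tempfile(fileext = ".asc")
  write_layer(g, "x", path)
  r <- read_layer(path, "x")
  expect_true(all(r$layers$x == 5))
  expect_false(any(r$nodata_mask))

  # three nodata cells -> exactly three masked entries
  m <- matrix(1, 6, 6); m[c(2, 9, 30)] <- NA
  g2 <- env_grid(list(x = m), 0, 45, 5,
                 nodata_mask = matrix(is.na(m), 6, 6))
  write_layer(g2, "x", path)
  expect_identical(sum(read_layer(path, "x")$nodata_mask), 3L)

  # projected (large cellsize) and truncated files are rejected
  writeLines(c("ncols 2", "nrows 2", "xllcorner 0", "yllcorner 0",
               "cellsize 1000", "NODATA_value -9999", "1 2", "3 4"),
             path)
  expect_error(read_layer(path, "x"), "geographic")
  writeLines(c("ncols 2", "nrows 2", "xllcorner 0", "yllcorner 0",
               "cellsize 0.1", "NODATA_value -9999", "1 2", "3 4", "5 6"),
             path)
  expect_error(read_layer(path, "x"), "single band|truncated")
})

test_that("bilinear resampling matches a pointwise closed-form oracle", {
  set.seed(11)
  vals <- matrix(rnorm(36), 6, 6)
  g <- env_grid(list(v = vals), origin_lon = 2, origin_lat = 50,
                res_arcmin = 3)
  out <- bilinear_resample(g, 5)

  # independent per-point bilinear interpolation in cell-center space
  oracle_at <- function(lon, lat) {
    gx <- (lon - g$origin_lon) / (3 / 60) - 0.5
    gy <- (g$origin_lat - lat) / (3 / 60) - 0.5
    gx <- min(max(gx, 0), 5); gy <- min(max(gy, 0), 5)
    x0 <- min(floor(gx), 4); y0 <- min(floor(gy), 4)
    tx <- gx - x0; ty <- gy - y0
    (1 - ty) * ((1 - tx) * vals[y0 + 1, x0 + 1] +
                tx * vals[y0 + 1, x0 + 2]) +
      ty * ((1 - tx) * vals[y0 + 2, x0 + 1] + tx * vals[y0 + 2, x0 + 2])
  }
  lons <- cell_lons(out); lats <- cell_lats(out)
  for (i in seq_len(out$n_rows)) {
    for (j in seq_len(out$n_cols)) {
      expect_equal(out$layers$v[i, j], oracle_at(lons[j], lats[i]),
                   tolerance = 1e-9)
    }
  }
})

test_that("bilinear resampling: constants, midpoints, identity, masks", {
  g <- flat_grid(8, 8, value = 3.25)
  expect_true(all(abs(bilinear_resample(g, 3)$layers$x - 3.25) < 1e-12))

  # 2x2 field [[0,1],[0,1]] sampled midway between columns gives 0.5
  g2 <- env_grid(list(x = rbind(c(0, 1), c(0, 1))), 0, 45, 60)
  out <- bilinear_resample(g2, 30)   # 4x4; middle columns at t = 0.25/0.75
  mid <- bilinear_resample(g2, 60)   # identity check below
  gx <- (cell_lons(out) - 0) / 1 - 0.5
  expect_equal(out$layers$x[1, ], pmin(pmax(gx, 0), 1), tolerance = 1e-12)

  # same resolution with aligned centers is the identity
  expect_equal(mid$layers$x, g2$layers$x, tolerance = 1e-12)

  # masked input cells propagate to touching output cells
  m <- matrix(1, 4, 4); mask <- matrix(FALSE, 4, 4); mask[2, 2] <- TRUE
  g3 <- env_grid(list(x = m), 0, 45, 10, nodata_mask = mask)
  fine <- bilinear_resample(g3, 5)
  expect_true(any(fine$nodata_mask))
  expect_true(all(is.na(fine$layers$x[fine$nodata_mask])))

  expect_error(bilinear_resample(g, -1))
})

test_that("cell areas follow the spherical closed form", {
  r_km <- 6371.0
  # global 1-degree tiling sums to the sphere surface
  g <- env_grid(list(x = matrix(0, 180, 360)), origin_lon = -180,
                origin_lat = 90, res_arcmin = 60)
  total <- sum(cell_areas_km2(g)) * 360
  expect_equal(total / (4 * pi * r_km^2), 1, tolerance = 1e-6)

  # 1x1 degree cell centered on the equator
  g_eq <- env_grid(list(x = matrix(0, 1, 1)), 0, 0.5, 60)
  expect_equal(cell_areas_km2(g_eq),
               r_km^2 * (pi / 180) * 2 * sin(0.5 * pi / 180),
               tolerance = 1e-12)

  # band ratio at 60 N vs the equator
  g_60 <- env_grid(list(x = matrix(0, 1, 1)), 0, 61, 60)
  ratio <- cell_areas_km2(g_60) / cell_areas_km2(g_eq)
  expect_equal(ratio,
               (sin(61 * pi / 180) - sin(60 * pi / 180)) /
                 (sin(0.5 * pi / 180) - sin(-0.5 * pi / 180)),
               tolerance = 1e-12)

  # strictly decreasing with |latitude| (northern rows: |lat| falls with i)
  g_band <- env_grid(list(x = matrix(0, 80, 2)), 0, 80, 60)
  a <- cell_areas_km2(g_band)
  expect_true(all(diff(a) > 0))

  g_bad <- env_grid(list(x = matrix(0, 4, 4)), 0, 92, 60)
  expect_error(cell_areas_km2(g_bad), "latitude")
})

test_that("align_or_fail names the first differing property", {
  g1 <- flat_grid(10, 10)
  expect_silent(align_or_fail(list(g1)))
  expect_silent(align_or_fail(list(g1, g1)))
  g2 <- flat_grid(10, 11)
  expect_error(align_or_fail(list(g1, g2)), "n_cols")
  g3 <- flat_grid(10, 10, origin_lon = 0.5)
  expect_error(align_or_fail(list(g1, g3)), "origin_lon")
  g4 <- flat_grid(10, 10, res_arcmin = 6)
  expect_error(align_or_fail(list(g1, g4)), "res_arcmin")
})

test_that("grid constructor enforces shape and name invariants", {
  expect_error(env_grid(list(matrix(0, 2, 2)), 0, 45, 5), "names")
  expect_error(env_grid(list(a = matrix(0, 2, 2), b = matrix(0, 3, 2)),
                        0, 45, 5), "share")
  expect_error(env_grid(list(a = matrix(0, 2, 2)), 0, 45, -5), "positive")
  g <- flat_grid()
  expect_error(get_layer(g, "missing"), "not present")
})
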