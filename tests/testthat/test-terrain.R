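write_raw_hgt <- function(vals_north_first, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(t(vals_north_first)), con, size = 2, endian = "big")
  path
}

test_that("an all-sea SRTM3 tile reads as zeros at 3 arc-seconds", {
  path <- tempfile(fileext = ".hgt")
  n <- 1201
  write_raw_hgt(matrix(0L, n, n), path)
  g <- read_hgt(path, origin_lon = -2, origin_lat = 43)
  expect_equal(g$n_rows, n)
  expect_equal(g$cell_arcsec, 3)
  expect_true(all(g$values == 0L))
  expect_false(any(g$void_mask))
  expect_equal(g$origin_lon, -2)
})

test_that("void sentinel cells are flagged and row order is south-first", {
  n <- 1201
  vals <- matrix(0L, n, n)
  vals[1, 5] <- 1234L    # north-west area on disk
  vals[n, 2] <- -32768L  # south row on disk
  path <- write_raw_hgt(vals, tempfile(fileext = ".hgt"))
  g <- read_hgt(path)
  expect_equal(sum(g$void_mask), 1L)
  expect_true(g$void_mask[1, 2])       # south row after re-ordering
  expect_equal(g$values[n, 5], 1234L)  # north row after re-ordering
})

test_that("SRTM1 tile size implies 1 arc-second resolution", {
  n <- 3601
  path <- write_raw_hgt(matrix(0L, n, n), tempfile(fileext = ".hgt"))
  g <- read_hgt(path)
  expect_equal(g$cell_arcsec, 1)
  expect_equal(g$n_cols, n)
})

test_that("malformed HGT files raise format errors naming expected sizes", {
  path <- tempfile(fileext = ".hgt")
  writeBin(raw(100), path)
  expect_error(read_hgt(path), "1201")
  expect_error(read_hgt(path), "3601")
  expect_error(read_hgt(tempfile(fileext = ".hgt")), "cannot read")
})

test_that("HGT write/read round-trips values and void mask", {
  n <- 1201
  vals <- matrix(as.integer(sample(-100:3000, n * n, replace = TRUE)), n, n)
  vals[3, 7] <- -32768L
  g0 <- elevation_grid(-2, 43, 3, vals)
  path <- tempfile(fileext = ".hgt")
  write_hgt(g0, path)
  g1 <- read_hgt(path, origin_lon = -2, origin_lat = 43)
  expect_identical(g1$values, g0$values)
  expect_identical(g1$void_mask, g0$void_mask)
})

test_that("ESRI ASCII grid round-trips a small synthetic grid", {
  g0 <- synth_terrain(list(lon = c(0, 0.5), lat = c(0, 0.5)), 120,
                      spec = list(amplitude = 900, ridge_lat = 0.2,
                                  ridge_width = 0.1, noise_sd = 25),
                      seed = 7)
  path <- tempfile(fileext = ".asc")
  write_ascii_grid(g0, path)
  g1 <- read_ascii_grid(path)
  expect_identical(g1$values, g0$values)
  expect_equal(g1$cell_arcsec, g0$cell_arcsec)
  expect_equal(g1$origin_lat, g0$origin_lat)
})

test_that("synthetic terrain: flat, crest and determinism behave analytically", {
  b <- list(lon = c(0, 1), lat = c(0, 1))
  flat <- synth_terrain(b, 120, spec = list(amplitude = 0))
  expect_true(all(flat$values == 0L))
  ridge <- synth_terrain(b, 120, spec = list(amplitude = 1200,
                                             ridge_lat = 0.5,
                                             ridge_width = 0.05))
  crest <- elevation_at(ridge, cbind(0.5, 0.5))
  expect_equal(crest, 1200)
  far <- elevation_at(ridge, cbind(0.5, 0))
  expect_equal(far, 0)
  spec <- list(amplitude = 500, ridge_lat = 0.4, ridge_width = 0.2,
               noise_sd = 30)
  expect_identical(synth_terrain(b, 120, spec, seed = 3)$values,
                   synth_terrain(b, 120, spec, seed = 3)$values)
  expect_false(identical(synth_terrain(b, 120, spec, seed = 3)$values,
                         synth_terrain(b, 120, spec, seed = 4)$values))
  expect_error(synth_terrain(b, 120, spec = list(amplitude = -5)),
               "parameter error")
  expect_error(synth_terrain(b, -3, spec = list(amplitude = 0)),
               "parameter error")
})

test_that("bilinear interpolation reproduces nodes, cell centres and bounds", {
  g <- flat_grid(7)
  expect_equal(elevation_at(g, cbind(runif(5), runif(5))), rep(7, 5))
  # two-row grid with corner values 0, 0 (south) and 100, 100 (north)
  vals <- rbind(c(0L, 0L), c(100L, 100L))
  g2 <- elevation_grid(0, 0, 3600, vals)
  expect_equal(elevation_at(g2, cbind(0.5, 0.5)), 50)
  expect_equal(elevation_at(g2, cbind(0, 1)), 100)   # exact node
  expect_error(elevation_at(g2, cbind(2, 0.5)), "outside")
})

test_that("interpolated values stay within the surrounding cell range", {
  g <- synth_terrain(list(lon = c(0, 1), lat = c(0, 1)), 240,
                     spec = list(amplitude = 800, ridge_lat = 0.6,
                                 ridge_width = 0.15, noise_sd = 40),
                     seed = 11)
  set.seed(42)
  pts <- cbind(runif(200), runif(200))
  v <- elevation_at(g, pts)
  expect_true(all(v >= min(g$values) - 1e-9))
  expect_true(all(v <= max(g$values) + 1e-9))
})

test_that("void cells fall back to the nearest non-void value", {
  vals <- matrix(10L, 3, 3)
  vals[2, 2] <- -32768L
  vals[1, 1] <- 40L
  g <- elevation_grid(0, 0, 3600, vals)
  # query adjacent to the void centre cell: nearest non-void dominates
  v <- elevation_at(g, cbind(0.9, 0.9))
  expect_true(is.finite(v) && v >= 10 && v <= 40)
  expect_true(all(is.finite(elevation_at(g, cbind(runif(10) * 2,
                                                  runif(10) * 2)))))
})
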