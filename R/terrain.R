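VOID_SENTINEL <- -32768L

#' Elevation grid container
#'
#' A regular lon/lat grid of integer elevations (metres above sea level), the
#' in-memory representation of an SRTM HGT tile or of a synthetic terrain.
#' Rows are stored south-to-north so that `(row, col)` increases with
#' `(lat, lon)`; `values[1, 1]` is the south-west corner. Sea level is 0 and
#' void (unknown) cells carry the raw sentinel -32768, mirrored in
#' `void_mask`.
#'
#' @param origin_lon,origin_lat degrees of the SW corner
#' @param cell_arcsec grid resolution in arc-seconds
#' @param values integer matrix, `values[row, col]` with row = latitude index
#'   (south first), col = longitude index (west first)
#' @param void_mask logical matrix of the same shape flagging unknown cells
#' @return an object of class `elevation_grid`
#' @export
elevation_grid <- function(origin_lon, origin_lat, cell_arcsec, values,
                           void_mask = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  if (is.null(void_mask)) void_mask <- values == VOID_SENTINEL
  if (!identical(dim(void_mask), dim(values)))
    stop("void_mask shape must match values")
  if (any(values[!void_mask] == VOID_SENTINEL))
    stop("unflagged cell equals the void sentinel -32768")
  structure(
    list(origin_lon = origin_lon, origin_lat = origin_lat,
         n_rows = nrow(values), n_cols = ncol(values),
         cell_arcsec = cell_arcsec, values = values, void_mask = void_mask),
    class = "elevation_grid")
}

#' @export
print.elevation_grid <- function(x, ...) {
  cat(sprintf(
    "<elevation_grid> %d x %d cells @ %g arcsec, SW corner (%.4f, %.4f)\n",
    x$n_rows, x$n_cols, x$cell_arcsec, x$origin_lon, x$origin_lat))
  cat(sprintf("  elevation range: %d..%d m, %d void cells\n",
              min(x$values[!x$void_mask]), max(x$values[!x$void_mask]),
              sum(x$void_mask)))
  invisible(x)
}

grid_lons <- function(grid) {
  grid$origin_lon + (seq_len(grid$n_cols) - 1) * grid$cell_arcsec / 3600
}

grid_lats <- function(grid) {
  grid$origin_lat + (seq_len(grid$n_rows) - 1) * grid$cell_arcsec / 3600
}

grid_bbox <- function(grid) {
  c(lon_min = grid$origin_lon,
    lon_max = grid$origin_lon + (grid$n_cols - 1) * grid$cell_arcsec / 3600,
    lat_min = grid$origin_lat,
    lat_max = grid$origin_lat + (grid$n_rows - 1) * grid$cell_arcsec / 3600)
}

#' Read an SRTM HGT elevation tile
#'
#' HGT tiles are raw big-endian signed 16-bit integers, row-major from the
#' north-west corner, covering 1 x 1 degree: 1201 x 1201 cells for SRTM3
#' (3 arc-second) or 3601 x 3601 for SRTM1 (1 arc-second). Unknown cells
#' equal -32768. Rows are re-ordered south-to-north on read.
#'
#' @param path path to the `.hgt` file
#' @param origin_lon,origin_lat SW corner of the tile in degrees; if `NULL`,
#'   parsed from a file name of the form `N43W002.hgt`, else 0
#' @return an [elevation_grid()]
#' @export
read_hgt <- function(path, origin_lon = NULL, origin_lat = NULL) {
  if (!file.exists(path)) stop("cannot read HGT file: ", path)
  sz <- file.size(path)
  n <- sqrt(sz / 2)
  if (!(n %in% c(1201, 3601)))
    stop(sprintf(paste0(
      "HGT format error: file size %d bytes; expected 2*1201^2 = %d ",
      "(SRTM3) or 2*3601^2 = %d (SRTM1) bytes"),
      sz, 2 * 1201^2, 2 * 3601^2))
  n <- as.integer(n)
  parsed <- parse_hgt_name(basename(path))
  if (is.null(origin_lon)) origin_lon <- parsed["lon"]
  if (is.null(origin_lat)) origin_lat <- parsed["lat"]
  con <- file(path, "rb")
  on.exit(close(con))
  raw <- readBin(con, "integer", n = n * n, size = 2, signed = TRUE,
                 endian = "big")
  vals <- matrix(raw, nrow = n, ncol = n, byrow = TRUE) # row 1 = north edge
  vals <- vals[n:1, , drop = FALSE]                     # re-order: row 1 = south
  elevation_grid(unname(origin_lon), unname(origin_lat),
                 cell_arcsec = if (n == 1201L) 3 else 1, values = vals)
}

parse_hgt_name <- function(name) {
  m <- regmatches(name, regexec("^([NS])(\\d{2})([EW])(\\d{3})", name))[[1]]
  if (length(m) == 5) {
    lat <- as.numeric(m[3]) * if (m[2] == "S") -1 else 1
    lon <- as.numeric(m[5]) * if (m[4] == "W") -1 else 1
    c(lon = lon, lat = lat)
  } else c(lon = 0, lat = 0)
}

#' Write an elevation grid in SRTM HGT byte layout
#'
#' Inverse of [read_hgt()] for square grids: big-endian int16, rows emitted
#' north first. Voids are written as the sentinel -32768.
#'
#' @param grid an [elevation_grid()]
#' @param path output file
#' @export
write_hgt <- function(grid, path) {
  vals <- grid$values
  vals[grid$void_mask] <- VOID_SENTINEL
  vals <- vals[grid$n_rows:1, , drop = FALSE] # north first on disk
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(t(vals)), con, size = 2, endian = "big")
  invisible(path)
}

#' Generate synthetic terrain
#'
#' Builds a deterministic analytic surface so the whole pipeline can run
#' without real SRTM tiles: a Gaussian ridge of amplitude `amplitude` metres
#' running east-west along the parallel `ridge_lat`, optionally interrupted
#' by a north-south valley gap (a Gaussian notch centred at `valley_lon`),
#' plus optional seeded white noise. Values are rounded to integer metres.
#'
#' @param bounds list with components `lon = c(min, max)` and
#'   `lat = c(min, max)` in degrees
#' @param resolution cell size in arc-seconds
#' @param spec list of surface parameters: `amplitude` (m, >= 0),
#'   `ridge_lat`, `ridge_width` (deg), `valley_lon` (deg or `NULL` for no
#'   gap), `valley_width` (deg), `noise_sd` (m), `base` (m)
#' @param seed integer seed for the noise component
#' @return an [elevation_grid()] with no voids
#' @export
synth_terrain <- function(bounds, resolution, spec = list(), seed = 1L) {
  if (resolution <= 0) stop("parameter error: resolution must be positive")
  s <- utils::modifyList(list(amplitude = 0, ridge_lat = NA_real_,
                              ridge_width = 0.1, valley_lon = NULL,
                              valley_width = 0.05, noise_sd = 0, base = 0),
                         spec)
  if (s$amplitude < 0) stop("parameter error: amplitude must be >= 0")
  step <- resolution / 3600
  lons <- seq(bounds$lon[1], bounds$lon[2], by = step)
  lats <- seq(bounds$lat[1], bounds$lat[2], by = step)
  z <- matrix(s$base, nrow = length(lats), ncol = length(lons))
  if (s$amplitude > 0 && is.finite(s$ridge_lat)) {
    ridge <- exp(-((lats - s$ridge_lat)^2) / (2 * s$ridge_width^2))
    notch <- if (is.null(s$valley_lon)) rep(1, length(lons)) else
      1 - exp(-((lons - s$valley_lon)^2) / (2 * s$valley_width^2))
    z <- z + s$amplitude * outer(ridge, notch)
  }
  if (s$noise_sd > 0) {
    z <- z + with_preserved_seed(seed, {
      matrix(stats::rnorm(length(z), sd = s$noise_sd), nrow = nrow(z))
    })
  }
  elevation_grid(bounds$lon[1], bounds$lat[1], resolution,
                 matrix(as.integer(round(z)), nrow = nrow(z)))
}

# Run expr with a local RNG seed, restoring the caller's RNG state.
with_preserved_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Interpolate elevation at arbitrary points
#'
#' Bilinear interpolation of the four surrounding cells. If any of the four
#' is void, the value of the nearest non-void cell is used instead.
#'
#' @param grid an [elevation_grid()]
#' @param points numeric matrix (or length-2 vector) with columns (lon, lat)
#' @return numeric vector of elevations in metres
#' @export
elevation_at <- function(grid, points) {
  points <- coerce_points(points)
  bb <- grid_bbox(grid)
  tol <- 1e-9
  bad <- points[, 1] < bb["lon_min"] - tol | points[, 1] > bb["lon_max"] + tol |
         points[, 2] < bb["lat_min"] - tol | points[, 2] > bb["lat_max"] + tol
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("point (%g, %g) outside elevation grid bounds [%g, %g] x [%g, %g]",
                 points[i, 1], points[i, 2], bb["lon_min"], bb["lon_max"],
                 bb["lat_min"], bb["lat_max"]))
  }
  step <- grid$cell_arcsec / 3600
  fx <- (points[, 1] - grid$origin_lon) / step
  fy <- (points[, 2] - grid$origin_lat) / step
  c0 <- pmin(pmax(floor(fx), 0), grid$n_cols - 2L) # SW cell corner indices, 0-based
  r0 <- pmin(pmax(floor(fy), 0), grid$n_rows - 2L)
  if (grid$n_cols == 1L) c0 <- rep(0, nrow(points))
  if (grid$n_rows == 1L) r0 <- rep(0, nrow(points))
  tx <- pmin(pmax(fx - c0, 0), 1)
  ty <- pmin(pmax(fy - r0, 0), 1)
  V <- grid$values
  idx <- function(dr, dc) cbind(r0 + 1L + dr, c0 + 1L + dc)
  v00 <- V[idx(0L, 0L)]; v01 <- V[idx(0L, min(1L, grid$n_cols - 1L))]
  v10 <- V[idx(min(1L, grid$n_rows - 1L), 0L)]
  v11 <- V[idx(min(1L, grid$n_rows - 1L), min(1L, grid$n_cols - 1L))]
  out <- (1 - ty) * ((1 - tx) * v00 + tx * v01) +
         ty * ((1 - tx) * v10 + tx * v11)
  if (any(grid$void_mask)) {
    W <- grid$void_mask
    hit <- W[idx(0L, 0L)] | W[idx(0L, min(1L, grid$n_cols - 1L))] |
           W[idx(min(1L, grid$n_rows - 1L), 0L)] |
           W[idx(min(1L, grid$n_rows - 1L), min(1L, grid$n_cols - 1L))]
    if (any(hit)) {
      ok <- which(!W, arr.ind = TRUE)
      if (nrow(ok) == 0) stop("elevation grid is entirely void")
      ok_lon <- grid_lons(grid)[ok[, 2]]
      ok_lat <- grid_lats(grid)[ok[, 1]]
      for (i in which(hit)) {
        d2 <- (ok_lon - points[i, 1])^2 + (ok_lat - points[i, 2])^2
        j <- which.min(d2)
        out[i] <- V[ok[j, 1], ok[j, 2]]
      }
    }
  }
  as.numeric(out)
}

coerce_points <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2, byrow = TRUE)
  points <- as.matrix(points)
  if (ncol(points) != 2) stop("points must have two columns (lon, lat)")
  storage.mode(points) <- "double"
  points
}

#' Write an elevation grid as an ESRI ASCII grid
#'
#' Plain-text fixture format: header (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize` in degrees, `NODATA_value`) followed by rows of
#' integers, north row first.
#'
#' @param grid an [elevation_grid()]
#' @param path output file
#' @export
write_ascii_grid <- function(grid, path) {
  vals <- grid$values
  vals[grid$void_mask] <- VOID_SENTINEL
  hdr <- c(sprintf("ncols %d", grid$n_cols),
           sprintf("nrows %d", grid$n_rows),
           sprintf("xllcorner %.10g", grid$origin_lon),
           sprintf("yllcorner %.10g", grid$origin_lat),
           sprintf("cellsize %.12g", grid$cell_arcsec / 3600),
           sprintf("NODATA_value %d", VOID_SENTINEL))
  rows <- apply(vals[grid$n_rows:1, , drop = FALSE], 1, paste, collapse = " ")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read an ESRI ASCII grid written by [write_ascii_grid()]
#' @param path input file
#' @return an [elevation_grid()]
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  kv <- stats::setNames(vapply(hdr, `[`, "", 2), tolower(vapply(hdr, `[`, "", 1)))
  nc <- as.integer(kv[["ncols"]]); nr <- as.integer(kv[["nrows"]])
  vals <- matrix(as.integer(scan(text = lines[-(1:6)], quiet = TRUE)),
                 nrow = nr, ncol = nc, byrow = TRUE)
  vals <- vals[nr:1, , drop = FALSE]
  elevation_grid(as.numeric(kv[["xllcorner"]]), as.numeric(kv[["yllcorner"]]),
                 as.numeric(kv[["cellsize"]]) * 3600, vals)
}
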