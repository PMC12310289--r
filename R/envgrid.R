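# Regular lon/lat grid with named layers: the data model shared by every
# other module. Origin is the upper-left corner; cells are square in degrees
# (res_arcmin/60); extents are half-open [origin, origin + n*res). Cell
# centers sit at origin + (k - 0.5)*res.

EARTH_RADIUS_KM <- 6371.0

#' Names of the climate predictor layers
#'
#' The climate set: minimum temperature of the coldest month (`tmin`, deg C),
#' maximum temperature of the warmest month (`tmax`, deg C), annual
#' precipitation (`pan`, mm) and precipitation seasonality (`pcv`,
#' coefficient of variation of monthly values).
#' @return Character vector of layer names.
#' @export
climate_layers <- function() c("tmin", "tmax", "pan", "pcv")

#' Names of the land-cover predictor layers
#'
#' Six land-cover percentage layers (0-100, summing to 100 per cell):
#' needleleaf evergreen forest, broadleaf deciduous forest, grassland,
#' shrub, crop and urban.
#' @return Character vector of layer names.
#' @export
landcover_layers <- function() {
  c("needleleaf", "broadleaf", "grassland", "shrub", "crop", "urban")
}

#' Name of the sampling-bias layer
#' @return The string `"bias"`.
#' @export
bias_layer <- function() "bias"

#' Construct an environmental grid
#'
#' @param layers Named list of numeric matrices, all with identical
#'   dimensions.
#' @param origin_lon,origin_lat Upper-left corner of the grid, decimal
#'   degrees.
#' @param res_arcmin Cell size in arcminutes (cells are square in degrees).
#' @param nodata_mask Logical matrix, `TRUE` = outside the study region.
#'   Defaults to all `FALSE`.
#' @param crs_label Text label for the (geographic) CRS.
#' @return An object of class `env_grid`.
#' @export
env_grid <- function(layers, origin_lon, origin_lat, res_arcmin,
                     nodata_mask = NULL, crs_label = "WGS84 lon/lat") {
  if (!is.list(layers) || length(layers) == 0L) {
    stop("`layers` must be a non-empty named list of matrices")
  }
  nm <- names(layers)
  if (is.null(nm) || anyNA(nm) || any(nm == "") || anyDuplicated(nm)) {
    stop("layer names must be unique and non-empty")
  }
  dims <- dim(layers[[1L]])
  if (is.null(dims)) stop("layers must be matrices")
  for (k in seq_along(layers)) {
    if (!is.matrix(layers[[k]]) || !identical(dim(layers[[k]]), dims)) {
      stop("all layers must share the same (n_rows, n_cols); layer '",
           nm[k], "' differs")
    }
    storage.mode(layers[[k]]) <- "double"
  }
  if (is.null(nodata_mask)) {
    nodata_mask <- matrix(FALSE, dims[1L], dims[2L])
  }
  stopifnot(is.logical(nodata_mask), identical(dim(nodata_mask), dims))
  if (!is.numeric(res_arcmin) || length(res_arcmin) != 1L || res_arcmin <= 0) {
    stop("res_arcmin must be a single positive number")
  }
  structure(
    list(origin_lon = as.numeric(origin_lon),
         origin_lat = as.numeric(origin_lat),
         res_arcmin = as.numeric(res_arcmin),
         n_rows = dims[1L], n_cols = dims[2L],
         layers = layers, nodata_mask = nodata_mask,
         crs_label = crs_label),
    class = "env_grid")
}

#' @export
#' @method print env_grid
print.env_grid <- function(x, ...) {
  cat(sprintf("<env_grid> %d x %d cells at %.4g arcmin, origin (%.4f, %.4f)\n",
              x$n_rows, x$n_cols, x$res_arcmin, x$origin_lon, x$origin_lat))
  cat("  layers:", paste(names(x$layers), collapse = ", "), "\n")
  cat(sprintf("  masked cells: %d / %d\n", sum(x$nodata_mask),
              x$n_rows * x$n_cols))
  invisible(x)
}

res_deg <- function(grid) grid$res_arcmin / 60

#' Cell-center longitudes (per column) and latitudes (per row)
#'
#' @param grid An `env_grid`.
#' @return Numeric vector of cell-center coordinates in decimal degrees.
#' @export
cell_lons <- function(grid) {
  grid$origin_lon + (seq_len(grid$n_cols) - 0.5) * res_deg(grid)
}

#' @rdname cell_lons
#' @export
cell_lats <- function(grid) {
  grid$origin_lat - (seq_len(grid$n_rows) - 0.5) * res_deg(grid)
}

#' Extract a single layer matrix
#' @param grid An `env_grid`.
#' @param name Layer name.
#' @return Numeric matrix.
#' @export
get_layer <- function(grid, name) {
  if (!name %in% names(grid$layers)) {
    stop("layer '", name, "' not present in grid; available: ",
         paste(names(grid$layers), collapse = ", "))
  }
  grid$layers[[name]]
}

#' Add or replace a layer
#' @inheritParams get_layer
#' @param values Numeric matrix matching the grid shape.
#' @return The modified `env_grid`.
#' @export
set_layer <- function(grid, name, values) {
  stopifnot(is.matrix(values),
            identical(dim(values), c(grid$n_rows, grid$n_cols)))
  storage.mode(values) <- "double"
  grid$layers[[name]] <- values
  grid
}

#' Read a single-band ESRI ASCII grid raster
#'
#' Reads the plain-text `.asc` raster format (header lines `ncols`, `nrows`,
#' `xllcorner`/`xllcenter`, `yllcorner`/`yllcenter`, `cellsize`,
#' `NODATA_value`, then rows from north to south). The cell size is
#' interpreted as decimal degrees on a geographic lon/lat grid.
#'
#' @param path Path to the `.asc` file.
#' @param name Layer name to assign.
#' @return An `env_grid` with one layer; nodata cells are masked.
#' @export
read_layer <- function(path, name) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, n = 7L)
  hdr <- list()
  n_hdr <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1L]]
    key <- tolower(parts[1L])
    if (key %in% c("ncols", "nrows", "xllcorner", "yllcorner", "xllcenter",
                   "yllcenter", "cellsize", "nodata_value")) {
      hdr[[key]] <- as.numeric(parts[2L])
      n_hdr <- n_hdr + 1L
    } else break
  }
  for (req in c("ncols", "nrows", "cellsize")) {
    if (is.null(hdr[[req]])) stop("missing '", req, "' in ASCII grid header")
  }
  if (hdr$cellsize > 1) {
    stop("cell size ", hdr$cellsize, " degrees: not a geographic ",
         "(lon/lat) grid in the expected resolution range; projected CRS ",
         "rasters are not supported")
  }
  n_rows <- as.integer(hdr$nrows); n_cols <- as.integer(hdr$ncols)
  vals <- scan(path, what = double(), skip = n_hdr, quiet = TRUE)
  if (length(vals) != n_rows * n_cols) {
    stop("expected ", n_rows * n_cols, " values (single band), got ",
         length(vals), "; multi-band or truncated file")
  }
  m <- matrix(vals, nrow = n_rows, ncol = n_cols, byrow = TRUE)
  mask <- matrix(FALSE, n_rows, n_cols)
  if (!is.null(hdr$nodata_value)) {
    mask <- m == hdr$nodata_value
    m[mask] <- NA_real_
  }
  cs <- hdr$cellsize
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else hdr$xllcenter - cs / 2
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else hdr$yllcenter - cs / 2
  env_grid(stats::setNames(list(m), name),
           origin_lon = xll, origin_lat = yll + n_rows * cs,
           res_arcmin = cs * 60, nodata_mask = mask)
}

#' Write one layer of a grid as an ESRI ASCII raster
#'
#' @param grid An `env_grid`.
#' @param name Layer to write.
#' @param path Output path.
#' @param nodata Numeric nodata sentinel written for masked cells.
#' @return `path`, invisibly.
#' @export
write_layer <- function(grid, name, path, nodata = -9999) {
  m <- get_layer(grid, name)
  m[grid$nodata_mask | is.na(m)] <- nodata
  cs <- res_deg(grid)
  hdr <- c(sprintf("ncols %d", grid$n_cols),
           sprintf("nrows %d", grid$n_rows),
           sprintf("xllcorner %.12g", grid$origin_lon),
           sprintf("yllcorner %.12g", grid$origin_lat - grid$n_rows * cs),
           sprintf("cellsize %.12g", cs),
           sprintf("NODATA_value %.12g", nodata))
  body <- apply(m, 1L, function(r) paste(sprintf("%.10g", r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Bilinear resampling to a new resolution
#'
#' Resamples every layer to `target_res_arcmin` over the same extent. Each
#' output value is the bilinear interpolation of the four surrounding input
#' cell centers; outside the hull of input centers values are edge-clamped.
#' An output cell is masked whenever a contributing (positive-weight) input
#' cell is masked.
#'
#' @param grid An `env_grid`.
#' @param target_res_arcmin Target cell size in arcminutes.
#' @return A resampled `env_grid`.
#' @export
bilinear_resample <- function(grid, target_res_arcmin) {
  stopifnot(target_res_arcmin > 0)
  if (grid$n_rows < 1L || grid$n_cols < 1L || length(grid$layers) == 0L) {
    stop("empty grid")
  }
  rd_in <- res_deg(grid)
  rd_out <- target_res_arcmin / 60
  n_rows_out <- max(1L, as.integer(round(grid$n_rows * rd_in / rd_out)))
  n_cols_out <- max(1L, as.integer(round(grid$n_cols * rd_in / rd_out)))

  # fractional 0-based center coordinates of output centers in input space
  frac_axis <- function(n_out, n_in, r_out, r_in) {
    g <- ((seq_len(n_out) - 0.5) * r_out) / r_in - 0.5
    g <- pmin(pmax(g, 0), n_in - 1)
    g[abs(g - round(g)) < 1e-9] <- round(g[abs(g - round(g)) < 1e-9])
    i0 <- pmin(floor(g), max(n_in - 2, 0))
    list(i0 = as.integer(i0) + 1L, t = g - i0)  # 1-based lower index
  }
  fr <- frac_axis(n_rows_out, grid$n_rows, rd_out, rd_in)
  fc <- frac_axis(n_cols_out, grid$n_cols, rd_out, rd_in)

  r0 <- fr$i0; tr <- fr$t
  c0 <- fc$i0; tc <- fc$t
  r1 <- pmin(r0 + 1L, grid$n_rows)
  c1 <- pmin(c0 + 1L, grid$n_cols)

  R0 <- matrix(r0, n_rows_out, n_cols_out)
  R1 <- matrix(r1, n_rows_out, n_cols_out)
  C0 <- matrix(c0, n_rows_out, n_cols_out, byrow = TRUE)
  C1 <- matrix(c1, n_rows_out, n_cols_out, byrow = TRUE)
  TR <- matrix(tr, n_rows_out, n_cols_out)
  TC <- matrix(tc, n_rows_out, n_cols_out, byrow = TRUE)

  w00 <- (1 - TR) * (1 - TC); w01 <- (1 - TR) * TC
  w10 <- TR * (1 - TC);       w11 <- TR * TC

  idx <- function(R, C) cbind(as.vector(R), as.vector(C))
  i00 <- idx(R0, C0); i01 <- idx(R0, C1); i10 <- idx(R1, C0); i11 <- idx(R1, C1)

  interp <- function(m) {
    v <- w00 * matrix(m[i00], n_rows_out) + w01 * matrix(m[i01], n_rows_out) +
      w10 * matrix(m[i10], n_rows_out) + w11 * matrix(m[i11], n_rows_out)
    v
  }
  out_layers <- lapply(grid$layers, interp)

  mk <- grid$nodata_mask
  eps <- 1e-12
  out_mask <- (matrix(mk[i00], n_rows_out) & w00 > eps) |
    (matrix(mk[i01], n_rows_out) & w01 > eps) |
    (matrix(mk[i10], n_rows_out) & w10 > eps) |
    (matrix(mk[i11], n_rows_out) & w11 > eps)

  out_layers <- lapply(out_layers, function(m) { m[out_mask] <- NA_real_; m })
  env_grid(out_layers, grid$origin_lon, grid$origin_lat, target_res_arcmin,
           nodata_mask = out_mask, crs_label = grid$crs_label)
}

#' Spherical cell areas per grid row
#'
#' Area of one cell in each row, on a sphere of radius 6371 km:
#' `R^2 * dlambda * (sin(phi_top) - sin(phi_bottom))` with `dlambda` the cell
#' width in radians. Constant within a row.
#'
#' @param grid An `env_grid`.
#' @return Numeric vector of length `n_rows`, km^2.
#' @export
cell_areas_km2 <- function(grid) {
  rd <- res_deg(grid)
  lat_top <- grid$origin_lat - (seq_len(grid$n_rows) - 1L) * rd
  lat_bot <- lat_top - rd
  if (any(lat_top > 90 + 1e-9) || any(lat_bot < -90 - 1e-9)) {
    stop("grid rows extend outside [-90, 90] latitude")
  }
  dl <- rd * pi / 180
  EARTH_RADIUS_KM^2 * dl * (sin(lat_top * pi / 180) - sin(lat_bot * pi / 180))
}

#' Assert that grids share origin, resolution and shape
#'
#' @param grids List of `env_grid` objects.
#' @param tol Tolerance in degrees for origin/resolution comparison.
#' @return `TRUE` invisibly, or an error naming the first differing property.
#' @export
align_or_fail <- function(grids, tol = 1e-9) {
  stopifnot(length(grids) >= 1L)
  ref <- grids[[1L]]
  for (k in seq_along(grids)[-1L]) {
    g <- grids[[k]]
    if (abs(g$origin_lon - ref$origin_lon) > tol) {
      stop("grid ", k, " misaligned: origin_lon ", g$origin_lon, " vs ",
           ref$origin_lon)
    }
    if (abs(g$origin_lat - ref$origin_lat) > tol) {
      stop("grid ", k, " misaligned: origin_lat ", g$origin_lat, " vs ",
           ref$origin_lat)
    }
    if (abs(g$res_arcmin - ref$res_arcmin) > tol * 60) {
      stop("grid ", k, " misaligned: res_arcmin ", g$res_arcmin, " vs ",
           ref$res_arcmin)
    }
    if (g$n_rows != ref$n_rows) {
      stop("grid ", k, " misaligned: n_rows ", g$n_rows, " vs ", ref$n_rows)
    }
    if (g$n_cols != ref$n_cols) {
      stop("grid ", k, " misaligned: n_cols ", g$n_cols, " vs ", ref$n_cols)
    }
  }
  invisible(TRUE)
}
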