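# Decoupled scenario inputs (both / climate-only / land-only change),
# thresholded binary maps, area of habitat, suitability-weighted centroids
# and great-circle shift distances.

#' Continuous suitability map
#'
#' @param values Numeric matrix in `[0, 1]` (masked cells `NA`).
#' @param grid The `env_grid` supplying the geometry (its layers are not
#'   retained).
#' @param provenance Optional list (species, scenario, mode).
#' @return A `suitability_map`.
#' @export
suitability_map <- function(values, grid, provenance = list()) {
  stopifnot(is.matrix(values),
            identical(dim(values), c(grid$n_rows, grid$n_cols)))
  v <- values[!is.na(values)]
  if (length(v) && (min(v) < -1e-9 || max(v) > 1 + 1e-9)) {
    stop("suitability values must lie in [0, 1]")
  }
  geom <- grid[c("origin_lon", "origin_lat", "res_arcmin", "n_rows",
                 "n_cols", "crs_label")]
  geom$layers <- list()
  geom$nodata_mask <- grid$nodata_mask | is.na(values)
  structure(list(values = values,
                 grid = structure(geom, class = "env_grid"),
                 provenance = provenance),
            class = "suitability_map")
}

#' @export
#' @method print suitability_map
print.suitability_map <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<suitability_map> %d x %d, %d unmasked cells, range %.3f-%.3f\n",
              x$grid$n_rows, x$grid$n_cols, length(v),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' Build the environmental inputs for a decoupled projection
#'
#' `mode = "both"` takes future climate and future land cover;
#' `"clim"` future climate with land cover held at present;
#' `"land"` future land cover with climate held at present. Any further
#' layers (e.g. bias) always come from the current grid.
#'
#' @param current Current `env_grid`.
#' @param future A `scenario_spec` (or aligned `env_grid`).
#' @param mode One of `"both"`, `"clim"`, `"land"`.
#' @return An `env_grid` ready for [predict_ensemble()].
#' @export
make_decoupled_inputs <- function(current, future,
                                  mode = c("both", "clim", "land")) {
  mode <- match.arg(mode)
  fut <- if (inherits(future, "scenario_spec")) future$layer_source else future
  stopifnot(inherits(current, "env_grid"), inherits(fut, "env_grid"))
  align_or_fail(list(current, fut))
  take_future <- switch(mode,
    both = c(climate_layers(), landcover_layers()),
    clim = climate_layers(),
    land = landcover_layers())
  out <- current
  for (nm in intersect(take_future, names(fut$layers))) {
    out$layers[[nm]] <- fut$layers[[nm]]
  }
  out
}

#' Threshold a suitability map into a binary range map
#'
#' @param suit A `suitability_map`.
#' @param threshold Suitability cut-off in `[0, 1]`; cells with
#'   `suitability >= threshold` are suitable.
#' @param region_mask Optional logical matrix (`TRUE` = outside the
#'   reporting region); masked or out-of-region cells are never suitable.
#' @return A `binary_map` recording the threshold used.
#' @export
binarize <- function(suit, threshold, region_mask = NULL) {
  stopifnot(inherits(suit, "suitability_map"),
            threshold >= 0, threshold <= 1)
  ok <- !is.na(suit$values)
  if (!is.null(region_mask)) {
    stopifnot(identical(dim(region_mask), dim(suit$values)))
    ok <- ok & !region_mask
  }
  b <- matrix(FALSE, nrow(suit$values), ncol(suit$values))
  b[ok] <- suit$values[ok] >= threshold
  structure(list(values = b, threshold = threshold, grid = suit$grid,
                 provenance = suit$provenance),
            class = "binary_map")
}

#' Area of habitat in km^2
#'
#' Sum of spherical cell areas over suitable cells of a binary map.
#'
#' @param bin A `binary_map`.
#' @param areas Per-row cell areas; default computed from the map's grid.
#' @return Area in km^2.
#' @export
area_of_habitat <- function(bin, areas = NULL) {
  stopifnot(inherits(bin, "binary_map"))
  if (is.null(areas)) areas <- cell_areas_km2(bin$grid)
  stopifnot(length(areas) == nrow(bin$values))
  sum(rowSums(bin$values) * areas)
}

#' Suitability-weighted range centroid
#'
#' Mean cell-center longitude and latitude weighted by continuous
#' suitability over unmasked (optionally region-restricted) cells. No
#' cell-area weighting enters, by definition.
#'
#' @param suit A `suitability_map`.
#' @param region_mask Optional logical matrix (`TRUE` = exclude).
#' @return Named numeric vector `c(lon, lat)` in degrees.
#' @export
weighted_centroid <- function(suit, region_mask = NULL) {
  stopifnot(inherits(suit, "suitability_map"))
  w <- suit$values
  ok <- !is.na(w)
  if (!is.null(region_mask)) ok <- ok & !region_mask
  w[!ok] <- 0
  tot <- sum(w)
  if (tot <= 0) stop("zero suitability mass in the region")
  lon_w <- colSums(w) %*% cell_lons(suit$grid) / tot
  lat_w <- rowSums(w) %*% cell_lats(suit$grid) / tot
  c(lon = as.numeric(lon_w), lat = as.numeric(lat_w))
}

#' Great-circle distance between two centroids
#'
#' Haversine distance on a sphere of radius 6371 km.
#'
#' @param c_current,c_future Numeric `c(lon, lat)` in degrees.
#' @return Distance in km.
#' @export
shift_km <- function(c_current, c_future) {
  to_rad <- pi / 180
  lon1 <- c_current[[1L]] * to_rad; lat1 <- c_current[[2L]] * to_rad
  lon2 <- c_future[[1L]] * to_rad; lat2 <- c_future[[2L]] * to_rad
  h <- sin((lat2 - lat1) / 2)^2 +
    cos(lat1) * cos(lat2) * sin((lon2 - lon1) / 2)^2
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(h)))
}

#' Restrict a suitability map to currently occupied cells
#'
#' Masks every cell not in the occupied set, so that area, centroid and
#' shift can be recomputed under the assumption that the species cannot
#' move beyond its present cells (dispersal limitation, microhabitat).
#'
#' @param suit A `suitability_map`.
#' @param occupied_cells Linear cell indices (as from [grid_presences()]).
#' @return The restricted `suitability_map`.
#' @export
restrict_to_occupied <- function(suit, occupied_cells) {
  stopifnot(inherits(suit, "suitability_map"), length(occupied_cells) >= 1L)
  n_cell <- nrow(suit$values) * ncol(suit$values)
  if (any(occupied_cells < 1L | occupied_cells > n_cell)) {
    stop("occupied cell indices outside the grid")
  }
  keep <- rep(FALSE, n_cell)
  keep[occupied_cells] <- TRUE
  v <- suit$values
  v[!keep] <- NA_real_
  if (all(is.na(v))) stop("no occupied cell carries a suitability value")
  suitability_map(v, suit$grid,
                  provenance = c(suit$provenance,
                                 list(restricted_to_occupied = TRUE)))
}

#' Percentage change in area of habitat
#'
#' @param area_future,area_current Areas in km^2; `area_current` must be
#'   positive.
#' @return `100 * (area_future - area_current) / area_current`.
#' @export
percent_change <- function(area_future, area_current) {
  if (any(area_current <= 0)) stop("current area must be positive")
  100 * (area_future - area_current) / area_current
}

#' Summarise one projection into a range-summary row
#'
#' @param suit A `suitability_map` for one species x scenario x mode.
#' @param threshold The species' fixed omission threshold.
#' @param current_centroid Centroid of the current projection (`NULL` for
#'   the current map itself, giving `shift_km = 0`).
#' @param species_id,scenario,mode Labels for the output row.
#' @param region_mask Optional reporting-region mask.
#' @param restricted Flag recorded in the row.
#' @return One-row data frame: labels, `area_km2`, `centroid_lon`,
#'   `centroid_lat`, `shift_km`, `restricted_to_occupied`.
#' @export
range_summary <- function(suit, threshold, current_centroid = NULL,
                          species_id = "species", scenario = "current",
                          mode = "current", region_mask = NULL,
                          restricted = FALSE) {
  bin <- binarize(suit, threshold, region_mask)
  cen <- weighted_centroid(suit, region_mask)
  data.frame(species = species_id, scenario = scenario, mode = mode,
             area_km2 = area_of_habitat(bin),
             centroid_lon = cen[["lon"]], centroid_lat = cen[["lat"]],
             shift_km = if (is.null(current_centroid)) 0 else
               shift_km(current_centroid, cen),
             restricted_to_occupied = restricted)
}
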