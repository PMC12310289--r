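# From point records to a weighted presence/pseudo-absence training table:
# gridding presences, the kernel-density effort (bias) surface,
# biome-constrained pseudo-absence draws, and 0.5-prevalence weighting.

#' Occurrence point set
#'
#' @param species_id Species label.
#' @param lons,lats Coordinates in decimal degrees (WGS84).
#' @param source_label Free-text provenance label.
#' @return An `occurrence_set`.
#' @export
occurrence_set <- function(species_id, lons, lats, source_label = "") {
  stopifnot(length(lons) == length(lats))
  if (length(lons) && (anyNA(lons) || anyNA(lats))) {
    stop("occurrence coordinates contain NA/NaN")
  }
  structure(list(species_id = species_id,
                 points = data.frame(lon = as.numeric(lons),
                                     lat = as.numeric(lats)),
                 source_label = source_label),
            class = "occurrence_set")
}

#' Read occurrences from a delimited text file
#'
#' Expects columns `species`, `lon`, `lat` (decimal degrees).
#'
#' @param path CSV path.
#' @param species Optional species to filter to; default keeps all rows.
#' @return An `occurrence_set`.
#' @export
read_occurrences <- function(path, species = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "lon", "lat")
  if (!all(need %in% names(df))) {
    stop("occurrence file must have columns: ", paste(need, collapse = ", "))
  }
  if (!is.null(species)) df <- df[df$species == species, , drop = FALSE]
  df <- df[!is.na(df$lon) & !is.na(df$lat), , drop = FALSE]
  sp <- if (is.null(species)) {
    if (nrow(df)) df$species[1L] else ""
  } else species
  occurrence_set(sp, df$lon, df$lat, source_label = path)
}

# half-open point-in-cell assignment; returns row/col or NA outside extent
point_cell <- function(grid, lon, lat) {
  rd <- res_deg(grid)
  col <- floor((lon - grid$origin_lon) / rd) + 1
  row <- floor((grid$origin_lat - lat) / rd) + 1
  # a point exactly on the top/left boundary belongs to the first cell;
  # on the bottom/right boundary it is outside (half-open extent)
  inside <- col >= 1 & col <= grid$n_cols & row >= 1 & row <= grid$n_rows
  row[!inside] <- NA_integer_
  col[!inside] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Grid occurrence points to presence cells
#'
#' A cell is a presence if at least one record falls in it (duplicates
#' collapse). Points outside the grid extent are dropped with a count
#' reported when more than 1% of the input is lost.
#'
#' @param occ An [occurrence_set()].
#' @param grid An `env_grid`.
#' @return Sorted integer vector of linear (column-major) cell indices.
#' @export
grid_presences <- function(occ, grid) {
  stopifnot(inherits(occ, "occurrence_set"))
  rc <- point_cell(grid, occ$points$lon, occ$points$lat)
  dropped <- sum(is.na(rc[, 1L]))
  if (dropped > 0 && dropped > 0.01 * nrow(rc)) {
    warning(dropped, " of ", nrow(rc), " points fall outside the grid ",
            "extent and were dropped")
  }
  rc <- rc[!is.na(rc[, 1L]), , drop = FALSE]
  if (nrow(rc) == 0L) stop("no occurrence points inside the grid extent")
  sort(unique(rc[, 1L] + (rc[, 2L] - 1L) * grid$n_rows))
}

#' Kernel-density sampling-effort surface
#'
#' Gaussian kernel density of (typically family-level) records evaluated at
#' cell centers and rescaled to `[0, 1]` by its maximum over unmasked cells.
#' Distances are measured in cell units, so the bandwidth is expressed in
#' cells at the working grain.
#'
#' @param family_points Two-column matrix or data frame of (lon, lat).
#' @param grid An `env_grid`.
#' @param bandwidth_cells Gaussian kernel standard deviation, in cells.
#' @return Numeric matrix in `[0, 1]` (masked cells `NA`).
#' @export
kernel_bias <- function(family_points, grid, bandwidth_cells = 10) {
  stopifnot(bandwidth_cells > 0)
  pts <- as.matrix(family_points)[, 1:2, drop = FALSE]
  if (nrow(pts) < 1L) stop("at least one point required")
  rd <- res_deg(grid)
  # 0-based cell-center coordinates of points, in cell units
  px <- (pts[, 1L] - grid$origin_lon) / rd - 0.5
  py <- (grid$origin_lat - pts[, 2L]) / rd - 0.5
  inside <- px > -0.5 & px < grid$n_cols - 0.5 &
    py > -0.5 & py < grid$n_rows - 0.5
  if (!any(inside)) stop("all points fall outside the grid extent")
  px <- px[inside]; py <- py[inside]
  cx <- seq_len(grid$n_cols) - 1
  cy <- seq_len(grid$n_rows) - 1
  h2 <- 2 * bandwidth_cells^2
  dens <- matrix(0, grid$n_rows, grid$n_cols)
  for (k in seq_along(px)) {
    dens <- dens + exp(-(cy - py[k])^2 / h2) %o% exp(-(cx - px[k])^2 / h2)
  }
  dens[grid$nodata_mask] <- NA_real_
  mx <- max(dens[!grid$nodata_mask])
  if (mx == 0) stop("kernel density is zero over all unmasked cells")
  dens / mx
}

#' Draw biome-constrained pseudo-absences
#'
#' Uniform draws without replacement from all cells belonging to a biome
#' that contains at least one presence, excluding presence cells and masked
#' cells. At most `n_max` cells are drawn (all available cells when fewer).
#'
#' @param presences Linear cell indices of presences.
#' @param biome_map Integer matrix of biome ids per cell.
#' @param n_max Maximum number of pseudo-absences (default 10000).
#' @param seed Integer seed; the draw is deterministic given it.
#' @param mask Optional logical matrix of cells to exclude (`TRUE` = out).
#' @return Sorted integer vector of linear cell indices.
#' @export
draw_pseudoabsences <- function(presences, biome_map, n_max = 10000, seed = 1L,
                                mask = NULL) {
  stopifnot(is.matrix(biome_map), length(presences) >= 1L)
  occupied_biomes <- unique(biome_map[presences])
  occupied_biomes <- occupied_biomes[!is.na(occupied_biomes)]
  eligible <- biome_map %in% occupied_biomes
  dim(eligible) <- dim(biome_map)
  if (!is.null(mask)) eligible <- eligible & !mask
  eligible[presences] <- FALSE
  avail <- which(eligible)
  if (length(avail) == 0L) {
    stop("no cells available for pseudo-absences in the occupied biomes")
  }
  n_draw <- min(n_max, length(avail))
  sort(with_seed(seed, avail[sample.int(length(avail), n_draw)]))
}

#' Assemble the weighted training table
#'
#' One row per presence cell (response 1) and pseudo-absence cell
#' (response 0), with every climate and land-cover predictor plus the bias
#' value. Rows with any missing predictor are dropped (reported when more
#' than 1% of the input is lost). Presences get weight 1 and
#' pseudo-absences weight `n_presences / n_pseudoabsences`, so weighted
#' prevalence is exactly 0.5.
#'
#' @param presences,pabs Linear cell indices.
#' @param env An `env_grid` with all predictor layers.
#' @param bias Numeric matrix, the effort surface.
#' @param predictors Predictor layer names (defaults to the climate and
#'   land-cover registries intersected with the grid's layers).
#' @return A `data.frame` of class `training_table` with attributes
#'   `predictors` and `cell_index`.
#' @export
assemble_training <- function(presences, pabs, env, bias,
                              predictors = NULL) {
  if (length(presences) == 0L) stop("empty presence set")
  if (length(pabs) == 0L) stop("empty pseudo-absence set")
  if (is.null(predictors)) {
    predictors <- intersect(c(climate_layers(), landcover_layers()),
                            names(env$layers))
  }
  cells <- c(presences, pabs)
  y <- rep(c(1, 0), c(length(presences), length(pabs)))
  df <- data.frame(response = y)
  for (nm in predictors) df[[nm]] <- env$layers[[nm]][cells]
  df$bias <- bias[cells]
  keep <- stats::complete.cases(df) & !env$nodata_mask[cells]
  n_drop <- sum(!keep)
  if (n_drop > 0 && n_drop > 0.01 * nrow(df)) {
    warning(n_drop, " of ", nrow(df), " training rows dropped for missing ",
            "predictor values")
  }
  df <- df[keep, , drop = FALSE]
  cells <- cells[keep]
  n1 <- sum(df$response == 1)
  n0 <- sum(df$response == 0)
  if (n1 == 0L || n0 == 0L) {
    stop("training table needs at least one presence and one pseudo-absence")
  }
  df$weight <- ifelse(df$response == 1, 1, n1 / n0)
  rownames(df) <- NULL
  structure(df, predictors = predictors, cell_index = cells,
            class = c("training_table", "data.frame"))
}
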