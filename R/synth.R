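# Virtual environments and virtual species with known ground truth.
# Climate layers are Gaussian random fields (white noise smoothed with a
# Gaussian kernel, affinely rescaled to realistic Iberian-like ranges);
# land cover is a six-part composition from a softmax over latent fields
# whose climate-linked share is controlled by alpha_cov.

# evaluate code under a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic environment
#'
#' @param n_rows,n_cols Grid dimensions.
#' @param correlation_length Spatial autocorrelation scale in cells (the
#'   standard deviation of the Gaussian smoothing kernel). 0 gives white
#'   noise.
#' @param alpha_cov Share, in `[0, 1]`, of each land-cover latent field drawn
#'   from climate-linked structure rather than independent noise. Controls
#'   climate/land-cover collinearity and hence the joint deviance fraction.
#' @param seed Integer seed; generation is deterministic given it.
#' @param origin_lon,origin_lat,res_arcmin Georeference of the grid
#'   (defaults roughly Iberian: 5-arcminute cells with upper-left corner at
#'   10 W, 44 N).
#' @param lat_gradient Deterministic poleward cooling in degrees C per
#'   degree of latitude, added to both temperature layers (0 = none).
#'   Mid-latitude lapse along the meridian is around 0.8.
#' @return A `field_spec` list.
#' @export
field_spec <- function(n_rows = 50, n_cols = 50, correlation_length = 5,
                       alpha_cov = 0.5, seed = 1L,
                       origin_lon = -10, origin_lat = 44, res_arcmin = 5,
                       lat_gradient = 0) {
  stopifnot(n_rows >= 1, n_cols >= 1, correlation_length >= 0,
            alpha_cov >= 0, alpha_cov <= 1)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 correlation_length = correlation_length,
                 alpha_cov = alpha_cov, seed = as.integer(seed),
                 origin_lon = origin_lon, origin_lat = origin_lat,
                 res_arcmin = res_arcmin, lat_gradient = lat_gradient),
            class = "field_spec")
}

# white noise smoothed with a Gaussian kernel (separable, edge-normalized),
# standardized to zero mean / unit variance
gaussian_field <- function(n_rows, n_cols, correlation_length) {
  z <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  if (correlation_length > 0) {
    half <- max(1L, ceiling(3 * correlation_length))
    k <- stats::dnorm(seq(-half, half), sd = correlation_length)
    smooth1 <- function(m, kern) {
      # convolve each column with kern, renormalizing at the edges
      n <- nrow(m)
      out <- matrix(0, n, ncol(m))
      wsum <- numeric(n)
      for (off in seq_along(kern)) {
        d <- off - half - 1L
        src <- seq_len(n) + d
        ok <- src >= 1L & src <= n
        out[ok, ] <- out[ok, ] + kern[off] * m[src[ok], ]
        wsum[ok] <- wsum[ok] + kern[off]
      }
      out / wsum
    }
    z <- smooth1(z, k)
    z <- t(smooth1(t(z), k))
  }
  (z - mean(z)) / stats::sd(z)
}

# fixed linear maps from the four standardized climate fields to the six
# land-cover latents (chosen once; forests wet/cool, crops warm/wet,
# shrubs dry/seasonal, urban climate-neutral)
.lc_climate_map <- function() {
  m <- rbind(
    needleleaf = c(tmin = -0.8, tmax = -0.6, pan =  0.7, pcv = -0.3),
    broadleaf  = c(tmin = -0.2, tmax = -0.5, pan =  0.9, pcv = -0.4),
    grassland  = c(tmin =  0.3, tmax =  0.2, pan =  0.2, pcv =  0.1),
    shrub      = c(tmin =  0.6, tmax =  0.8, pan = -0.8, pcv =  0.6),
    crop       = c(tmin =  0.5, tmax =  0.3, pan =  0.4, pcv = -0.2),
    urban      = c(tmin =  0.0, tmax =  0.0, pan =  0.0, pcv =  0.0))
  m
}

#' Generate a synthetic environment
#'
#' Produces the four climate layers (`tmin`, `tmax`, `pan`, `pcv`) and the
#' six land-cover percentage layers as spatially autocorrelated random
#' fields. `tmax` is `tmin` plus a strictly positive offset field; `pan` is
#' non-negative; `pcv` lies in (0, 1); the land-cover layers are
#' `100 * softmax` over six latent fields, each a mixture
#' `alpha_cov * (linear map of climate) + (1 - alpha_cov) * independent
#' noise`. Deterministic given `spec$seed`. Default scales mirror
#' mid-latitude (Iberian) climatologies at 5-arcminute grain.
#'
#' @param spec A [field_spec()].
#' @return An `env_grid` with ten layers and an all-clear mask.
#' @export
generate_environment <- function(spec) {
  stopifnot(inherits(spec, "field_spec"))
  with_seed(spec$seed, {
    nr <- spec$n_rows; nc <- spec$n_cols; cl <- spec$correlation_length
    z_tmin <- gaussian_field(nr, nc, cl)
    z_off <- gaussian_field(nr, nc, cl)
    z_pan <- gaussian_field(nr, nc, cl)
    z_pcv <- gaussian_field(nr, nc, cl)

    tmin <- 1.6 + 2.9 * z_tmin
    if (spec$lat_gradient != 0) {
      lat <- spec$origin_lat - (seq_len(nr) - 0.5) * spec$res_arcmin / 60
      tmin <- tmin + spec$lat_gradient * (mean(lat) - lat)  # cooler northward
    }
    offset <- 27.9 + 2.0 * tanh(z_off)            # strictly positive
    tmax <- tmin + offset
    pan <- 674 * exp(0.45 * z_pan)                # >= 0, right-skewed
    pcv <- stats::plogis(stats::qlogis(0.43) + 0.6 * z_pcv)

    zclim <- list(tmin = z_tmin, tmax = (tmax - mean(tmax)) / stats::sd(tmax),
                  pan = z_pan, pcv = z_pcv)
    map <- .lc_climate_map()
    lc_names <- landcover_layers()
    latents <- vector("list", length(lc_names))
    names(latents) <- lc_names
    for (k in lc_names) {
      clim_part <- Reduce(`+`, Map(function(w, z) w * z,
                                   as.list(map[k, ]), zclim))
      noise <- gaussian_field(nr, nc, cl)
      latents[[k]] <- spec$alpha_cov * clim_part +
        (1 - spec$alpha_cov) * noise
    }
    lc <- softmax_layers(latents)
    layers <- c(list(tmin = tmin, tmax = tmax, pan = pan, pcv = pcv), lc)
    env_grid(layers, spec$origin_lon, spec$origin_lat, spec$res_arcmin)
  })
}

# 100 * softmax across a named list of latent matrices
softmax_layers <- function(latents) {
  mx <- Reduce(pmax, latents)
  ex <- lapply(latents, function(m) exp(m - mx))
  tot <- Reduce(`+`, ex)
  lapply(ex, function(m) 100 * m / tot)
}

#' Define a virtual species
#'
#' A known logistic suitability function used as ground truth:
#' `logistic(intercept + sum(beta * z) + sum(beta_sq * z^2))` where `z` are
#' layers standardized over unmasked cells.
#'
#' @param beta Named numeric vector of linear coefficients (names are layer
#'   names).
#' @param beta_sq Named numeric vector of quadratic coefficients.
#' @param intercept Intercept on the logit scale.
#' @param detection_gamma Non-negative exponent controlling how strongly
#'   occurrence sampling follows the bias (effort) surface; 0 = unbiased.
#' @return A `virtual_species` object.
#' @export
virtual_species <- function(beta, beta_sq = numeric(0), intercept = 0,
                            detection_gamma = 0) {
  stopifnot(detection_gamma >= 0)
  if (length(beta) && is.null(names(beta))) stop("beta must be named")
  if (length(beta_sq) && is.null(names(beta_sq))) {
    stop("beta_sq must be named")
  }
  structure(list(beta = beta, beta_sq = beta_sq,
                 intercept = intercept,
                 detection_gamma = detection_gamma),
            class = "virtual_species")
}

# standardize a layer over unmasked cells
std_layer <- function(grid, name) {
  m <- get_layer(grid, name)
  v <- m[!grid$nodata_mask]
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) s <- 1
  (m - mean(v)) / s
}

#' True suitability of a virtual species
#'
#' @param env An `env_grid` containing every layer the species references.
#' @param sp A [virtual_species()].
#' @return A `suitability_map` (values in (0, 1); masked cells `NA`).
#' @export
true_suitability <- function(env, sp) {
  stopifnot(inherits(sp, "virtual_species"))
  all_nm <- union(names(sp$beta), names(sp$beta_sq))
  missing <- setdiff(all_nm, names(env$layers))
  if (length(missing)) {
    stop("unknown layer name(s) in species coefficients: ",
         paste(missing, collapse = ", "))
  }
  eta <- matrix(sp$intercept, env$n_rows, env$n_cols)
  for (nm in names(sp$beta)) {
    eta <- eta + sp$beta[[nm]] * std_layer(env, nm)
  }
  for (nm in names(sp$beta_sq)) {
    eta <- eta + sp$beta_sq[[nm]] * std_layer(env, nm)^2
  }
  v <- stats::plogis(eta)
  v[env$nodata_mask] <- NA_real_
  suitability_map(v, env, provenance = list(kind = "true_suitability"))
}

#' Sample biased occurrence records from a suitability surface
#'
#' Each unmasked cell is recorded as a presence independently with
#' probability proportional to `suitability * bias^detection_gamma`, scaled
#' so the expected number of presences is about `n_target` (per-cell
#' probabilities are capped at 1). Returns cell-center points.
#'
#' @param suit A `suitability_map`.
#' @param bias Numeric matrix in `[0, 1]` (the effort surface), matching the
#'   grid shape.
#' @param n_target Target expected number of presence cells.
#' @param sp The [virtual_species()] supplying `detection_gamma`.
#' @param seed Integer seed.
#' @param species_id Label stored on the returned set.
#' @return An `occurrence_set`.
#' @export
sample_occurrences <- function(suit, bias, n_target, sp, seed,
                               species_id = "virtual") {
  stopifnot(inherits(suit, "suitability_map"))
  grid <- suit$grid
  if (is.null(dim(bias))) stop("bias must be a matrix")
  if (min(bias, na.rm = TRUE) < 0 || max(bias, na.rm = TRUE) > 1) {
    stop("bias layer must lie in [0, 1]")
  }
  ok <- !grid$nodata_mask & !is.na(suit$values)
  n_avail <- sum(ok)
  if (n_target > n_avail) {
    stop("n_target (", n_target, ") exceeds unmasked cells (", n_avail, ")")
  }
  w <- suit$values
  g <- sp$detection_gamma
  if (g > 0) w <- w * bias^g
  w[!ok] <- 0
  tot <- sum(w)
  if (tot == 0) {
    return(occurrence_set(species_id, numeric(0), numeric(0), "synthetic"))
  }
  p <- pmin(1, w * n_target / tot)
  hit <- with_seed(seed, matrix(stats::runif(length(p)) < p,
                                grid$n_rows, grid$n_cols))
  idx <- which(hit & ok, arr.ind = TRUE)
  lons <- cell_lons(grid)[idx[, 2L]]
  lats <- cell_lats(grid)[idx[, 1L]]
  occurrence_set(species_id, lons, lats, "synthetic")
}

#' Build a perturbed future layer set
#'
#' Applies named perturbations to a current environment: additive shifts
#' for temperatures (`tmin`, `tmax`), multiplicative factors for
#' precipitation layers (`pan`, `pcv`; `pcv` is clipped back into (0, 1)
#' with a warning if pushed outside), and additive shifts to land-cover
#' latents (log-proportions) before re-applying the softmax, so the
#' percentage composition still sums to 100. Defaults emulate a
#' mid-century, intermediate-emissions trajectory: about +2 degrees C,
#' 12% less annual precipitation, and cropland expansion at the expense of
#' open natural habitats.
#'
#' @param env Current `env_grid`.
#' @param delta Named list of perturbations; names must be existing layers.
#' @param name Scenario label.
#' @param gcm_label Circulation-model label carried through for bookkeeping.
#' @return A `scenario_spec` with `layer_source` aligned to `env`.
#' @export
generate_future <- function(env,
                            delta = list(tmin = 2.2, tmax = 2.2, pan = 0.88,
                                         crop = 0.3, grassland = -0.2,
                                         shrub = -0.2),
                            name = "SSP2-4.5", gcm_label = "IPSL") {
  unknown <- setdiff(names(delta), names(env$layers))
  if (length(unknown)) {
    stop("perturbation names not in environment: ",
         paste(unknown, collapse = ", "))
  }
  out <- env
  for (nm in intersect(names(delta), c("tmin", "tmax"))) {
    out$layers[[nm]] <- env$layers[[nm]] + delta[[nm]]
  }
  for (nm in intersect(names(delta), c("pan", "pcv"))) {
    out$layers[[nm]] <- env$layers[[nm]] * delta[[nm]]
  }
  if ("pcv" %in% names(delta)) {
    v <- out$layers[["pcv"]]
    bad <- !env$nodata_mask & (v <= 0 | v >= 1)
    if (any(bad)) {
      warning(sum(bad), " cells pushed outside (0,1) for pcv; clipped")
      out$layers[["pcv"]] <- pmin(pmax(v, 1e-6), 1 - 1e-6)
    }
  }
  lc_delta <- intersect(names(delta), landcover_layers())
  if (length(lc_delta)) {
    eps <- 1e-9
    latents <- lapply(landcover_layers(), function(nm) {
      log(pmax(env$layers[[nm]], eps) / 100)
    })
    names(latents) <- landcover_layers()
    for (nm in lc_delta) latents[[nm]] <- latents[[nm]] + delta[[nm]]
    lc <- softmax_layers(latents)
    for (nm in landcover_layers()) {
      lc[[nm]][env$nodata_mask] <- NA_real_
      out$layers[[nm]] <- lc[[nm]]
    }
  }
  scenario_spec(name, gcm_label, out)
}

#' Scenario container
#'
#' @param name Scenario label (e.g. `"SSP1-2.6"`).
#' @param gcm_label Circulation-model label (e.g. `"IPSL"`).
#' @param layer_source An `env_grid` holding the future-period layers.
#' @return A `scenario_spec`.
#' @export
scenario_spec <- function(name, gcm_label, layer_source) {
  stopifnot(inherits(layer_source, "env_grid"))
  structure(list(name = name, gcm_label = gcm_label,
                 layer_source = layer_source),
            class = "scenario_spec")
}

#' Simulate an observation-effort (bias) surface
#'
#' Draws `n_hubs` "observer hub" points uniformly over unmasked cells and
#' returns their Gaussian kernel density rescaled to `[0, 1]` — the same
#' kernel-density construction used for real effort surfaces.
#'
#' @param env An `env_grid`.
#' @param n_hubs Number of hub points.
#' @param bandwidth_cells Kernel bandwidth in cells.
#' @param seed Integer seed.
#' @return Numeric matrix in `[0, 1]` matching the grid.
#' @export
simulate_bias <- function(env, n_hubs = 15, bandwidth_cells = 8, seed = 1L) {
  ok <- which(!env$nodata_mask, arr.ind = TRUE)
  stopifnot(nrow(ok) >= 1)
  pick <- with_seed(seed, ok[sample.int(nrow(ok), min(n_hubs, nrow(ok))), ,
                             drop = FALSE])
  lons <- cell_lons(env)[pick[, 2L]]
  lats <- cell_lats(env)[pick[, 1L]]
  kernel_bias(cbind(lons, lats), env, bandwidth_cells = bandwidth_cells)
}
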