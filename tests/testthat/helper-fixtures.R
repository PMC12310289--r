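# Shared fixtures, memoized for the whole test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# a small simulated world: climate-driven species on a 40x40 grid
small_world <- function() {
  memo("small_world", {
    spec <- field_spec(n_rows = 40, n_cols = 40, correlation_length = 5,
                       alpha_cov = 0.5, seed = 101, lat_gradient = 1)
    env <- generate_environment(spec)
    bias <- simulate_bias(env, n_hubs = 12, bandwidth_cells = 8, seed = 102)
    biomes <- synthetic_biomes(env)
    sp <- virtual_species(beta = c(tmax = -1.5, pan = 0.6, broadleaf = 0.5),
                          beta_sq = c(tmax = -0.8), intercept = -0.5,
                          detection_gamma = 0.5)
    suit <- true_suitability(env, sp)
    occ <- sample_occurrences(suit, bias, 350, sp, seed = 103)
    presences <- grid_presences(occ, env)
    pabs <- draw_pseudoabsences(presences, biomes, seed = 104,
                                mask = env$nodata_mask)
    table <- assemble_training(presences, pabs, env, bias)
    list(spec = spec, env = env, bias = bias, biomes = biomes, sp = sp,
         suit = suit, occ = occ, presences = presences, pabs = pabs,
         table = table)
  })
}

small_ensemble <- function() {
  memo("small_ensemble", {
    w <- small_world()
    fit_ensemble(w$table, seed = 105, species_id = "fixture",
                 n_trees = 100)
  })
}

# training table built directly from simulated logistic data (no grid):
# X ~ N(0,1), eta = intercept + X %*% beta, y ~ Bernoulli(plogis(eta))
sim_logistic_table <- function(n, beta, intercept = 0, seed = 1) {
  p <- length(beta)
  nms <- names(beta)
  withr_seed <- function(code) with_seed_test(seed, code)
  X <- withr_seed(matrix(stats::rnorm(n * p), n, p))
  eta <- intercept + as.vector(X %*% beta)
  y <- with_seed_test(seed + 1L, stats::rbinom(n, 1, stats::plogis(eta)))
  df <- as.data.frame(X)
  names(df) <- nms
  df$response <- y
  df$bias <- with_seed_test(seed + 2L, stats::runif(n))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  stopifnot(n1 > 0, n0 > 0)
  df$weight <- ifelse(y == 1, 1, n1 / n0)
  structure(df, predictors = nms, class = c("training_table", "data.frame"))
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# constant-layer grid helper
flat_grid <- function(n_rows = 10, n_cols = 10, value = 1,
                      origin_lon = 0, origin_lat = 45, res_arcmin = 5,
                      name = "x") {
  env_grid(stats::setNames(list(matrix(value, n_rows, n_cols)), name),
           origin_lon, origin_lat, res_arcmin)
}
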