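# Virtual environments, species, occurrence sampling and future scenarios.

test_that("generated environments satisfy their structural contracts", {
  env <- generate_environment(field_spec(n_rows = 30, n_cols = 30,
                                         seed = 21))
  expect_setequal(names(env$layers),
                  c(climate_layers(), landcover_layers()))
  expect_true(all(env$layers$tmax > env$layers$tmin))
  expect_true(all(env$layers$pan >= 0))
  expect_true(all(env$layers$pcv > 0 & env$layers$pcv < 1))
  lc_sum <- Reduce(`+`, env$layers[landcover_layers()])
  expect_equal(max(abs(lc_sum - 100)), 0, tolerance = 1e-9)
  for (nm in landcover_layers()) {
    expect_true(all(env$layers[[nm]] >= 0 & env$layers[[nm]] <= 100))
  }
  # determinism
  env2 <- generate_environment(field_spec(n_rows = 30, n_cols = 30,
                                          seed = 21))
  expect_identical(env$layers, env2$layers)
  env3 <- generate_environment(field_spec(n_rows = 30, n_cols = 30,
                                          seed = 22))
  expect_false(identical(env$layers$tmin, env3$layers$tmin))
})

test_that("alpha_cov = 0 decouples land cover from climate", {
  env <- generate_environment(field_spec(n_rows = 200, n_cols = 200,
                                         correlation_length = 5,
                                         alpha_cov = 0, seed = 31))
  # latents recovered up to an additive field via log proportions
  cors <- outer(climate_layers(), landcover_layers(),
                Vectorize(function(cl, lc) {
                  abs(stats::cor(as.vector(env$layers[[cl]]),
                                 as.vector(log(pmax(env$layers[[lc]], 1e-9)))))
                }))
  expect_lt(mean(cors), 0.1)
})

test_that("alpha_cov = 1 couples land cover tightly to climate", {
  env <- generate_environment(field_spec(n_rows = 100, n_cols = 100,
                                         correlation_length = 5,
                                         alpha_cov = 1, seed = 32))
  cors <- vapply(c("needleleaf", "shrub"), function(lc) {
    max(abs(stats::cor(as.vector(env$layers$tmax),
                       as.vector(log(pmax(env$layers[[lc]], 1e-9))))))
  }, numeric(1))
  expect_true(all(cors > 0.5))
})

test_that("true suitability follows the logistic ground-truth model", {
  env <- generate_environment(field_spec(n_rows = 25, n_cols = 25,
                                         seed = 41))
  # all coefficients zero -> 0.5 everywhere
  sp0 <- virtual_species(beta = c(tmax = 0), intercept = 0)
  expect_true(all(abs(true_suitability(env, sp0)$values - 0.5) < 1e-12))

  # large intercept -> suitability approaches 1
  sp_hi <- virtual_species(beta = c(tmax = 0), intercept = 20)
  expect_true(all(true_suitability(env, sp_hi)$values > 0.999))

  # single positive linear coefficient -> strictly monotone in that layer
  sp1 <- virtual_species(beta = c(pan = 1), intercept = 0)
  s <- true_suitability(env, sp1)$values
  ord <- order(as.vector(env$layers$pan))
  expect_true(all(diff(s[ord]) >= 0))

  expect_error(true_suitability(env, virtual_species(beta = c(nope = 1))),
               "unknown layer")
})

test_that("occurrence sampling honours bias, determinism and edge cases", {
  n_r <- 80; n_c <- 100
  g <- flat_grid(n_r, n_c, value = 0)
  suit <- suitability_map(matrix(0.5, n_r, n_c), g)
  bias <- matrix(rep(c(0.9, 0.1), each = n_r * n_c / 2), n_r, n_c)

  # detection_gamma = 0: sampling ignores bias
  sp0 <- virtual_species(beta = c(x = 0), detection_gamma = 0)
  occ <- sample_occurrences(suit, bias, 2500, sp0, seed = 51)
  cells <- grid_presences(occ, g)
  col_of <- (cells - 1) %/% n_r + 1
  n_hi <- sum(col_of <= n_c / 2); n_lo <- sum(col_of > n_c / 2)
  pt <- stats::prop.test(c(n_hi, n_lo),
                         c(n_r * n_c / 2, n_r * n_c / 2))
  expect_gt(pt$p.value, 0.001)

  # detection_gamma > 0: heavy concentration in the high-bias half
  sp2 <- virtual_species(beta = c(x = 0), detection_gamma = 2)
  occ2 <- sample_occurrences(suit, bias, 1000, sp2, seed = 52)
  col2 <- (grid_presences(occ2, g) - 1) %/% n_r + 1
  expect_gt(mean(col2 <= n_c / 2), 0.9)

  # zero suitability -> empty set; determinism; capacity guard
  suit0 <- suitability_map(matrix(0, n_r, n_c), g)
  expect_identical(nrow(sample_occurrences(suit0, bias, 10, sp0,
                                           seed = 53)$points), 0L)
  occ_a <- sample_occurrences(suit, bias, 500, sp0, seed = 54)
  occ_b <- sample_occurrences(suit, bias, 500, sp0, seed = 54)
  expect_identical(occ_a$points, occ_b$points)
  expect_error(sample_occurrences(suit, bias, n_r * n_c + 1, sp0, seed = 1),
               "exceeds")
})

test_that("future scenarios perturb layers by the documented rules", {
  env <- generate_environment(field_spec(n_rows = 20, n_cols = 20,
                                         seed = 61))
  # zero perturbation is the identity
  same <- generate_future(env, delta = list())
  expect_identical(same$layer_source$layers, env$layers)

  # additive temperature, multiplicative precipitation
  fut <- generate_future(env, delta = list(tmin = 2, tmax = 2, pan = 0.9))
  expect_equal(fut$layer_source$layers$tmin - env$layers$tmin,
               matrix(2, 20, 20), tolerance = 1e-12)
  expect_equal(fut$layer_source$layers$pan / env$layers$pan,
               matrix(0.9, 20, 20), tolerance = 1e-12)

  # land-cover latent shift: crop increases, composition stays closed
  fut2 <- generate_future(env, delta = list(crop = 0.5))
  expect_gt(mean(fut2$layer_source$layers$crop), mean(env$layers$crop))
  lc_sum <- Reduce(`+`, fut2$layer_source$layers[landcover_layers()])
  expect_equal(max(abs(lc_sum - 100)), 0, tolerance = 1e-9)
  # softmax oracle: shifted log-proportions renormalized
  k <- landcover_layers()
  lat <- lapply(k, function(nm) log(pmax(env$layers[[nm]], 1e-9) / 100))
  names(lat) <- k
  lat$crop <- lat$crop + 0.5
  tot <- Reduce(`+`, lapply(lat, exp))
  expect_equal(fut2$layer_source$layers$crop, 100 * exp(lat$crop) / tot,
               tolerance = 1e-6)

  expect_error(generate_future(env, delta = list(bogus = 1)), "bogus")
})

test_that("a strong linear species is recoverable from gridded sampling", {
  # signs of linear effects recovered through the full data path
  env <- generate_environment(field_spec(n_rows = 80, n_cols = 80,
                                         alpha_cov = 0.3, seed = 71))
  sp <- virtual_species(beta = c(tmax = -1.2, pan = 0.8, broadleaf = 0.6),
                        intercept = -1, detection_gamma = 0)
  suit <- true_suitability(env, sp)
  bias <- matrix(0.5, 80, 80)
  occ <- sample_occurrences(suit, bias, 1200, sp, seed = 72)
  pres <- grid_presences(occ, env)
  pabs <- draw_pseudoabsences(pres, synthetic_biomes(env), seed = 73)
  tab <- assemble_training(pres, pabs, env, bias)
  comp <- fit_glm(tab)
  cf <- stats::coef(comp$fit)
  expect_lt(cf[["z.tmax"]], 0)
  expect_gt(cf[["z.pan"]], 0)
  expect_gt(cf[["z.broadleaf"]], 0)
})
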