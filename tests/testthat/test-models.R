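# Component models and the ensemble.

test_that("GLM recovers known logistic coefficients within 3 SE", {
  beta <- c(a = 0.8, b = -1.2, c = 0.4)
  tab <- sim_logistic_table(20000, beta, intercept = -0.3, seed = 201)
  comp <- fit_glm(tab)
  sm <- summary(comp$fit)$coefficients
  for (nm in names(beta)) {
    zn <- paste0("z.", nm)
    # truth on the standardized scale: beta * sd(x) with x ~ N(0,1)
    truth <- beta[[nm]] * comp$scale[[nm]]
    expect_lt(abs(sm[zn, "Estimate"] - truth), 3 * sm[zn, "Std. Error"])
    # quadratic terms are genuinely absent
    z2 <- paste0("z2.", nm)
    expect_lt(abs(sm[z2, "Estimate"]), 3 * sm[z2, "Std. Error"])
  }
})

test_that("GLM rejects degenerate input and honours the weighting identity", {
  tab <- sim_logistic_table(500, c(a = 1), seed = 202)
  tab_const <- tab
  tab_const$response <- 1
  tab_const$weight <- 1
  expect_error(fit_glm(tab_const), "balance|constant")

  # duplicated rows with halved weights give identical coefficients
  comp1 <- fit_glm(tab)
  tab2 <- rbind(tab, tab)
  tab2$weight <- tab2$weight / 2
  attr(tab2, "predictors") <- attr(tab, "predictors")
  class(tab2) <- class(tab)
  comp2 <- fit_glm(tab2)
  expect_equal(stats::coef(comp2$fit), stats::coef(comp1$fit),
               tolerance = 1e-6)
})

test_that("stepwise AIC drops noise terms, keeps bias, never raises AIC", {
  # under AIC each true-zero term survives with asymptotic probability
  # P(chi2_1 > 2) ~ 0.157, so expect each noise term absent ~84% of the
  # time while the signal term is always retained
  drop_lin <- drop_sq <- 0L
  for (r in 1:20) {
    tab <- sim_logistic_table(3000, c(sig = 1, noise = 0), seed = 210 + r)
    full <- fit_glm(tab)
    red <- stepwise_aic(full, tab)
    kept <- attr(stats::terms(stats::formula(red$fit)), "term.labels")
    expect_true("z.bias" %in% kept)
    expect_true("z.sig" %in% kept)
    expect_lte(stats::AIC(red$fit), stats::AIC(full$fit) + 1e-9)
    if (!"z.noise" %in% kept) drop_lin <- drop_lin + 1L
    if (!"z2.noise" %in% kept) drop_sq <- drop_sq + 1L
  }
  expect_gte(drop_lin, 13L)
  expect_gte(drop_sq, 13L)

  # an already-minimal model is a fixed point
  tab <- sim_logistic_table(2000, c(sig = 1.5), seed = 231)
  red1 <- stepwise_aic(fit_glm(tab), tab)
  red2 <- stepwise_aic(red1, tab)
  expect_equal(stats::formula(red2$fit), stats::formula(red1$fit))
})

test_that("random forest separates, is deterministic and respects the null", {
  # perfectly separable table -> training AUC 1
  n <- 200
  x <- c(stats::rnorm(n / 2, -3), stats::rnorm(n / 2, 3))
  tab <- data.frame(a = x, response = rep(c(0, 1), each = n / 2),
                    bias = 0.5, weight = 1)
  attr(tab, "predictors") <- "a"
  class(tab) <- c("training_table", "data.frame")
  comp <- fit_rf(tab, seed = 240, n_trees = 100)
  p <- predict_component(comp, tab)
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(auc(p[tab$response == 1], p[tab$response == 0]), 1.0)

  # same seed -> identical predictions; different seed -> different forest
  comp_b <- fit_rf(tab, seed = 240, n_trees = 100)
  expect_identical(predict_component(comp_b, tab), p)

  # label permutation: held-out AUC centred on 0.5
  aucs <- numeric(20)
  for (r in 1:20) {
    tabr <- sim_logistic_table(600, c(a = 1.5, b = -1), seed = 250 + r)
    tabr$response <- with_seed_test(300 + r, sample(tabr$response))
    train <- tabr[1:300, ]; test <- tabr[301:600, ]
    n1 <- sum(train$response == 1)
    train$weight <- ifelse(train$response == 1, 1,
                           n1 / sum(train$response == 0))
    attr(train, "predictors") <- attr(tabr, "predictors")
    class(train) <- class(tabr)
    f <- fit_rf(train, seed = 260 + r, n_trees = 60)
    pp <- predict_component(f, test)
    aucs[r] <- auc(pp[test$response == 1], pp[test$response == 0])
  }
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("MaxEnt-like component: penalty limit, sparsity, affine invariance", {
  tab <- sim_logistic_table(1500, c(a = 1.5, b = 0, c = 0), seed = 270)
  comp <- fit_maxentlike(tab, seed = 271)
  p <- predict_component(comp, tab)
  expect_true(all(p >= 0 & p <= 1))

  # infinite-penalty limit: all penalized coefficients zero, prediction =
  # weighted prevalence 0.5 (bias unpenalized but near-orthogonal here)
  x <- climland:::maxent_features(tab, attr(tab, "predictors"),
                                  comp$center, comp$scale)
  big <- glmnet::glmnet(x, tab$response, family = "binomial",
                        weights = tab$weight, alpha = 1,
                        lambda = 1e6, standardize = FALSE,
                        penalty.factor = rep(1, ncol(x)))
  expect_true(all(abs(as.numeric(big$beta)) < 1e-8))
  expect_equal(mean(stats::predict(big, newx = x, type = "response")), 0.5,
               tolerance = 1e-6)

  # sparse truth: the CV-deviance-minimal penalty shrinks true-zero
  # features to (near) zero while the signal feature stays strong
  zero_hits <- 0L
  noise_mag <- sig_mag <- numeric(10)
  for (r in 1:10) {
    tr <- sim_logistic_table(1200, c(a = 1.5, b = 0, c = 0),
                             seed = 280 + r)
    f <- fit_maxentlike(tr, seed = 290 + r)
    cf <- as.matrix(stats::predict(f$fit, s = f$lambda,
                                   type = "coefficients"))
    zero_hits <- zero_hits +
      (abs(cf["z.b", 1]) < 1e-8) + (abs(cf["z.c", 1]) < 1e-8)
    noise_mag[r] <- max(abs(cf[c("z.b", "z.c"), 1]))
    sig_mag[r] <- abs(cf["z.a", 1])
  }
  expect_gte(zero_hits, 10L)          # half the 20 noise coefficients exact 0
  expect_lt(mean(noise_mag), 0.08)    # the rest heavily shrunk
  expect_gt(min(sig_mag), 0.5)

  # affine rescaling of a predictor leaves predictions invariant
  tab2 <- tab
  tab2$a <- 10 * tab2$a + 7
  attr(tab2, "predictors") <- attr(tab, "predictors")
  class(tab2) <- class(tab)
  comp2 <- fit_maxentlike(tab2, seed = 271)
  expect_equal(predict_component(comp2, tab2), p, tolerance = 1e-6)
})

test_that("ensemble averaging is exact, order-invariant and range-safe", {
  w <- small_world()
  ens <- small_ensemble()
  env <- w$env

  sm <- predict_ensemble(ens, env)
  expect_true(all(sm$values >= 0 & sm$values <= 1, na.rm = TRUE))

  # per-cell brute-force mean of component predictions
  ok <- !env$nodata_mask
  newdata <- data.frame(row.names = seq_len(sum(ok)))
  for (nm in ens$predictors) newdata[[nm]] <- env$layers[[nm]][ok]
  newdata$bias <- ens$bias_max
  comp_preds <- sapply(ens$components, predict_component,
                       newdata = newdata)
  expect_equal(sm$values[ok], rowMeans(comp_preds), tolerance = 1e-12)

  # permutation invariance in component order
  ens_rev <- ens
  ens_rev$components <- rev(ens$components)
  expect_equal(predict_ensemble(ens_rev, env)$values, sm$values,
               tolerance = 1e-15)

  # two components predicting p1 and p2 average to (p1 + p2) / 2
  ens2 <- ens
  ens2$components <- ens$components[c("glm", "rf")]
  p_glm <- predict_component(ens$components$glm, newdata)
  p_rf <- predict_component(ens$components$rf, newdata)
  expect_equal(predict_ensemble(ens2, env)$values[ok],
               (p_glm + p_rf) / 2, tolerance = 1e-12)

  # missing layer is reported by name
  env_missing <- env
  env_missing$layers$pan <- NULL
  expect_error(predict_ensemble(ens, env_missing), "pan")
})

test_that("all components rank cells concordantly with a strong truth", {
  env <- generate_environment(field_spec(n_rows = 60, n_cols = 60,
                                         seed = 301))
  sp <- virtual_species(beta = c(tmax = -2), intercept = 0,
                        detection_gamma = 0)
  suit <- true_suitability(env, sp)
  bias <- matrix(0.5, 60, 60)
  occ <- sample_occurrences(suit, bias, 800, sp, seed = 302)
  pres <- grid_presences(occ, env)
  pabs <- draw_pseudoabsences(pres, synthetic_biomes(env), seed = 303)
  # single-predictor model, matching the single-driver truth
  tab <- assemble_training(pres, pabs, env, bias, predictors = "tmax")
  ens <- fit_ensemble(tab, seed = 304, n_trees = 150)
  for (k in names(ens$components)) {
    e1 <- ens
    e1$components <- ens$components[k]
    p <- predict_ensemble(e1, env)$values
    rho <- stats::cor(as.vector(p), as.vector(suit$values),
                      method = "spearman")
    expect_gte(rho, 0.9)
  }
})
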