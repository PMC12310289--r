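# The three component niche models (weighted logistic GLM with stepwise-AIC
# reduction, probability random forest, L1-penalized "MaxEnt-like" logistic
# on derived features) and their unweighted-average ensemble.

validate_training <- function(table) {
  stopifnot(inherits(table, "training_table"))
  preds <- attr(table, "predictors")
  if (is.null(preds) || !all(preds %in% names(table))) {
    stop("training table lacks its predictor columns")
  }
  if (!all(c("response", "weight", "bias") %in% names(table))) {
    stop("training table needs response, weight and bias columns")
  }
  if (anyNA(table[c("response", "weight", "bias", preds)])) {
    stop("training table contains missing values")
  }
  w1 <- sum(table$weight[table$response == 1])
  w0 <- sum(table$weight[table$response == 0])
  if (w1 == 0 || w0 == 0 || abs(w1 - w0) > 1e-8 * max(w1, w0)) {
    stop("presence and pseudo-absence weights must balance (0.5 prevalence)")
  }
  invisible(preds)
}

# suppress expected warnings from weighted binomial fits: non-integer
# successes (case weights) and saturated fitted probabilities (flexible
# quadratic surfaces); genuine separation still surfaces via the
# convergence check. Anything else propagates.
quiet_binomial <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("non-integer|numerically 0 or 1", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}

# standardized model frame with z.<nm> (linear) and z2.<nm> (quadratic)
# columns for each predictor, plus z.bias
glm_frame <- function(table, predictors, center = NULL, scale = NULL) {
  vars <- c(predictors, "bias")
  if (is.null(center)) {
    # weighted population moments: invariant under duplicating rows with
    # proportionally split weights
    w <- if ("weight" %in% names(table)) table$weight else
      rep(1, nrow(table))
    wm <- function(x) sum(w * x) / sum(w)
    center <- vapply(table[vars], wm, numeric(1))
    scale <- sqrt(vapply(seq_along(vars), function(k) {
      wm((table[[vars[k]]] - center[[k]])^2)
    }, numeric(1)))
    names(scale) <- vars
    scale[!is.finite(scale) | scale == 0] <- 1
  }
  fr <- data.frame(row.names = seq_len(nrow(table)))
  if ("response" %in% names(table)) fr$response <- table$response
  if ("weight" %in% names(table)) fr$weight <- table$weight
  for (nm in predictors) {
    z <- (table[[nm]] - center[[nm]]) / scale[[nm]]
    fr[[paste0("z.", nm)]] <- z
    fr[[paste0("z2.", nm)]] <- z^2
  }
  fr$z.bias <- (table$bias - center[["bias"]]) / scale[["bias"]]
  attr(fr, "center") <- center
  attr(fr, "scale") <- scale
  fr
}

glm_terms <- function(predictors) {
  if (!length(predictors)) return("z.bias")
  c(rbind(paste0("z.", predictors), paste0("z2.", predictors)), "z.bias")
}

#' Fit the weighted logistic-regression component
#'
#' Weighted binomial GLM (logit link) on linear and quadratic terms of every
#' predictor plus the linear sampling-bias covariate. Predictors are
#' standardized internally; each linear and quadratic term is a separate
#' model term so stepwise selection can drop them independently.
#'
#' @param table A `training_table`.
#' @param seed Unused by the deterministic fit; kept for interface symmetry.
#' @param predictors Predictor subset (defaults to the table's full set).
#' @return A `climland_component` of kind `"glm"`.
#' @export
fit_glm <- function(table, seed = 1L, predictors = NULL) {
  validate_training(table)
  if (is.null(predictors)) predictors <- attr(table, "predictors")
  if (length(unique(table$response)) < 2L) {
    stop("response is constant; cannot fit a presence/absence model")
  }
  fr <- glm_frame(table, predictors)
  fml <- stats::as.formula(
    paste("response ~", paste(glm_terms(predictors), collapse = " + ")),
    env = baseenv())
  # the call carries the frame and weights as literals so that step()'s
  # internal update()/add1()/drop1() re-evaluations are self-contained
  fit <- quiet_binomial(do.call(stats::glm, list(
    formula = fml, family = stats::binomial(), data = fr,
    weights = fr$weight, control = stats::glm.control(maxit = 50))))
  if (!fit$converged) {
    stop("GLM did not converge after 50 IRLS iterations; deviance = ",
         format(fit$deviance))
  }
  structure(list(kind = "glm", fit = fit, predictors = predictors,
                 center = attr(fr, "center"), scale = attr(fr, "scale")),
            class = "climland_component")
}

#' Reduce a GLM component by stepwise AIC
#'
#' Backward-forward stepwise selection over the linear and quadratic terms.
#' The sampling-bias covariate is the scope's lower bound and is never
#' dropped (it is a control variable, not a candidate).
#'
#' @param comp A `climland_component` of kind `"glm"` (the full model).
#' @param table The `training_table` it was fitted on (unused beyond
#'   interface symmetry; the fit carries its own frame).
#' @return The reduced `climland_component`.
#' @export
stepwise_aic <- function(comp, table = NULL) {
  stopifnot(inherits(comp, "climland_component"), comp$kind == "glm")
  fit <- comp$fit
  upper <- stats::formula(fit)
  lower <- stats::as.formula("response ~ z.bias", env = baseenv())
  red <- quiet_binomial(stats::step(
    fit, scope = list(lower = lower, upper = upper),
    direction = "both", trace = 0))
  comp$fit <- red
  comp
}

#' Fit the random-forest component
#'
#' Probability forest: regression trees on the 0/1 response, each grown on a
#' weight-proportional bootstrap sample with `mtry` features tried per
#' split. Predictions are the across-tree mean of leaf means, hence in
#' `[0, 1]`.
#'
#' @param table A `training_table`.
#' @param seed Integer seed (forest growth is deterministic given it).
#' @param n_trees Number of trees (default 500).
#' @param mtry Features tried per split; default `floor(sqrt(p))`.
#' @param min_node Minimum samples per leaf (default 5).
#' @return A `climland_component` of kind `"rf"`.
#' @export
fit_rf <- function(table, seed = 1L, n_trees = 500, mtry = NULL,
                   min_node = 5) {
  preds <- validate_training(table)
  feats <- c(preds, "bias")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(length(feats))))
  X <- as.matrix(table[feats])
  forest <- .rf_grow(X, as.numeric(table$response),
                     as.numeric(table$weight),
                     as.integer(n_trees), as.integer(mtry),
                     as.integer(min_node), as.integer(seed))
  structure(list(kind = "rf", forest = forest, features = feats,
                 predictors = preds),
            class = "climland_component")
}

# standardized feature matrix for the MaxEnt-like component: linear,
# quadratic and pairwise-product terms plus the (unpenalized) bias
maxent_features <- function(table, predictors, center, scale) {
  fr <- glm_frame(table, predictors, center, scale)
  z <- as.matrix(fr[paste0("z.", predictors)])
  cols <- list()
  for (nm in predictors) {
    cols[[paste0("z.", nm)]] <- fr[[paste0("z.", nm)]]
    cols[[paste0("z2.", nm)]] <- fr[[paste0("z2.", nm)]]
  }
  if (length(predictors) >= 2L) {
    for (a in seq_len(length(predictors) - 1L)) {
      for (b in seq.int(a + 1L, length(predictors))) {
        cols[[paste0("x.", predictors[a], ".", predictors[b])]] <-
          z[, a] * z[, b]
      }
    }
  }
  cols[["z.bias"]] <- fr$z.bias
  do.call(cbind, cols)
}

#' Fit the MaxEnt-like component
#'
#' L1-penalized logistic regression (glmnet) on linear, quadratic and
#' pairwise-product features of the standardized predictors — the
#' penalized-likelihood formulation of MaxEnt. The penalty is chosen by
#' 5-fold cross-validated binomial deviance; the sampling-bias covariate is
#' left unpenalized so it always stays in the model.
#'
#' @param table A `training_table`.
#' @param seed Integer seed (fixes the cross-validation folds).
#' @param nfolds Cross-validation folds (default 5).
#' @return A `climland_component` of kind `"maxent"`.
#' @export
fit_maxentlike <- function(table, seed = 1L, nfolds = 5) {
  preds <- validate_training(table)
  fr0 <- glm_frame(table, preds)
  center <- attr(fr0, "center"); scale <- attr(fr0, "scale")
  x <- maxent_features(table, preds, center, scale)
  pf <- rep(1, ncol(x))
  pf[colnames(x) == "z.bias"] <- 0
  foldid <- with_seed(seed, sample(rep_len(seq_len(nfolds), nrow(x))))
  cv <- quiet_binomial(glmnet::cv.glmnet(
    x, table$response, family = "binomial", weights = table$weight,
    alpha = 1, foldid = foldid, penalty.factor = pf, standardize = FALSE))
  structure(list(kind = "maxent", fit = cv$glmnet.fit,
                 lambda = cv$lambda.min, predictors = preds,
                 center = center, scale = scale),
            class = "climland_component")
}

#' Predict a single component on tabular data
#'
#' @param comp A `climland_component`.
#' @param newdata Data frame with raw predictor columns and a `bias` column.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_component <- function(comp, newdata) {
  stopifnot(inherits(comp, "climland_component"))
  switch(comp$kind,
    glm = {
      fr <- glm_frame(newdata, comp$predictors, comp$center, comp$scale)
      as.numeric(stats::predict(comp$fit, newdata = fr, type = "response"))
    },
    rf = as.numeric(.rf_predict(comp$forest,
                                as.matrix(newdata[comp$features]))),
    maxent = {
      x <- maxent_features(newdata, comp$predictors, comp$center,
                           comp$scale)
      as.numeric(stats::predict(comp$fit, newx = x, s = comp$lambda,
                                type = "response"))
    },
    stop("unknown component kind: ", comp$kind))
}

#' Fit the three-technique ensemble
#'
#' Fits the GLM (stepwise-reduced), random-forest and MaxEnt-like
#' components on the same weighted training table and records the training
#' maximum of the bias covariate for later projection.
#'
#' @param table A `training_table`.
#' @param seed Integer root seed for the stochastic components.
#' @param species_id Label carried through to outputs.
#' @param components Subset of `c("glm", "rf", "maxent")`.
#' @param stepwise Reduce the GLM by AIC (default `TRUE`).
#' @param n_trees Trees for the forest component.
#' @return A `fitted_ensemble`.
#' @export
fit_ensemble <- function(table, seed = 1L, species_id = "species",
                         components = c("glm", "rf", "maxent"),
                         stepwise = TRUE, n_trees = 500) {
  preds <- validate_training(table)
  components <- match.arg(components, several.ok = TRUE)
  fits <- list()
  if ("glm" %in% components) {
    g <- fit_glm(table, seed)
    if (stepwise) g <- stepwise_aic(g, table)
    fits$glm <- g
  }
  if ("rf" %in% components) {
    fits$rf <- fit_rf(table, seed = seed + 1L, n_trees = n_trees)
  }
  if ("maxent" %in% components) {
    fits$maxent <- fit_maxentlike(table, seed = seed + 2L)
  }
  if (!length(fits)) stop("no component fitted")
  structure(list(components = fits, species_id = species_id,
                 predictors = preds, seed = seed,
                 bias_max = max(table$bias)),
            class = "fitted_ensemble")
}

#' @export
#' @method print fitted_ensemble
print.fitted_ensemble <- function(x, ...) {
  cat("<fitted_ensemble>", x$species_id, "|",
      paste(names(x$components), collapse = " + "), "\n")
  invisible(x)
}

#' Predict the ensemble on tabular data
#'
#' Unweighted mean of the component predictions.
#'
#' @param object A `fitted_ensemble`.
#' @param newdata Data frame with raw predictor columns and `bias`.
#' @param ... Unused.
#' @return Numeric vector in `[0, 1]`.
#' @export
predict.fitted_ensemble <- function(object, newdata, ...) {
  preds <- lapply(object$components, predict_component, newdata = newdata)
  Reduce(`+`, preds) / length(preds)
}

#' Project the ensemble onto an environmental grid
#'
#' Builds the prediction table from the grid's layers, fixes the sampling
#' bias covariate (at the training maximum by default, so predictions
#' describe a fully surveyed world), averages the component predictions and
#' returns a suitability map. Masked cells stay masked.
#'
#' @param ens A `fitted_ensemble`.
#' @param env An `env_grid` holding every predictor layer.
#' @param bias_value `"max"` (training maximum) or a number in `[0, 1]`.
#' @param provenance Optional list recorded on the map (species, scenario,
#'   mode).
#' @return A `suitability_map`.
#' @export
predict_ensemble <- function(ens, env, bias_value = "max",
                             provenance = list()) {
  stopifnot(inherits(ens, "fitted_ensemble"), inherits(env, "env_grid"))
  missing <- setdiff(ens$predictors, names(env$layers))
  if (length(missing)) {
    stop("environment grid lacks predictor layer(s): ",
         paste(missing, collapse = ", "))
  }
  bv <- if (identical(bias_value, "max")) ens$bias_max else {
    stopifnot(is.numeric(bias_value), length(bias_value) == 1L)
    bias_value
  }
  ok <- !env$nodata_mask
  newdata <- data.frame(row.names = seq_len(sum(ok)))
  for (nm in ens$predictors) newdata[[nm]] <- env$layers[[nm]][ok]
  newdata$bias <- bv
  complete <- stats::complete.cases(newdata)
  vals <- matrix(NA_real_, env$n_rows, env$n_cols)
  if (any(complete)) {
    p <- predict(ens, newdata[complete, , drop = FALSE])
    cells <- which(ok)[complete]
    vals[cells] <- pmin(pmax(p, 0), 1)
  }
  suitability_map(vals, env,
                  provenance = c(list(species = ens$species_id), provenance))
}
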