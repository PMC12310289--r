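# Deviance partitioning: how much of a species' occurrence pattern is
# explained independently by climate, independently by land cover, and
# jointly (indistinguishably) by the two correlated sets. Four weighted
# binomial GLMs: bias-only null, climate+bias, landcover+bias, both+bias;
# each non-null model reduced by stepwise AIC before its residual deviance
# is read off.

#' Partition explained deviance into climate, land-cover and joint fractions
#'
#' Fits the bias-only null model and the three stepwise-reduced predictor
#' models, then computes explained-deviance fractions relative to the null,
#' `D_M = (dev_null - dev_M) / dev_null`, and the two-set decomposition
#' `a = D_CL - D_L` (independent climate), `b = D_CL - D_C` (independent
#' land cover), `c = D_C + D_L - D_CL` (joint). The identity
#' `a + b + c = D_CL` holds exactly by construction. Percentages are
#' components over `D_CL`. Negative components (possible under suppression
#' or stepwise reduction) are reported as-is.
#'
#' @param table A `training_table` whose predictors include both variable
#'   sets.
#' @param seed Unused by the deterministic fits; interface symmetry.
#' @param climate,landcover Names of the two predictor sets (defaults:
#'   the layer-name registries).
#' @param stepwise Reduce each non-null model by AIC (default `TRUE`).
#' @return A `partition_result` list with the four deviances, `D_C`, `D_L`,
#'   `D_CL`, components `a`, `b`, `c` and percentages `pct_a`, `pct_b`,
#'   `pct_c`.
#' @export
partition_deviance <- function(table, seed = 1L,
                               climate = climate_layers(),
                               landcover = landcover_layers(),
                               stepwise = TRUE) {
  preds <- validate_training(table)
  climate <- intersect(climate, preds)
  landcover <- intersect(landcover, preds)
  if (!length(climate) || !length(landcover)) {
    stop("both predictor sets must be present in the training table")
  }
  if (length(unique(table$response)) < 2L) {
    stop("degenerate response: only one class present")
  }

  fit_set <- function(set) {
    comp <- fit_glm(table, seed, predictors = set)
    if (stepwise) comp <- stepwise_aic(comp, table)
    comp$fit$deviance
  }
  # bias-only null: fit the full-frame model restricted to z.bias
  null_comp <- fit_glm(table, seed, predictors = character(0))
  dev_null <- null_comp$fit$deviance
  if (dev_null <= 0) stop("null deviance is zero: degenerate response")

  dev_C <- fit_set(climate)
  dev_L <- fit_set(landcover)
  dev_CL <- fit_set(c(climate, landcover))

  D_C <- (dev_null - dev_C) / dev_null
  D_L <- (dev_null - dev_L) / dev_null
  D_CL <- (dev_null - dev_CL) / dev_null
  # independent stepwise searches can leave the full model a whisker above
  # a component model in deviance; small violations surface as negative
  # components, larger ones indicate a failed fit
  if (D_CL < max(D_C, D_L) - 0.01) {
    stop("full model explains less than a component model beyond stepwise ",
         "noise (D_CL = ", format(D_CL), ", max component = ",
         format(max(D_C, D_L)), ")")
  }
  a <- D_CL - D_L
  b <- D_CL - D_C
  cc <- D_C + D_L - D_CL
  structure(list(dev_null = dev_null, dev_C = dev_C, dev_L = dev_L,
                 dev_CL = dev_CL, D_C = D_C, D_L = D_L, D_CL = D_CL,
                 a = a, b = b, c = cc,
                 pct_a = 100 * a / D_CL, pct_b = 100 * b / D_CL,
                 pct_c = 100 * cc / D_CL),
            class = "partition_result")
}

#' @export
#' @method print partition_result
print.partition_result <- function(x, ...) {
  cat(sprintf("<partition_result> D_CL = %.1f%% of null deviance\n",
              100 * x$D_CL))
  cat(sprintf("  climate %.1f%% | land cover %.1f%% | joint %.1f%%\n",
              x$pct_a, x$pct_b, x$pct_c))
  invisible(x)
}

#' Partition a batch of species and summarise
#'
#' Runs [partition_deviance()] per species, continuing past per-species
#' failures (recorded in the `failures` attribute), and appends the
#' across-species mean and sample SD of `D_CL` and the percentage
#' components. With a single species the SD is reported as `NA`.
#'
#' @param tables Named list of `training_table`s (names are species ids).
#' @param seed Passed through to each fit.
#' @param ... Passed to [partition_deviance()].
#' @return A data frame, one row per species plus `mean` and `sd` rows;
#'   failed species are listed in `attr(, "failures")`.
#' @export
partition_batch <- function(tables, seed = 1L, ...) {
  stopifnot(length(tables) >= 1L)
  ids <- names(tables)
  if (is.null(ids)) ids <- paste0("species_", seq_along(tables))
  rows <- list()
  failures <- character(0)
  for (k in seq_along(tables)) {
    res <- tryCatch(partition_deviance(tables[[k]], seed = seed, ...),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, stats::setNames(conditionMessage(res), ids[k]))
      next
    }
    rows[[ids[k]]] <- data.frame(species = ids[k],
                                 as.data.frame(unclass(res)))
  }
  if (!length(rows)) stop("every species failed: ",
                          paste(failures, collapse = "; "))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  num <- c("D_CL", "pct_a", "pct_b", "pct_c")
  summarise <- function(f, label) {
    r <- out[1L, , drop = FALSE]
    r$species <- label
    for (nm in setdiff(names(r), "species")) {
      r[[nm]] <- if (nm %in% num) f(out[[nm]]) else NA_real_
    }
    r
  }
  sd_or_na <- function(v) if (length(v) > 1L) stats::sd(v) else NA_real_
  out <- rbind(out, summarise(mean, "mean"), summarise(sd_or_na, "sd"))
  attr(out, "failures") <- failures
  out
}
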