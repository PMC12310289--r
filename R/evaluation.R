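# Accuracy metrics: continuous Boyce index (calibration), AUC and TSS
# (discrimination) at the 5% omission threshold, and shuffle-correlation
# variable importance.

#' Continuous Boyce index
#'
#' Moving windows of width `window_frac` times the range of the background
#' predictions are slid across that range at `n_windows` evenly spaced
#' midpoints. In each window with background mass the predicted-to-expected
#' ratio F = (fraction of presence predictions in the window) / (fraction
#' of background predictions in the window) is computed; the index is the
#' Spearman rank correlation between F and the window midpoint. It ranges
#' from -1 to 1; high positive values mean higher suitability classes hold
#' disproportionately many presences (good calibration), values near 0 a
#' random model, and negative values counter-predictions.
#'
#' @param pred_at_presences,pred_at_background Predictions in `[0, 1]`.
#' @param n_windows Number of window midpoints (default 101).
#' @param window_frac Window width as a fraction of the background
#'   prediction range (default 0.1).
#' @return The index, a single number in `[-1, 1]`.
#' @export
boyce_index <- function(pred_at_presences, pred_at_background,
                        n_windows = 101, window_frac = 0.1) {
  p <- pred_at_presences; b <- pred_at_background
  stopifnot(length(p) >= 1L, length(b) >= 1L)
  if (min(c(p, b)) < 0 || max(c(p, b)) > 1) {
    stop("predictions must lie in [0, 1]")
  }
  rng <- range(b)
  width <- window_frac * (rng[2L] - rng[1L])
  if (width <= 0) stop("background predictions have zero range")
  mids <- seq(rng[1L], rng[2L], length.out = n_windows)
  f <- rep(NA_real_, n_windows)
  for (k in seq_len(n_windows)) {
    lo <- mids[k] - width / 2; hi <- mids[k] + width / 2
    eb <- mean(b >= lo & b <= hi)
    if (eb > 0) f[k] <- mean(p >= lo & p <= hi) / eb
  }
  ok <- !is.na(f)
  if (sum(ok) < 2L) stop("fewer than 2 windows hold background mass")
  stats::cor(f[ok], mids[ok], method = "spearman")
}

#' Area under the ROC curve (Mann-Whitney concordance)
#'
#' The probability that a randomly chosen positive scores above a randomly
#' chosen negative, ties counting one half. Computed via the rank-sum
#' identity, which equals the mean over all positive x negative pairs of
#' `1[pos > neg] + 0.5 * 1[pos == neg]`.
#'
#' @param pos,neg Prediction vectors for the two classes.
#' @return AUC in `[0, 1]`; 0.5 is random.
#' @export
auc <- function(pos, neg) {
  stopifnot(length(pos) >= 1L, length(neg) >= 1L)
  r <- rank(c(pos, neg), ties.method = "average")
  n1 <- length(pos); n0 <- length(neg)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Omission threshold from presence predictions
#'
#' The empirical `q`-quantile of the presence predictions, by the linear
#' interpolation convention (`stats::quantile` type 7). Binarizing at this
#' threshold keeps at least `1 - q` of presences classified suitable.
#'
#' @param pred_at_presences Predictions at presence records.
#' @param q Omission rate (default 0.05, the 5% threshold).
#' @return The threshold.
#' @export
omission_threshold <- function(pred_at_presences, q = 0.05) {
  stopifnot(length(pred_at_presences) >= 1L, q > 0, q < 1)
  as.numeric(stats::quantile(pred_at_presences, probs = q, type = 7,
                             names = FALSE))
}

#' True skill statistic
#'
#' Classifies `pred >= threshold` as suitable and returns
#' `sensitivity + specificity - 1`.
#'
#' @param pred Numeric predictions.
#' @param labels 0/1 observed classes (both must occur).
#' @param threshold Classification threshold.
#' @return TSS in `[-1, 1]`.
#' @export
tss <- function(pred, labels, threshold) {
  stopifnot(length(pred) == length(labels))
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present to compute TSS")
  }
  suit <- pred >= threshold
  sens <- sum(suit & labels == 1) / sum(labels == 1)
  spec <- sum(!suit & labels == 0) / sum(labels == 0)
  sens + spec - 1
}

#' Shuffle-correlation variable importance
#'
#' For each predictor and repetition: permute that column of the training
#' table, re-predict with the ensemble, and score
#' `1 - max(0, cor(original, shuffled))` (Pearson). A variable the model
#' ignores scores near 0; the sole driver of a model scores near 1. Mean
#' over repetitions per variable. Deterministic given `seed`.
#'
#' @param ens A `fitted_ensemble`.
#' @param table A `training_table` (or any data frame with predictor and
#'   bias columns).
#' @param n_rep Repetitions (default 3).
#' @param seed Integer seed.
#' @param variables Columns to assess (default: predictors + bias).
#' @return Data frame with per-repetition values and a `mean_importance`
#'   summary attribute column order (variable, rep, importance).
#' @export
variable_importance <- function(ens, table, n_rep = 3, seed = 1L,
                                variables = NULL) {
  stopifnot(inherits(ens, "fitted_ensemble"), nrow(table) >= 2L)
  if (is.null(variables)) variables <- c(ens$predictors, "bias")
  base_pred <- predict(ens, table)
  if (stats::sd(base_pred) == 0) {
    warning("constant predictions; importance defined as 0")
  }
  rows <- list()
  k <- 0L
  for (v in variables) {
    for (r in seq_len(n_rep)) {
      shuffled <- table
      perm <- with_seed(seed + 131L * k, sample.int(nrow(table)))
      k <- k + 1L
      shuffled[[v]] <- shuffled[[v]][perm]
      p <- predict(ens, shuffled)
      imp <- if (stats::sd(base_pred) == 0 || stats::sd(p) == 0) 0 else {
        1 - max(0, stats::cor(base_pred, p))
      }
      rows[[length(rows) + 1L]] <- data.frame(variable = v, rep = r,
                                              importance = imp)
    }
  }
  out <- do.call(rbind, rows)
  means <- stats::aggregate(importance ~ variable, out, mean)
  names(means)[2L] <- "mean_importance"
  merge(out, means, by = "variable", sort = FALSE)
}

#' Evaluate an ensemble against presence and background predictions
#'
#' Convenience wrapper returning the Boyce index, AUC and TSS (at the 5%
#' omission threshold computed from the presence predictions) in one
#' report.
#'
#' @param pred_at_presences,pred_at_background Predictions in `[0, 1]`.
#' @param q Omission rate for the TSS threshold.
#' @return A one-row data frame: `boyce`, `auc`, `tss`, `threshold_used`,
#'   `n_presence_eval`, `n_background_eval`.
#' @export
evaluate_predictions <- function(pred_at_presences, pred_at_background,
                                 q = 0.05) {
  thr <- omission_threshold(pred_at_presences, q)
  data.frame(
    boyce = boyce_index(pred_at_presences, pred_at_background),
    auc = auc(pred_at_presences, pred_at_background),
    tss = tss(c(pred_at_presences, pred_at_background),
              rep(c(1, 0), c(length(pred_at_presences),
                             length(pred_at_background))),
              thr),
    threshold_used = thr,
    n_presence_eval = length(pred_at_presences),
    n_background_eval = length(pred_at_background))
}
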