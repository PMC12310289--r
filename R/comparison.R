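# Cross-species paired comparisons of range metrics between prediction
# modes and scenarios: Wilcoxon signed-rank tests, exact for small
# tie-free samples.

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on matched per-species values. Zero
#' differences are dropped (Wilcoxon's convention; `zero_method = "pratt"`
#' keeps them in the ranking but excludes them from the statistic). The
#' null distribution is exact (via the signed-rank distribution) when the
#' effective sample is at most 25 with no tied absolute differences, and a
#' normal approximation with tie correction otherwise. If every difference
#' is zero the result is defined as p = 1 with the statistic at its null
#' expectation and `all_zero = TRUE`.
#'
#' @param x,y Equal-length numeric vectors matched by species.
#' @param zero_method `"drop"` (default) or `"pratt"`.
#' @param exact_max Largest effective n for which the exact null is used.
#' @return A one-row data frame: `n_effective`, `statistic` (V, the sum of
#'   positive-difference ranks), `p_value`, `direction` (sign of the median
#'   paired difference), `method`, `all_zero`.
#' @export
wilcoxon_paired <- function(x, y, zero_method = c("drop", "pratt"),
                            exact_max = 25) {
  zero_method <- match.arg(zero_method)
  stopifnot(length(x) == length(y), length(x) >= 2L)
  d <- x - y
  if (anyNA(d)) stop("missing values in paired differences")
  nz <- d != 0
  if (!any(nz)) {
    return(data.frame(n_effective = 0L, statistic = 0, p_value = 1,
                      direction = 0, method = "all-zero", all_zero = TRUE))
  }
  if (zero_method == "drop") {
    d_use <- d[nz]
    r <- rank(abs(d_use))
  } else {
    r_all <- rank(abs(d))
    d_use <- d[nz]
    r <- r_all[nz]
  }
  n <- length(d_use)
  v <- sum(r[d_use > 0])
  ties <- any(duplicated(r))
  if (!ties && zero_method == "drop" && n <= exact_max) {
    p <- 2 * min(stats::psignrank(v, n),
                 stats::psignrank(v - 1, n, lower.tail = FALSE))
    p <- min(1, p)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (v - mu) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal-approximation"
  }
  data.frame(n_effective = n, statistic = v, p_value = p,
             direction = sign(stats::median(d_use)), method = method,
             all_zero = FALSE)
}

# fetch the per-species metric vector for one (scenario, mode) cell,
# ordered by `species`; errors on duplicates or gaps
.metric_cell <- function(summaries, species, scenario, mode, metric) {
  sel <- summaries$scenario == scenario & summaries$mode == mode
  sub <- summaries[sel, , drop = FALSE]
  if (anyDuplicated(sub$species)) {
    stop("duplicated species rows for scenario '", scenario, "', mode '",
         mode, "'")
  }
  miss <- setdiff(species, sub$species)
  if (length(miss)) {
    stop("missing summaries for scenario '", scenario, "', mode '", mode,
         "': species ", paste(miss, collapse = ", "))
  }
  sub[[metric]][match(species, sub$species)]
}

#' Grid of paired comparisons across modes and scenarios
#'
#' For each metric (`area_km2`, `centroid_lon`, `centroid_lat`,
#' `shift_km`) runs [wilcoxon_paired()] for every unordered mode pair
#' within each future scenario, and every scenario pair (including
#' `"current"`) within each prediction mode. Current-condition values come
#' from the rows with `scenario == "current"` regardless of mode.
#'
#' @param summaries A range-summary table ([range_summary()] rows).
#' @param restricted Which `restricted_to_occupied` stratum to compare.
#' @param metrics Metric columns to compare.
#' @return Data frame of comparison rows; per-species z-scores across the
#'   compared cells (for plotting) in `attr(, "standardized")`.
#' @export
compare_grid <- function(summaries, restricted = FALSE,
                         metrics = c("area_km2", "centroid_lon",
                                     "centroid_lat", "shift_km")) {
  summaries <- summaries[summaries$restricted_to_occupied == restricted, ,
                         drop = FALSE]
  if (nrow(summaries) == 0L) stop("no summaries in the requested stratum")
  species <- sort(unique(summaries$species))
  if (length(species) < 2L) stop("at least two species required")
  scenarios <- setdiff(unique(summaries$scenario), "current")
  modes <- setdiff(unique(summaries$mode), "current")
  has_current <- any(summaries$scenario == "current")

  rows <- list()
  std <- list()
  add <- function(metric, kind, within, a, b, xa, xb) {
    w <- wilcoxon_paired(xa, xb)
    rows[[length(rows) + 1L]] <<- data.frame(
      metric = metric, comparison = kind, within = within,
      level_a = a, level_b = b, n_species = length(species), w)
  }
  for (metric in metrics) {
    # standardized per-species values across all cells of the grid
    cells <- expand.grid(scenario = scenarios, mode = modes,
                         stringsAsFactors = FALSE)
    if (has_current) {
      cells <- rbind(cells, data.frame(scenario = "current",
                                       mode = "current"))
    }
    vals <- sapply(seq_len(nrow(cells)), function(k) {
      .metric_cell(summaries, species, cells$scenario[k], cells$mode[k],
                   metric)
    })
    if (is.null(dim(vals))) vals <- matrix(vals, nrow = length(species))
    zz <- t(apply(vals, 1L, function(v) {
      s <- stats::sd(v); if (!is.finite(s) || s == 0) s <- 1
      (v - mean(v)) / s
    }))
    std[[length(std) + 1L]] <- data.frame(
      metric = metric,
      species = rep(species, times = nrow(cells)),
      scenario = rep(cells$scenario, each = length(species)),
      mode = rep(cells$mode, each = length(species)),
      value = as.vector(vals), z = as.vector(zz))

    # mode pairs within each future scenario
    if (length(modes) >= 2L) {
      for (s in scenarios) {
        pairs <- utils::combn(modes, 2L)
        for (k in seq_len(ncol(pairs))) {
          m1 <- pairs[1L, k]; m2 <- pairs[2L, k]
          add(metric, "mode-pair", s, m1, m2,
              .metric_cell(summaries, species, s, m1, metric),
              .metric_cell(summaries, species, s, m2, metric))
        }
      }
    }
    # scenario pairs (incl. current) within each mode
    sc_levels <- c(if (has_current) "current", scenarios)
    if (length(sc_levels) >= 2L) {
      for (m in modes) {
        pairs <- utils::combn(sc_levels, 2L)
        for (k in seq_len(ncol(pairs))) {
          s1 <- pairs[1L, k]; s2 <- pairs[2L, k]
          g1 <- if (s1 == "current") {
            .metric_cell(summaries, species, "current", "current", metric)
          } else .metric_cell(summaries, species, s1, m, metric)
          g2 <- if (s2 == "current") {
            .metric_cell(summaries, species, "current", "current", metric)
          } else .metric_cell(summaries, species, s2, m, metric)
          add(metric, "scenario-pair", m, s1, s2, g1, g2)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "standardized") <- do.call(rbind, std)
  out
}

#' Holm correction across a comparison table
#'
#' Off by default in the pipeline (raw pairwise p-values are reported);
#' provided for users who want family-wise control.
#'
#' @param comparisons Output of [compare_grid()].
#' @return The table with a `p_holm` column appended.
#' @export
adjust_holm <- function(comparisons) {
  comparisons$p_holm <- stats::p.adjust(comparisons$p_value,
                                        method = "holm")
  comparisons
}
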