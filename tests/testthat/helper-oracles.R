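# Independent test oracles.

# exact two-sided signed-rank p-value by enumerating all 2^n sign patterns
enum_signrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  p_lo <- mean(v_all <= v_obs)
  p_hi <- mean(v_all >= v_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# brute-force pairwise AUC
brute_auc <- function(pos, neg) {
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# a simulated world for partition-recovery checks: climate-driven species,
# land-cover collinearity controlled by alpha_cov. Short correlation length
# and a largish grid keep the effective spatial sample size high enough
# that independent smooth fields do not spuriously absorb deviance.
partition_world <- function(seed, alpha_cov, n_rows = 60, n_cols = 60,
                            n_target = 700, correlation_length = 2) {
  env <- generate_environment(field_spec(n_rows = n_rows, n_cols = n_cols,
                                         correlation_length =
                                           correlation_length,
                                         alpha_cov = alpha_cov,
                                         seed = seed))
  sp <- virtual_species(beta = c(tmax = -1.5, pan = 0.8),
                        beta_sq = c(tmax = -0.6), intercept = -0.5,
                        detection_gamma = 0)
  suit <- true_suitability(env, sp)
  bias <- matrix(0.5, n_rows, n_cols)
  occ <- sample_occurrences(suit, bias, n_target, sp, seed = seed + 1L)
  pres <- grid_presences(occ, env)
  pabs <- draw_pseudoabsences(pres, synthetic_biomes(env),
                              seed = seed + 2L)
  assemble_training(pres, pabs, env, bias)
}

# the demo study, run once and memoized (shared by the end-to-end and
# determinism checks)
demo_run <- function() {
  memo("demo_run", {
    outdir <- file.path(tempdir(), "climland-demo-a")
    res <- run_study(demo_config(seed = 1), outdir = outdir)
    list(res = res, outdir = outdir)
  })
}
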