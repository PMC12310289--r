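# Orchestration: one config drives synthesis, training-table assembly,
# deviance partitioning, ensemble fitting, evaluation, decoupled scenario
# projection and cross-species comparison, with per-species failure
# isolation and a reproducibility manifest. All randomness flows from the
# config's root seed through named substreams.

# substream rule: seed(species i, stage s) =
#   (root + 1009 * i + stage_code) mod (2^31 - 1)
stage_seed <- function(root, species_index, stage) {
  codes <- c(environment = 1L, bias = 2L, occurrences = 3L,
             pseudoabsences = 4L, partition = 5L, ensemble = 6L,
             importance = 7L)
  as.integer((as.numeric(root) + 1009 * species_index + codes[[stage]]) %%
               2147483647)
}

#' Synthetic biome map from climate bands
#'
#' Bins the minimum-temperature layer into `n_biomes` quantile classes,
#' giving contiguous climatic bands that stand in for a biome map when no
#' real one is supplied.
#'
#' @param env An `env_grid` with a `tmin` layer.
#' @param n_biomes Number of classes (default 3).
#' @return Integer matrix of biome ids (1..n_biomes).
#' @export
synthetic_biomes <- function(env, n_biomes = 3) {
  v <- get_layer(env, "tmin")
  qs <- stats::quantile(v[!env$nodata_mask],
                        probs = seq(0, 1, length.out = n_biomes + 1L))
  qs[1L] <- -Inf; qs[length(qs)] <- Inf
  b <- matrix(as.integer(cut(v, qs, labels = FALSE)),
              env$n_rows, env$n_cols)
  b[env$nodata_mask] <- NA_integer_
  b
}

#' Demo study configuration
#'
#' Three cool-adapted virtual species on a 50 x 50 grid with a poleward
#' (northward) temperature gradient, two future scenarios whose climate
#' deltas mirror mid-century SSP1-2.6 / SSP2-4.5 trajectories (about +1.4
#' and +2.2 degrees C, 8%-12% less precipitation, cropland expansion), and
#' all three decoupled prediction modes.
#'
#' @param seed Root seed.
#' @param n_rows,n_cols Grid size.
#' @param n_trees Forest size (default 200 here to keep the demo quick;
#'   the full default elsewhere is 500).
#' @return A `study_config` list accepted by [run_study()].
#' @export
demo_config <- function(seed = 1L, n_rows = 50, n_cols = 50, n_trees = 200) {
  cool <- function(id, tmax_lin, broad) {
    # coefficient sets are named lists so the config survives JSON
    list(id = id,
         beta = list(tmax = tmax_lin, pan = 0.6, broadleaf = broad,
                     crop = -0.3),
         beta_sq = list(tmax = -0.8),
         intercept = -0.5, detection_gamma = 0.5, n_target = 400)
  }
  list(
    grid = list(n_rows = n_rows, n_cols = n_cols, correlation_length = 5,
                alpha_cov = 0.5, origin_lon = -10, origin_lat = 44,
                res_arcmin = 5, lat_gradient = 2),
    species = list(cool("sp1", -1.6, 0.6),
                   cool("sp2", -1.2, 0.9),
                   cool("sp3", -2.0, 0.4)),
    scenarios = list(
      list(name = "SSP1-2.6", gcm_label = "IPSL",
           delta = list(tmin = 1.4, tmax = 1.4, pan = 0.92,
                        needleleaf = 0.3, broadleaf = 0.3,
                        grassland = -0.25, shrub = -0.25, crop = 0.2)),
      list(name = "SSP2-4.5", gcm_label = "IPSL",
           delta = list(tmin = 2.2, tmax = 2.2, pan = 0.88,
                        grassland = -0.1, shrub = -0.1, crop = 0.15))),
    modes = c("both", "clim", "land"),
    settings = list(bandwidth_cells = 10, n_pseudoabsences = 10000,
                    q = 0.05, boyce_windows = 101, boyce_frac = 0.1,
                    n_biomes = 3, n_hubs = 15, n_trees = n_trees,
                    importance_reps = 3),
    seed = as.integer(seed))
}

run_one_species <- function(sp_cfg, i, env, bias, biomes, cfg) {
  st <- cfg$settings
  sp <- virtual_species(beta = unlist(sp_cfg$beta),
                        beta_sq = unlist(sp_cfg$beta_sq),
                        intercept = sp_cfg$intercept,
                        detection_gamma = sp_cfg$detection_gamma)
  suit_true <- true_suitability(env, sp)
  occ <- sample_occurrences(suit_true, bias, sp_cfg$n_target, sp,
                            seed = stage_seed(cfg$seed, i, "occurrences"),
                            species_id = sp_cfg$id)
  presences <- grid_presences(occ, env)
  pabs <- draw_pseudoabsences(presences, biomes,
                              n_max = st$n_pseudoabsences,
                              seed = stage_seed(cfg$seed, i,
                                                "pseudoabsences"),
                              mask = env$nodata_mask)
  table <- assemble_training(presences, pabs, env, bias)

  part <- partition_deviance(table,
                             seed = stage_seed(cfg$seed, i, "partition"))
  ens <- fit_ensemble(table, seed = stage_seed(cfg$seed, i, "ensemble"),
                      species_id = sp_cfg$id, n_trees = st$n_trees)

  current <- predict_ensemble(ens, env,
                              provenance = list(scenario = "current",
                                                mode = "current"))
  p_pres <- current$values[presences]
  p_back <- current$values[pabs]
  ev <- evaluate_predictions(p_pres[!is.na(p_pres)],
                             p_back[!is.na(p_back)], q = st$q)
  imp <- variable_importance(ens, table, n_rep = st$importance_reps,
                             seed = stage_seed(cfg$seed, i, "importance"))
  thr <- ev$threshold_used

  cur_cen <- weighted_centroid(current)
  summaries <- range_summary(current, thr, NULL, sp_cfg$id,
                             "current", "current")
  maps <- list(current = current)
  for (sc_cfg in cfg$scenarios) {
    fut <- generate_future(env, delta = sc_cfg$delta, name = sc_cfg$name,
                           gcm_label = sc_cfg$gcm_label)
    for (mode in cfg$modes) {
      env_m <- make_decoupled_inputs(env, fut, mode)
      pm <- predict_ensemble(ens, env_m,
                             provenance = list(scenario = sc_cfg$name,
                                               mode = mode))
      maps[[paste(sc_cfg$name, mode, sep = "|")]] <- pm
      summaries <- rbind(summaries,
                         range_summary(pm, thr, cur_cen, sp_cfg$id,
                                       sc_cfg$name, mode))
    }
  }
  # repeat the metrics restricted to currently occupied cells
  occ_restricted <- lapply(maps, restrict_to_occupied, occupied_cells = presences)
  cur_cen_r <- weighted_centroid(occ_restricted$current)
  for (nm in names(occ_restricted)) {
    lab <- strsplit(nm, "|", fixed = TRUE)[[1L]]
    scen <- lab[1L]; mode <- if (length(lab) > 1L) lab[2L] else "current"
    summaries <- rbind(summaries,
                       range_summary(occ_restricted[[nm]], thr,
                                     if (scen == "current") NULL else cur_cen_r,
                                     sp_cfg$id, scen, mode,
                                     restricted = TRUE))
  }
  list(species = sp_cfg$id, table = table, partition = part,
       ensemble = ens, evaluation = cbind(species = sp_cfg$id, ev),
       importance = cbind(species = sp_cfg$id, imp),
       threshold = thr, summaries = summaries, maps = maps,
       presences = presences)
}

#' Run the full study from a configuration
#'
#' Synthesizes the environment, effort surface and biome bands; then, per
#' species: samples occurrences, draws pseudo-absences, assembles the
#' weighted training table, partitions deviance, fits the ensemble,
#' evaluates it, and projects it under every scenario x decoupled mode
#' (plus the occupied-cell restriction). Cross-species Wilcoxon
#' comparisons close the run. One species' failure never aborts the batch;
#' failures are recorded in the manifest. Outputs are deterministic given
#' `config$seed`.
#'
#' @param config A `study_config` list, e.g. from [demo_config()] or
#'   [read_study_config()].
#' @param outdir Output directory (created if needed); `NULL` skips all
#'   file writing and returns results only.
#' @param write_maps Also write every suitability map as an ASCII raster.
#' @return Invisibly, a list: `partition`, `evaluation`, `importance`,
#'   `summaries`, `comparisons`, `manifest`, and per-species `results`.
#' @export
run_study <- function(config, outdir = NULL, write_maps = FALSE) {
  g <- config$grid
  spec <- field_spec(n_rows = g$n_rows, n_cols = g$n_cols,
                     correlation_length = g$correlation_length,
                     alpha_cov = g$alpha_cov,
                     seed = stage_seed(config$seed, 0L, "environment"),
                     origin_lon = g$origin_lon, origin_lat = g$origin_lat,
                     res_arcmin = g$res_arcmin,
                     lat_gradient = if (is.null(g$lat_gradient)) 0 else
                       g$lat_gradient)
  env <- generate_environment(spec)
  st <- config$settings
  bias <- simulate_bias(env, n_hubs = st$n_hubs,
                        bandwidth_cells = st$bandwidth_cells,
                        seed = stage_seed(config$seed, 0L, "bias"))
  biomes <- synthetic_biomes(env, n_biomes = st$n_biomes)

  results <- list()
  failures <- list()
  for (i in seq_along(config$species)) {
    sp_cfg <- config$species[[i]]
    res <- tryCatch(run_one_species(sp_cfg, i, env, bias, biomes, config),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures[[sp_cfg$id]] <- conditionMessage(res)
    } else {
      results[[sp_cfg$id]] <- res
    }
  }
  if (!length(results)) {
    stop("every species failed: ",
         paste(unlist(failures), collapse = "; "))
  }

  part_tab <- partition_batch(lapply(results, `[[`, "table"),
                              seed = config$seed)
  eval_tab <- do.call(rbind, lapply(results, `[[`, "evaluation"))
  imp_tab <- do.call(rbind, lapply(results, `[[`, "importance"))
  sum_tab <- do.call(rbind, lapply(results, `[[`, "summaries"))
  rownames(eval_tab) <- rownames(imp_tab) <- rownames(sum_tab) <- NULL
  comparisons <- if (length(results) >= 2L) {
    rbind(cbind(stratum = "full", compare_grid(sum_tab, FALSE)),
          cbind(stratum = "occupied", compare_grid(sum_tab, TRUE)))
  } else NULL

  manifest <- list(
    package_version = as.character(utils::packageVersion("climland")),
    r_version = R.version.string,
    seed = config$seed,
    n_species_requested = length(config$species),
    n_species_completed = length(results),
    failures = failures,
    config = config)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(part_tab, file.path(outdir, "partition.csv"),
                     row.names = FALSE)
    utils::write.csv(eval_tab, file.path(outdir, "evaluation.csv"),
                     row.names = FALSE)
    utils::write.csv(imp_tab, file.path(outdir, "importance.csv"),
                     row.names = FALSE)
    utils::write.csv(sum_tab, file.path(outdir, "range_summary.csv"),
                     row.names = FALSE)
    if (!is.null(comparisons)) {
      utils::write.csv(comparisons, file.path(outdir, "comparisons.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
    if (write_maps) {
      for (res in results) {
        for (nm in names(res$maps)) {
          sm <- res$maps[[nm]]
          gg <- sm$grid
          gg$layers <- list(suitability = sm$values)
          fn <- paste0("suitability_", res$species, "_",
                       gsub("[^A-Za-z0-9.-]", "_", nm), ".asc")
          write_layer(gg, "suitability", file.path(outdir, fn))
        }
      }
    }
  }
  invisible(list(partition = part_tab, evaluation = eval_tab,
                 importance = imp_tab, summaries = sum_tab,
                 comparisons = comparisons, manifest = manifest,
                 results = results, env = env, bias = bias,
                 biomes = biomes))
}

#' Read a study configuration from JSON
#'
#' The on-disk mirror of the config list: layer synthesis parameters,
#' species coefficient sets, scenario deltas, modes, tunables and the root
#' seed.
#'
#' @param path JSON file path.
#' @return A `study_config` list.
#' @export
read_study_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  cfg$seed <- as.integer(cfg$seed)
  cfg$modes <- unlist(cfg$modes)
  cfg
}
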