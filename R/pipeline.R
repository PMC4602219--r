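#' Experiment run configuration
#'
#' Bundles a synthetic-cohort configuration (or a saved-cohort manifest
#' path) with the preprocessing, feature and classification parameters of
#' a full run.
#'
#' @param synth A `synth_config` for simulated cohorts, or `NULL` when
#'   loading from disk.
#' @param manifest_path Manifest TSV of a saved cohort (used when `synth`
#'   is `NULL`).
#' @param window_ms Epoch window.
#' @param reject_uV Artifact rejection threshold.
#' @param k_grid Trial-average block sizes.
#' @param kinds Feature families.
#' @param channels Multi-channel set.
#' @param pc_grid Candidate PC counts.
#' @param map_k Block size used for the cohort-level discriminant map.
#' @param seed Run seed (propagated to the simulator).
#' @param out_dir Output directory.
#' @return A `run_config` list.
#' @export
run_config <- function(synth = default_config(), manifest_path = NULL,
                       window_ms = c(-500, 500), reject_uV = 1000,
                       k_grid = c(1, 2, 4, 8, 16, 32),
                       kinds = FEATURE_KINDS, channels = CLASSIFY_CHANNELS,
                       pc_grid = default_pc_grid(), map_k = 4,
                       seed = 0L, out_dir = "epierp_run") {
  if (is.null(synth) && is.null(manifest_path))
    stop("either a synth config or a cohort manifest is required")
  if (!is.null(manifest_path) && !file.exists(manifest_path))
    stop("manifest does not exist: ", manifest_path)
  structure(list(synth = synth, manifest_path = manifest_path,
                 window_ms = window_ms, reject_uV = reject_uV,
                 k_grid = k_grid, kinds = kinds, channels = channels,
                 pc_grid = pc_grid, map_k = map_k, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Simulate (or load) a cohort as rejected single-trial epoch sets
#'
#' Processes one animal at a time — simulate or load, epoch, reject — so
#' continuous signals are never all held in memory at once.
#'
#' @param config A `run_config`.
#' @return List of `epoch_set`s, one per animal.
#' @export
cohort_epochs <- function(config) {
  if (!is.null(config$synth)) {
    synth <- config$synth
    synth$seed <- config$seed
    mf <- cohort_manifest(synth)
    eps <- lapply(seq_len(nrow(mf)), function(i) {
      rec <- simulate_animal(synth, mf$genotype[i], mf$animal_id[i],
                             seed = mf$seed[i], sex = mf$sex[i])
      reject_artifacts(extract_epochs(rec, config$window_ms),
                       config$reject_uV)
    })
    names(eps) <- mf$animal_id
    eps
  } else {
    recs <- load_cohort(config$manifest_path)
    lapply(recs, function(rec)
      reject_artifacts(extract_epochs(rec, config$window_ms),
                       config$reject_uV))
  }
}

#' Cohort-level temporal discriminant and per-animal spatial maps
#'
#' Fits the multi-channel waveform-PC pipeline on all animals at block
#' size `map_k` (PCA, then Fisher LDA on the leading `n_pcs` scores),
#' factors the discriminant into temporal x spatial parts, and projects
#' each animal's mean ERP onto the temporal profile to build per-animal
#' interpolated cortical maps. This map product is descriptive (it is
#' never fed back into cross-validation).
#'
#' @param ep_list Rejected single-trial `epoch_set`s.
#' @param map_k Block size.
#' @param n_pcs PCs for the map discriminant (default 20, capped by
#'   availability).
#' @param channels Channel set used for the discriminant.
#' @param mont Montage for interpolation.
#' @param window_ms Analysis window.
#' @return List with `discriminant` (a `temporal_discriminant`), `maps`
#'   (per-animal `spatial_map`s) and `group_difference` (WT minus HYPO
#'   mean channel values).
#' @export
cohort_spatial_maps <- function(ep_list, map_k = 4, n_pcs = 20,
                                channels = CLASSIFY_CHANNELS,
                                mont = default_montage(),
                                window_ms = c(0, 250)) {
  fm <- cohort_features(ep_list, "pc_multi", map_k, channels, window_ms)
  pca <- fit_pca(fm, rank. = max(n_pcs, 2))
  n_pcs <- min(n_pcs, n_components(pca))
  scores <- project_pca(pca, fm, n_pcs)
  cls <- fit_fisher(scores)
  n_time <- sum(ep_list[[1]]$time_ms >= window_ms[1] &
                  ep_list[[1]]$time_ms < window_ms[2])
  disc <- extract_temporal_discriminant(cls, pca, channels, n_time)
  use_mont <- mont[mont$kind == "eeg" & mont$label %in% channels, ]
  sel <- window_index(ep_list[[1]]$time_ms, window_ms)
  maps <- lapply(ep_list, function(ep) {
    ga <- grand_average(ep)[, sel, drop = FALSE]
    channel_projection_map(ga, disc$temporal, use_mont,
                           animal_id = ep$animal_id)
  })
  vals <- t(vapply(maps, `[[`, numeric(nrow(use_mont)), "channel_values"))
  geno <- vapply(ep_list, `[[`, "", "genotype")
  gdiff <- colMeans(vals[geno == "WT", , drop = FALSE]) -
    colMeans(vals[geno == "HYPO", , drop = FALSE])
  list(discriminant = disc, maps = maps, group_difference = gdiff)
}

#' Run the full experiment
#'
#' simulate (optional) -> epoch -> reject -> features -> classify -> map,
#' writing `cv_report.csv`, `chosen_pcs.csv`, `cv_summary.json`,
#' per-animal spatial maps, a projection scatter of single-trial channel
#' waveforms on the grand-average spanning plane, and a JSON run manifest
#' capturing the configuration and seed. Deterministic for a fixed seed.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the `cv_report`, the spatial products
#'   and the output paths.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage [", name, "] failed: ", conditionMessage(e), call. = FALSE))
  }
  eps <- stage("simulate/preprocess", cohort_epochs(config))
  report <- stage("classify",
                  error_vs_averaging(eps, config$kinds, config$k_grid,
                                     config$pc_grid, config$channels))
  write_cv_report(report, out("cv_report.csv"), out("cv_summary.json"))
  chosen <- report[report$feature_kind == "pc_multi",
                   c("k", "n_pcs", "error")]
  write.table(chosen, out("chosen_pcs.csv"), sep = ",", quote = FALSE,
              row.names = FALSE)
  spatial <- NULL
  if ("pc_multi" %in% config$kinds) {
    spatial <- stage("map", cohort_spatial_maps(eps, config$map_k,
                                                channels = config$channels))
    for (m in spatial$maps)
      write_spatial_map(m, out(paste0("map_", m$animal_id, ".tsv")),
                        out(paste0("map_", m$animal_id, ".json")))
  }
  scatter <- stage("scatter", {
    pooled <- pool_channel_trials(eps, c("FR", "PR", "OR"))
    write.table(pooled, out("plane_scatter.csv"), sep = ",", quote = FALSE,
                row.names = FALSE)
    pooled
  })
  manifest <- list(seed = config$seed, window_ms = config$window_ms,
                   reject_uV = config$reject_uV, k_grid = config$k_grid,
                   kinds = config$kinds, channels = config$channels,
                   pc_grid = config$pc_grid, map_k = config$map_k,
                   package_version = as.character(utils::packageVersion("epierp")))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), out("run_manifest.json"))
  invisible(list(report = report, spatial = spatial, scatter = scatter,
                 out_dir = config$out_dir))
}

# Single-trial channel waveforms projected on the pooled grand-average
# spanning plane (FR/PR/OR cluster geometry).
pool_channel_trials <- function(ep_list, plane_channels = c("FR", "PR", "OR"),
                                window_ms = c(0, 250)) {
  sel <- window_index(ep_list[[1]]$time_ms, window_ms)
  gas <- lapply(plane_channels, function(ch) {
    mats <- lapply(ep_list, function(ep) {
      idx <- which(ep$mask)
      ci <- match(ch, ep$channels)
      M <- ep$data[idx, ci, sel, drop = FALSE]
      dim(M) <- c(length(idx), length(sel))
      M
    })
    do.call(rbind, mats)
  })
  names(gas) <- plane_channels
  ga_mean <- lapply(gas, colMeans)
  plane <- spanning_plane(ga_mean[[1]], ga_mean[[2]], ga_mean[[3]])
  rows <- lapply(plane_channels, function(ch) {
    xy <- project_onto_plane(plane, gas[[ch]])
    data.frame(channel = ch, coord1 = xy[, 1], coord2 = xy[, 2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
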