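#' Pipeline configuration
#'
#' A single global seed deterministically derives one sub-seed per stage, so
#' the whole run is reproducible and each stage can also be reproduced in
#' isolation.
#'
#' @param outdir Output directory for CSV tables and the JSON manifest.
#' @param seed Global seed.
#' @param n_sets Bootstrap sets for the adequacy screen.
#' @param n_rand Randomizations for Monte Carlo / permutation tests.
#' @param n_perm Permutations for spatial statistics and envfit.
#' @param class_width_km Correlogram class width.
#' @param alpha Significance level used throughout.
#' @param min_dbh_cm Tree-diameter filter threshold.
#' @param nmds_k,nmds_starts NMDS dimensionality and random starts.
#' @param ctree_min_node,ctree_n_perm Tree controls.
#' @param ctree_predictors Covariate columns offered to the tree.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir = tempfile("forestshift_run_"),
                            seed = 1, n_sets = 100, n_rand = 10000,
                            n_perm = 999, class_width_km = 15,
                            alpha = 0.05, min_dbh_cm = 12.5, nmds_k = 2,
                            nmds_starts = 50, ctree_min_node = 20,
                            ctree_n_perm = 9999,
                            ctree_predictors = c(
                              "gdd", "precip_mm", "elevation_m",
                              "ruggedness_m", "agri_peak", "agri_peak_year",
                              "agri_decline_rate", "canopy_pct", "sand_pct",
                              "clay_pct", "latitude", "longitude")) {
  structure(as.list(environment()), class = "pipeline_config")
}

.stage_seed <- function(seed, stage) {
  # deterministic per-stage sub-seed, kept within 32-bit integer range
  (seed * 1000003L + match(stage, c("adequacy", "change", "beta", "spatial",
                                    "ordination", "tree")) * 7919L) %%
    2147483647L
}

#' Run the full analysis pipeline
#'
#' Executes load -> filter -> adequacy screen -> per-town change ->
#' abundance table -> beta diversity -> spatial statistics -> ordination ->
#' regression tree on a dataset, writing CSV tables and a JSON manifest
#' (seed, parameters, and record counts at every exclusion stage) to
#' `config$outdir`.
#'
#' @param dataset A `forest_dataset` (from [load_dataset()] or
#'   [simulate_landscape()]`$dataset`).
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_result` with every stage's output plus
#'   `manifest`.
#' @export
run_pipeline <- function(dataset, config = pipeline_config()) {
  stopifnot(inherits(dataset, "forest_dataset"),
            inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed,
                   parameters = config[setdiff(names(config), "outdir")],
                   counts = list(towns_input = nrow(dataset$towns),
                                 plots_input = nrow(dataset$plots),
                                 trees_input = nrow(dataset$trees)))

  # --- filter ------------------------------------------------------------
  filt <- filter_modern(dataset$plots, dataset$trees,
                        min_dbh_cm = config$min_dbh_cm)
  ds <- dataset
  ds$plots <- filt$plots
  ds$trees <- filt$trees
  ds$towns <- ds$towns[!(ds$towns$town_id %in% filt$towns_dropped), ,
                       drop = FALSE]
  ds$trees <- ds$trees[ds$trees$town_id %in% ds$towns$town_id, ,
                       drop = FALSE]
  manifest$counts$filter <- as.list(filt$log)

  # --- adequacy screen ----------------------------------------------------
  thresholds <- ecoregion_thresholds(ds, n_sets = config$n_sets,
                                     seed = .stage_seed(config$seed,
                                                        "adequacy"))
  included <- screen_towns(ds, thresholds)
  manifest$counts$towns_screened_in <- length(included)
  ds$towns <- ds$towns[ds$towns$town_id %in% included, , drop = FALSE]
  ds$trees <- ds$trees[ds$trees$town_id %in% included, , drop = FALSE]
  ds$plots <- ds$plots[ds$plots$town_id %in% included, , drop = FALSE]
  if (length(included) < 4) stop("pipeline aborted at screen stage: fewer ",
                                 "than 4 towns pass the adequacy screen")

  # --- compositions -------------------------------------------------------
  trees <- ds$trees
  pre <- town_composition(trees[trees$era == "precolonial", ])
  mod <- town_composition(trees[trees$era == "modern", ])
  al <- align_compositions(pre, mod)
  pre <- al$pre; mod <- al$mod
  towns <- ds$towns[match(al$towns, ds$towns$town_id), , drop = FALSE]
  eco <- stats::setNames(towns$ecoregion, towns$town_id)

  # --- change + abundance table -------------------------------------------
  change <- change_per_town(pre, mod, ecoregion = eco,
                            n_rand = config$n_rand,
                            seed = .stage_seed(config$seed, "change"))
  abundance <- abundance_change_table(pre, mod, ecoregion = eco,
                                      n_rand = config$n_rand)

  # --- beta diversity -------------------------------------------------------
  beta <- beta_diversity(pre, mod, ecoregion = eco, n_rand = config$n_rand,
                         seed = .stage_seed(config$seed, "beta"))

  # --- spatial --------------------------------------------------------------
  seed_sp <- .stage_seed(config$seed, "spatial")
  geo <- geo_distances(towns)
  moran <- morans_correlogram(change$change, geo,
                              class_width_km = config$class_width_km,
                              n_perm = config$n_perm, alpha = config$alpha,
                              seed = seed_sp)
  d_pre <- sorensen_matrix(pre)
  d_mod <- sorensen_matrix(mod)
  mcor_pre <- mantel_correlogram(d_pre, geo,
                                 class_width_km = config$class_width_km,
                                 n_perm = config$n_perm,
                                 alpha = config$alpha, seed = seed_sp + 1)
  mcor_mod <- mantel_correlogram(d_mod, geo,
                                 class_width_km = config$class_width_km,
                                 n_perm = config$n_perm,
                                 alpha = config$alpha, seed = seed_sp + 2)
  env_mantel <- env_mantel_table(d_pre, d_mod, towns,
                                 n_perm = config$n_perm, seed = seed_sp + 3)

  # --- ordination -----------------------------------------------------------
  stacked <- rbind(pre, mod)
  rownames(stacked) <- c(paste0(rownames(pre), "_pre"),
                         paste0(rownames(mod), "_mod"))
  era <- rep(c("precolonial", "modern"), each = nrow(pre))
  wis <- wisconsin_standardize(stacked)
  ord <- nmds(sorensen_matrix(wis), k = config$nmds_k,
              n_starts = config$nmds_starts,
              seed = .stage_seed(config$seed, "ordination"))
  env_rows <- rbind(towns, towns)
  envfit <- env_vector_fit(ord$points,
                           env_rows[, intersect(config$ctree_predictors,
                                                names(env_rows)),
                                    drop = FALSE],
                           n_perm = config$n_perm,
                           seed = .stage_seed(config$seed, "ordination") + 1)
  separation <- era_axis_separation(ord, era)

  # --- regression tree --------------------------------------------------------
  Xp <- towns[, intersect(config$ctree_predictors, names(towns)),
              drop = FALSE]
  tree <- fit_change_tree(Xp, change$change, alpha = config$alpha,
                          n_perm = config$ctree_n_perm,
                          min_node = config$ctree_min_node,
                          seed = .stage_seed(config$seed, "tree"))

  # --- write outputs ------------------------------------------------------------
  w <- function(df, name) utils::write.csv(
    df, file.path(config$outdir, name), row.names = FALSE)
  w(data.frame(town_id = names(change$change), change = change$change),
    "change_per_town.csv")
  w(abundance, "abundance_change.csv")
  w(beta$per_town, "beta_per_town.csv")
  w(as.data.frame(thresholds), "adequacy_thresholds.csv")
  w(as.data.frame(moran), "moran_correlogram.csv")
  w(cbind(era = "precolonial", as.data.frame(mcor_pre)),
    "mantel_correlogram_pre.csv")
  w(cbind(era = "modern", as.data.frame(mcor_mod)),
    "mantel_correlogram_mod.csv")
  w(env_mantel, "env_mantel.csv")
  w(data.frame(row = rownames(ord$points), era = era, ord$points),
    "nmds_coordinates.csv")
  w(as.data.frame(envfit), "envfit.csv")
  w(tree_report(tree), "tree_report.csv")
  manifest$stress <- ord$stress
  manifest$separation <- separation
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  structure(list(thresholds = thresholds, included = included,
                 pre = pre, mod = mod, towns = towns, change = change,
                 abundance = abundance, beta = beta, geo = geo,
                 moran = moran, mantel_correlogram_pre = mcor_pre,
                 mantel_correlogram_mod = mcor_mod,
                 env_mantel = env_mantel, ordination = ord,
                 envfit = envfit, separation = separation, tree = tree,
                 manifest = manifest, config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("forestshift pipeline result\n")
  cat("  towns analysed:", length(x$included), "\n")
  cat(sprintf("  mean change %.3f (sd %.3f)\n",
              x$change$regional["mean"], x$change$regional["sd"]))
  cat(sprintf("  beta diversity: pre %.3f, modern %.3f\n",
              x$beta$era_summary$mean[1], x$beta$era_summary$mean[2]))
  cat(sprintf("  NMDS stress (k = %d): %.4f\n", x$ordination$k,
              x$ordination$stress))
  invisible(x)
}
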