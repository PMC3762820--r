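#' Bootstrap similarity curve over sampling units
#'
#' For each of `n_sets` bootstrap sets and each sample size `n = 1..N`
#' (N = number of units), draws `n` units (with replacement by default),
#' pools their stem counts, and records the Sorensen *similarity*
#' (1 - Sorensen distance) between the pooled sample composition and the
#' full-town composition. Similarity rises steeply with `n` and then
#' saturates as composition stabilizes.
#'
#' @param unit_counts Units x taxa matrix of stem counts (one row per FIA
#'   plot, or per witness-tree bin).
#' @param n_sets Number of bootstrap sets (default 100).
#' @param replace Sample units with replacement (`TRUE`, the production
#'   mode). `FALSE` is a test mode in which the full-census sample
#'   reproduces similarity 1 exactly.
#' @param seed Optional seed.
#' @return Data frame: `set`, `n`, `similarity`.
#' @export
bootstrap_curve <- function(unit_counts, n_sets = 100, replace = TRUE,
                            seed = NULL) {
  stopifnot(is.matrix(unit_counts), nrow(unit_counts) >= 1)
  if (!is.null(seed)) set.seed(seed)
  N <- nrow(unit_counts)
  full <- colSums(unit_counts)
  full_p <- full / sum(full)
  rows <- vector("list", n_sets)
  for (s in seq_len(n_sets)) {
    sim <- vapply(seq_len(N), function(n) {
      idx <- sample.int(N, n, replace = replace)
      pooled <- colSums(unit_counts[idx, , drop = FALSE])
      1 - sorensen(pooled / sum(pooled), full_p)
    }, numeric(1))
    rows[[s]] <- data.frame(set = s, n = seq_len(N), similarity = sim)
  }
  do.call(rbind, rows)
}

#' Bootstrap similarity curve for witness trees, binned in twenties
#'
#' Witness trees have no plot structure, so each bootstrap set first
#' partitions the town's trees at random into bins of `bin_size` (leftover
#' trees, count mod `bin_size`, are dropped; bins are re-randomized every
#' set) and then proceeds as [bootstrap_curve()] with bins as units.
#'
#' @param codes Character vector of taxon codes, one per witness tree.
#' @param bin_size Trees per bin (default 20).
#' @param n_sets Number of bootstrap sets.
#' @param taxa Taxa vocabulary for the count matrices.
#' @param replace Sample bins with replacement (see [bootstrap_curve()]).
#' @param seed Optional seed.
#' @return Data frame: `set`, `n`, `similarity`.
#' @export
bootstrap_curve_wt <- function(codes, bin_size = 20, n_sets = 100,
                               taxa = taxon_codes(), replace = TRUE,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_bins <- length(codes) %/% bin_size
  if (n_bins < 1) stop("fewer than one full bin of witness trees")
  rows <- vector("list", n_sets)
  for (s in seq_len(n_sets)) {
    idx <- sample.int(length(codes))[seq_len(n_bins * bin_size)]
    bin <- rep(seq_len(n_bins), each = bin_size)
    counts <- table(factor(bin), factor(codes[idx], levels = taxa))
    counts <- matrix(counts, nrow = n_bins, dimnames = list(NULL, taxa))
    cur <- bootstrap_curve(counts, n_sets = 1, replace = replace)
    cur$set <- s
    rows[[s]] <- cur
  }
  do.call(rbind, rows)
}

#' Fit a Michaelis-Menten saturation curve through the origin
#'
#' Least-squares fit of `y = s_max * n / (k + n)`. At 90 percent of the
#' asymptote, `0.9 * s_max = s_max * n / (k + n)` gives the analytic
#' identity `n = 9 * k`, so the minimum adequate unit count is
#' `d_min_units = k * proportion / (1 - proportion)`.
#'
#' @param n Unit counts (at least 3 distinct values).
#' @param similarity Similarity values in `[0, 1]`.
#' @param proportion Fraction of the asymptote defining adequacy
#'   (default 0.9).
#' @return List of class `mm_fit`: `s_max`, `k_half`, `d_min_units`, `rss`,
#'   `converged`. Non-convergent or degenerate fits return
#'   `converged = FALSE` (callers exclude them from threshold averaging).
#' @export
fit_mm <- function(n, similarity, proportion = 0.9) {
  stopifnot(length(n) == length(similarity), proportion > 0, proportion < 1)
  if (length(unique(n)) < 3)
    return(structure(list(s_max = NA_real_, k_half = NA_real_,
                          d_min_units = NA_real_, rss = NA_real_,
                          converged = FALSE), class = "mm_fit"))
  df <- data.frame(x = n, y = similarity)
  fit <- tryCatch(
    stats::nls(y ~ SSmicmen(x, Vm, K), data = df),
    error = function(e) tryCatch(
      minpack.lm::nlsLM(y ~ Vm * x / (K + x), data = df,
                        start = list(Vm = max(df$y), K = 1),
                        lower = c(1e-8, 1e-8)),
      error = function(e2) NULL))
  if (is.null(fit)) {
    return(structure(list(s_max = NA_real_, k_half = NA_real_,
                          d_min_units = NA_real_, rss = NA_real_,
                          converged = FALSE), class = "mm_fit"))
  }
  cf <- stats::coef(fit)
  ok <- is.finite(cf["Vm"]) && is.finite(cf["K"]) && cf["K"] > 0 &&
    cf["Vm"] > 0
  structure(list(s_max = unname(cf["Vm"]), k_half = unname(cf["K"]),
                 d_min_units = unname(cf["K"]) * proportion /
                   (1 - proportion),
                 rss = sum(stats::resid(fit)^2), converged = ok),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf(
    "M-M fit: s_max = %.4f, k_half = %.4f, d_min_units = %.4f (%s)\n",
    x$s_max, x$k_half, x$d_min_units,
    if (x$converged) "converged" else "FLAGGED"))
  invisible(x)
}

# Per-town unit-count builders -------------------------------------------

.plot_count_matrix <- function(trees, plot_ids, taxa = taxon_codes()) {
  trees <- trees[trees$taxon_code %in% taxa, , drop = FALSE]
  counts <- table(factor(trees$plot_id, levels = plot_ids),
                  factor(trees$taxon_code, levels = taxa))
  matrix(counts, nrow = length(plot_ids), dimnames = list(plot_ids, taxa))
}

#' Per-town mean minimum sampling density
#'
#' Fits one M-M curve per bootstrap set and averages the implied minimum
#' density (units per km^2) over the converged sets.
#'
#' @param curve Output of [bootstrap_curve()] / [bootstrap_curve_wt()].
#' @param area_km2 Town area.
#' @param units_per_sample Stems represented by one unit (1 for FIA plots;
#'   the bin size for witness-tree bins, so the density is expressed in
#'   trees per km^2).
#' @param proportion See [fit_mm()].
#' @return List: `d_min_density` (mean over converged sets), `n_converged`,
#'   `n_sets`.
#' @export
town_dmin <- function(curve, area_km2, units_per_sample = 1,
                      proportion = 0.9) {
  stopifnot(area_km2 > 0)
  per_set <- vapply(split(curve, curve$set), function(cs) {
    f <- fit_mm(cs$n, cs$similarity, proportion)
    if (f$converged) f$d_min_units * units_per_sample / area_km2
    else NA_real_
  }, numeric(1))
  list(d_min_density = mean(per_set, na.rm = TRUE),
       n_converged = sum(!is.na(per_set)), n_sets = length(per_set))
}

#' Ecoregion minimum sampling-density thresholds
#'
#' The seven-step screen: within each ecoregion, take the most densely
#' sampled towns (FIA path: at least `min_plots` plots and within the upper
#' tercile of plot density; witness-tree path: at least `min_wts` trees and
#' within the upper tercile of tree density; tercile boundaries closed,
#' computed within ecoregion), run `n_sets` bootstrap sets per town, fit a
#' Michaelis-Menten curve per set, convert the `proportion`-of-asymptote
#' unit count to a density via the town's area, average over sets, then
#' average over towns to get the ecoregion grand mean threshold.
#'
#' @param dataset A filtered `forest_dataset` (see [filter_modern()]).
#' @param n_sets Bootstrap sets per town (default 100).
#' @param proportion Fraction of the asymptote defining adequacy.
#' @param min_plots,min_wts Eligibility floors for the two paths.
#' @param bin_size Witness-tree bin size.
#' @param seed Optional seed.
#' @return Data frame of class `adequacy_thresholds`: `ecoregion`,
#'   `d_min_plots_km2`, `n_towns_fia`, `d_min_wts_km2`, `n_towns_wt`.
#'   Ecoregions with no eligible town get `NA` with a warning.
#' @export
ecoregion_thresholds <- function(dataset, n_sets = 100, proportion = 0.9,
                                 min_plots = 5, min_wts = 100,
                                 bin_size = 20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  towns <- dataset$towns
  dens <- town_sampling_density(dataset)
  towns <- merge(towns[, c("town_id", "ecoregion", "area_km2")], dens,
                 by = "town_id")
  trees <- dataset$trees
  modern <- trees[trees$era == "modern", , drop = FALSE]
  wt <- trees[trees$era == "precolonial" & trees$taxon_code != UNBINNED, ,
              drop = FALSE]

  rows <- lapply(sort(unique(towns$ecoregion)), function(eco) {
    te <- towns[towns$ecoregion == eco, , drop = FALSE]
    # FIA path
    cand <- te[te$n_plots >= min_plots, , drop = FALSE]
    fia_d <- NA_real_; n_fia <- 0L
    if (nrow(cand) > 0) {
      cut3 <- stats::quantile(cand$plot_density, 2 / 3)
      elig <- cand[cand$plot_density >= cut3, , drop = FALSE]
      vals <- vapply(seq_len(nrow(elig)), function(i) {
        tid <- elig$town_id[i]
        pids <- dataset$plots$plot_id[dataset$plots$town_id == tid]
        cm <- .plot_count_matrix(modern[modern$town_id == tid, ], pids)
        cur <- bootstrap_curve(cm, n_sets = n_sets)
        town_dmin(cur, elig$area_km2[i], 1, proportion)$d_min_density
      }, numeric(1))
      vals <- vals[is.finite(vals)]
      if (length(vals)) { fia_d <- mean(vals); n_fia <- length(vals) }
    }
    # WT path
    cand <- te[te$n_wts >= min_wts, , drop = FALSE]
    wt_d <- NA_real_; n_wt <- 0L
    if (nrow(cand) > 0) {
      cut3 <- stats::quantile(cand$wt_density, 2 / 3)
      elig <- cand[cand$wt_density >= cut3, , drop = FALSE]
      vals <- vapply(seq_len(nrow(elig)), function(i) {
        tid <- elig$town_id[i]
        codes <- wt$taxon_code[wt$town_id == tid]
        cur <- bootstrap_curve_wt(codes, bin_size = bin_size,
                                  n_sets = n_sets)
        town_dmin(cur, elig$area_km2[i], bin_size,
                  proportion)$d_min_density
      }, numeric(1))
      vals <- vals[is.finite(vals)]
      if (length(vals)) { wt_d <- mean(vals); n_wt <- length(vals) }
    }
    if (n_fia == 0L || n_wt == 0L)
      warning("ecoregion ", eco, " has no eligible town on at least one ",
              "path; threshold undefined")
    data.frame(ecoregion = eco, d_min_plots_km2 = fia_d, n_towns_fia = n_fia,
               d_min_wts_km2 = wt_d, n_towns_wt = n_wt,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("adequacy_thresholds", "data.frame")
  out
}

#' Per-town sampling densities
#'
#' @param dataset A `forest_dataset`.
#' @return Data frame: `town_id`, `n_plots`, `n_wts`, `plot_density`,
#'   `wt_density` (units per km^2).
#' @export
town_sampling_density <- function(dataset) {
  towns <- dataset$towns
  n_plots <- table(factor(dataset$plots$town_id, levels = towns$town_id))
  wt <- dataset$trees[dataset$trees$era == "precolonial", , drop = FALSE]
  n_wts <- table(factor(wt$town_id, levels = towns$town_id))
  data.frame(town_id = towns$town_id,
             n_plots = as.integer(n_plots),
             n_wts = as.integer(n_wts),
             plot_density = as.integer(n_plots) / towns$area_km2,
             wt_density = as.integer(n_wts) / towns$area_km2,
             stringsAsFactors = FALSE)
}

#' Screen towns against the ecoregion sampling thresholds
#'
#' A town is included iff its witness-tree density meets the witness-tree
#' threshold AND its plot density meets the plot threshold for its
#' ecoregion (both per km^2; towns exactly at a threshold are included).
#'
#' @param dataset A `forest_dataset`.
#' @param thresholds Output of [ecoregion_thresholds()].
#' @return Character vector of included town ids.
#' @export
screen_towns <- function(dataset, thresholds) {
  towns <- dataset$towns
  present <- unique(towns$ecoregion)
  th <- thresholds[match(towns$ecoregion, thresholds$ecoregion), ]
  if (anyNA(th$ecoregion))
    stop("thresholds missing for ecoregion(s): ",
         paste(setdiff(present, thresholds$ecoregion), collapse = ", "))
  dens <- town_sampling_density(dataset)
  ok <- dens$wt_density >= th$d_min_wts_km2 &
    dens$plot_density >= th$d_min_plots_km2
  ok[is.na(ok)] <- FALSE
  towns$town_id[ok]
}
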