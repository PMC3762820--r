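#' Great-circle distance matrix between town centroids
#'
#' Haversine distances (sphere radius 6371 km) between centroid coordinates;
#' at the ~8 degrees of latitude the study region spans, planar
#' approximations drift, so geodesic distances are used throughout.
#'
#' @param towns Data frame with `town_id`, `centroid_lon`, `centroid_lat`.
#' @return Symmetric matrix of distances in km, zero diagonal, dimnames =
#'   town ids.
#' @export
geo_distances <- function(towns) {
  stopifnot(all(c("town_id", "centroid_lon", "centroid_lat") %in%
                  names(towns)))
  if (anyNA(towns$centroid_lon) || anyNA(towns$centroid_lat))
    stop("missing centroid coordinates")
  pts <- as.matrix(towns[, c("centroid_lon", "centroid_lat")])
  d <- geosphere::distm(pts, fun = function(p1, p2)
    geosphere::distHaversine(p1, p2, r = 6371000)) / 1000
  dimnames(d) <- list(towns$town_id, towns$town_id)
  d
}

#' Moran's I for a scalar with a binary weight matrix
#'
#' `I = (n / W) * sum_ij w_ij z_i z_j / sum_i z_i^2` with `z` the centered
#' values and `W = sum_ij w_ij`. Expectation under randomization is
#' `-1 / (n - 1)`.
#'
#' @param values Numeric vector.
#' @param w Symmetric weight matrix (diagonal ignored).
#' @return Moran's I.
#' @export
morans_i <- function(values, w) {
  n <- length(values)
  stopifnot(nrow(w) == n, ncol(w) == n)
  diag(w) <- 0
  W <- sum(w)
  if (W == 0) return(NA_real_)
  z <- values - mean(values)
  if (sum(z^2) == 0) stop("constant values: Moran's I undefined")
  (n / W) * as.numeric(t(z) %*% w %*% z) / sum(z^2)
}

#' Moran's I spatial correlogram
#'
#' Binary weights per half-open distance class `[lower, upper)`; per-class
#' significance from a permutation test of the values over towns. Two-sided
#' p-values are reported as `2 * min(P(I* >= I), P(I* <= I))` with the
#' add-one convention, capped at 1. By default classes are evaluated only up
#' to half the maximum inter-town distance (edge-effect guard).
#'
#' @param values Named per-town scalar (e.g. per-town Sorensen change).
#' @param geo Geographic distance matrix in km (same ordering).
#' @param class_width_km Uniform class width (default 15).
#' @param n_perm Permutations per class (default 999).
#' @param alpha Nominal significance level recorded in the output.
#' @param max_dist_km Upper end of the evaluated range; default half the
#'   maximum observed distance.
#' @param seed Optional seed.
#' @return Data frame of class `correlogram_result`: `lower`, `upper`,
#'   `midpoint`, `n_pairs`, `statistic` (Moran's I; `NA` for empty classes),
#'   `expectation`, `p`, `significant`.
#' @export
morans_correlogram <- function(values, geo, class_width_km = 15,
                               n_perm = 999, alpha = 0.05,
                               max_dist_km = NULL, seed = NULL) {
  n <- length(values)
  stopifnot(nrow(geo) == n)
  if (stats::sd(values) == 0) stop("constant values: Moran's I undefined")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(max_dist_km)) max_dist_km <- max(geo) / 2
  edges <- seq(0, max_dist_km + class_width_km, by = class_width_km)
  rows <- lapply(seq_len(length(edges) - 1), function(k) {
    lo <- edges[k]; hi <- edges[k + 1]
    w <- (geo >= lo & geo < hi) * 1
    diag(w) <- 0
    n_pairs <- sum(w) / 2
    if (n_pairs < 1) {
      return(data.frame(lower = lo, upper = hi, midpoint = (lo + hi) / 2,
                        n_pairs = 0, statistic = NA_real_,
                        expectation = -1 / (n - 1), p = NA_real_,
                        significant = NA))
    }
    obs <- morans_i(values, w)
    null <- vapply(seq_len(n_perm), function(r)
      morans_i(values[sample.int(n)], w), numeric(1))
    p_hi <- (1 + sum(null >= obs)) / (1 + n_perm)
    p_lo <- (1 + sum(null <= obs)) / (1 + n_perm)
    p <- min(1, 2 * min(p_hi, p_lo))
    data.frame(lower = lo, upper = hi, midpoint = (lo + hi) / 2,
               n_pairs = n_pairs, statistic = obs,
               expectation = -1 / (n - 1), p = p, significant = p < alpha)
  })
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  attr(out, "kind") <- "morans_i"
  class(out) <- c("correlogram_result", "data.frame")
  out
}

.upper_tri <- function(m) m[upper.tri(m)]

#' Mantel test between two distance matrices
#'
#' `r_M` is the Pearson correlation over the `n(n-1)/2` upper-triangle
#' entries; significance comes from jointly permuting rows and columns of
#' the second matrix.
#'
#' @param a,b Symmetric matrices with identical ordering.
#' @param n_perm Permutations (default 999).
#' @param alternative `"greater"` (the classic one-sided Mantel test,
#'   default) or `"two.sided"`.
#' @param seed Optional seed.
#' @return List of class `mantel_result`: `r_m`, `p`, `n_perm`,
#'   `alternative`.
#' @export
mantel_test <- function(a, b, n_perm = 999, alternative = "greater",
                        seed = NULL) {
  n <- nrow(a)
  stopifnot(ncol(a) == n, nrow(b) == n, ncol(b) == n)
  if (n < 4) stop("need at least 4 objects for a Mantel test")
  if (!is.null(seed)) set.seed(seed)
  va <- .upper_tri(a)
  if (stats::sd(va) == 0 || stats::sd(.upper_tri(b)) == 0)
    stop("zero variance in a distance-matrix triangle")
  obs <- stats::cor(va, .upper_tri(b))
  null <- vapply(seq_len(n_perm), function(r) {
    idx <- sample.int(n)
    stats::cor(va, .upper_tri(b[idx, idx]))
  }, numeric(1))
  p_hi <- (1 + sum(null >= obs)) / (1 + n_perm)
  p_lo <- (1 + sum(null <= obs)) / (1 + n_perm)
  p <- switch(alternative,
              greater = p_hi,
              two.sided = min(1, 2 * min(p_hi, p_lo)),
              stop("unknown alternative: ", alternative))
  structure(list(r_m = obs, p = p, n_perm = n_perm,
                 alternative = alternative),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel r_M = %.4f, p = %.4g (%s, %d permutations)\n",
              x$r_m, x$p, x$alternative, x$n_perm))
  invisible(x)
}

#' Mantel correlogram of composition against geographic distance classes
#'
#' Per half-open class `[lower, upper)`, the Mantel correlation between the
#' composition distance matrix and the binary class-membership matrix. The
#' raw correlation is negated so that positive `r_M` means towns within the
#' class are compositionally more similar than expected by chance (members
#' have membership 1 but small composition distance). Significance is a
#' two-sided permutation test per class with a plain Bonferroni correction
#' across all evaluated classes.
#'
#' @param comp Composition distance matrix.
#' @param geo Geographic distance matrix in km (same ordering).
#' @param class_width_km Class width (default 15).
#' @param n_perm Permutations per class.
#' @param alpha Familywise level before Bonferroni division.
#' @param max_dist_km Default half the maximum observed distance.
#' @param seed Optional seed.
#' @return Data frame of class `correlogram_result`: `lower`, `upper`,
#'   `midpoint`, `n_pairs`, `statistic` (sign-corrected `r_M`), `p` (raw),
#'   `p_corrected_alpha` (the Bonferroni threshold used), `significant`.
#'   Classes whose membership is constant over pairs are degenerate and
#'   reported `NA`.
#' @export
mantel_correlogram <- function(comp, geo, class_width_km = 15, n_perm = 999,
                               alpha = 0.05, max_dist_km = NULL,
                               seed = NULL) {
  n <- nrow(geo)
  stopifnot(nrow(comp) == n, ncol(comp) == n, ncol(geo) == n)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(max_dist_km)) max_dist_km <- max(geo) / 2
  edges <- seq(0, max_dist_km + class_width_km, by = class_width_km)
  vc <- .upper_tri(comp)
  rows <- lapply(seq_len(length(edges) - 1), function(k) {
    lo <- edges[k]; hi <- edges[k + 1]
    memb <- (geo >= lo & geo < hi) * 1
    diag(memb) <- 0
    vm <- .upper_tri(memb)
    n_pairs <- sum(vm)
    if (n_pairs < 1 || stats::sd(vm) == 0) {
      return(data.frame(lower = lo, upper = hi, midpoint = (lo + hi) / 2,
                        n_pairs = n_pairs, statistic = NA_real_,
                        p = NA_real_, significant = NA))
    }
    obs <- -stats::cor(vc, vm)  # negated: + => more similar within class
    null <- vapply(seq_len(n_perm), function(r) {
      idx <- sample.int(n)
      m2 <- memb[idx, idx]
      -stats::cor(vc, .upper_tri(m2))
    }, numeric(1))
    p_hi <- (1 + sum(null >= obs)) / (1 + n_perm)
    p_lo <- (1 + sum(null <= obs)) / (1 + n_perm)
    p <- min(1, 2 * min(p_hi, p_lo))
    data.frame(lower = lo, upper = hi, midpoint = (lo + hi) / 2,
               n_pairs = n_pairs, statistic = obs, p = p,
               significant = NA)
  })
  out <- do.call(rbind, rows)
  n_eval <- sum(!is.na(out$p))
  out$p_corrected_alpha <- alpha / max(1, n_eval)
  out$significant <- !is.na(out$p) & out$p < out$p_corrected_alpha
  attr(out, "alpha") <- alpha
  attr(out, "kind") <- "mantel"
  class(out) <- c("correlogram_result", "data.frame")
  out
}

#' Mantel correlations between composition and environmental covariates
#'
#' For each covariate, the environmental distance between towns is the
#' absolute difference of the scalar covariate; `r_M` and a permutation p
#' are computed per era.
#'
#' @param comp_pre,comp_mod Composition distance matrices, same town order
#'   as `towns`.
#' @param towns Data frame of per-town covariates.
#' @param covariates Covariate column names (skipped with a warning if
#'   absent or constant).
#' @param n_perm Permutations per test.
#' @param seed Optional seed.
#' @return Data frame: `covariate`, `era`, `r_m`, `p`.
#' @export
env_mantel_table <- function(comp_pre, comp_mod, towns,
                             covariates = c("gdd", "precip_mm",
                                            "elevation_m", "sand_pct"),
                             n_perm = 999, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (cv in covariates) {
    if (!cv %in% names(towns) || stats::sd(towns[[cv]]) == 0) {
      warning("covariate skipped: ", cv)
      next
    }
    env_d <- abs(outer(towns[[cv]], towns[[cv]], "-"))
    for (era in c("precolonial", "modern")) {
      cd <- if (era == "precolonial") comp_pre else comp_mod
      mt <- mantel_test(cd, env_d, n_perm = n_perm)
      rows[[length(rows) + 1]] <- data.frame(
        covariate = cv, era = era, r_m = mt$r_m, p = mt$p,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
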