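#' Wisconsin double standardization
#'
#' Divides each column by its maximum, then each row by its sum. All-zero
#' columns (taxa absent everywhere in scope) are dropped with a warning;
#' all-zero rows are an error.
#'
#' @param m Nonnegative numeric matrix (towns x taxa).
#' @return Standardized matrix; rows sum to 1.
#' @examples
#' wisconsin_standardize(matrix(c(2, 1, 0, 1), 2))
#' @export
wisconsin_standardize <- function(m) {
  stopifnot(is.matrix(m), all(m >= 0))
  zero_col <- colSums(m) == 0
  if (any(zero_col)) {
    warning("dropping all-zero column(s): ",
            paste(colnames(m)[zero_col], collapse = ", "))
    m <- m[, !zero_col, drop = FALSE]
  }
  if (any(rowSums(m) == 0)) stop("all-zero row(s) in matrix")
  m <- sweep(m, 2, apply(m, 2, max), "/")
  sweep(m, 1, rowSums(m), "/")
}

#' Non-metric multidimensional scaling of a distance matrix
#'
#' Minimizes Kruskal stress-1 via monotone regression of configuration
#' distances on dissimilarity ranks (vegan's `monoMDS` engine under
#' `metaMDS`-style restarts), keeping the best of `n_starts` random starts.
#' The returned configuration is centered and rotated to its principal
#' components so axis 1 carries maximal variance. Half-change scaling is
#' deliberately omitted (a presentation-only rescaling; stress and the
#' era-separation readout are unaffected).
#'
#' @param d Symmetric dissimilarity matrix (or `dist`).
#' @param k Number of axes.
#' @param n_starts Random starts (default 50).
#' @param max_iter Iterations per start.
#' @param seed Optional seed.
#' @return List of class `nmds_result`: `points` (n x k, PC-rotated),
#'   `stress` (Kruskal stress-1 in `[0, 1]`), `converged`, `k`, `n_starts`.
#' @export
nmds <- function(d, k = 2, n_starts = 50, max_iter = 200, seed = NULL) {
  if (!inherits(d, "dist")) {
    stopifnot(is.matrix(d), nrow(d) == ncol(d))
    d <- stats::as.dist(d)
  }
  n <- attr(d, "Size")
  if (n < k + 2) stop("need at least k + 2 objects")
  v <- as.vector(d)
  if (stats::sd(v) == 0) stop("all dissimilarities equal; NMDS undefined")
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  for (s in seq_len(n_starts)) {
    fit <- vegan::monoMDS(d, k = k, maxit = max_iter)
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  pts <- scale(best$points, center = TRUE, scale = FALSE)
  pc <- stats::prcomp(pts, center = FALSE)
  pts <- pc$x[, seq_len(k), drop = FALSE]
  colnames(pts) <- paste0("axis", seq_len(k))
  rownames(pts) <- attr(d, "Labels")
  structure(list(points = pts, stress = best$stress,
                 converged = best$maxits == 0 || best$stress < 1,
                 k = k, n_starts = n_starts),
            class = "nmds_result")
}

#' @export
print.nmds_result <- function(x, ...) {
  cat(sprintf("NMDS: k = %d, stress = %.4f (best of %d starts)\n",
              x$k, x$stress, x$n_starts))
  invisible(x)
}

#' Stress scree over candidate dimensionalities
#'
#' Runs [nmds()] for each `k` and tabulates the final stress, the standard
#' device for choosing the number of axes.
#'
#' @param d Dissimilarity matrix.
#' @param k_max Largest dimensionality (default 4).
#' @param n_starts,seed Passed to [nmds()].
#' @return Data frame: `k`, `stress`.
#' @export
nmds_scree <- function(d, k_max = 4, n_starts = 20, seed = NULL) {
  data.frame(k = seq_len(k_max),
             stress = vapply(seq_len(k_max), function(k)
               nmds(d, k = k, n_starts = n_starts, seed = seed)$stress,
               numeric(1)))
}

#' Fit environmental vectors onto ordination axes
#'
#' For each covariate, a least-squares regression of the (standardized)
#' covariate on the ordination axes gives its direction cosines and R^2;
#' significance comes from permuting the covariate over rows.
#'
#' @param coords n x k matrix of ordination coordinates.
#' @param covariates Data frame (one row per ordinated row).
#' @param n_perm Permutations (default 999).
#' @param seed Optional seed.
#' @return Data frame of class `envfit_result`: `covariate`, one direction
#'   column per axis (unit norm), `r2`, `p`. Constant covariates are
#'   skipped with a warning.
#' @export
env_vector_fit <- function(coords, covariates, n_perm = 999, seed = NULL) {
  stopifnot(is.matrix(coords), nrow(coords) == nrow(covariates))
  if (!is.null(seed)) set.seed(seed)
  X <- scale(coords, center = TRUE, scale = FALSE)
  fit_one <- function(y) {
    b <- stats::coef(stats::lm.fit(X, y - mean(y)))
    pred <- X %*% b
    r2 <- sum(pred^2) / sum((y - mean(y))^2)
    list(b = b, r2 = r2)
  }
  rows <- list()
  for (cv in names(covariates)) {
    y <- covariates[[cv]]
    if (!is.numeric(y) || stats::sd(y) == 0) {
      warning("covariate skipped: ", cv)
      next
    }
    f <- fit_one(y)
    null <- vapply(seq_len(n_perm), function(r)
      fit_one(y[sample.int(length(y))])$r2, numeric(1))
    p <- (1 + sum(null >= f$r2)) / (1 + n_perm)
    dir <- f$b / sqrt(sum(f$b^2))
    row <- data.frame(covariate = cv, t(dir), r2 = f$r2, p = p,
                      stringsAsFactors = FALSE)
    names(row)[2:(1 + ncol(coords))] <- colnames(coords)
    rows[[length(rows) + 1]] <- row
  }
  if (length(rows) == 0) {
    out <- data.frame(covariate = character(0), r2 = numeric(0),
                      p = numeric(0))
  } else {
    out <- do.call(rbind, rows)
  }
  class(out) <- c("envfit_result", "data.frame")
  out
}

#' Era separation along the ordination's best-separating axis
#'
#' Stacked pre-colonial + modern town scores are compared on the axis that
#' maximizes the standardized between-era mean separation; the axis sign is
#' fixed so that the pre-colonial mean is negative. Reports the fraction of
#' pre-colonial rows below zero and of modern rows above zero (both near 1
#' for well-separated eras, near 0.5 for identical eras).
#'
#' @param ord An `nmds_result` over stacked pre+modern rows.
#' @param era Character vector (`"precolonial"`/`"modern"`), one per row.
#' @return List: `axis` (index used), `frac_pre_below`, `frac_mod_above`.
#' @export
era_axis_separation <- function(ord, era) {
  pts <- ord$points
  stopifnot(nrow(pts) == length(era))
  pre <- era == "precolonial"
  sep <- vapply(seq_len(ncol(pts)), function(j) {
    s <- stats::sd(pts[, j])
    if (s == 0) return(0)
    abs(mean(pts[pre, j]) - mean(pts[!pre, j])) / s
  }, numeric(1))
  ax <- which.max(sep)
  v <- pts[, ax]
  if (mean(v[pre]) > mean(v[!pre])) v <- -v
  list(axis = ax,
       frac_pre_below = mean(v[pre] < 0),
       frac_mod_above = mean(v[!pre] > 0))
}
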