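#' Permutation-based conditional inference regression tree
#'
#' Recursive partitioning of a numeric response on numeric predictors in
#' which every split must first pass a permutation test: at each node the
#' association between each predictor and the response is measured by
#' `T = |Pearson correlation|`, its p-value comes from `n_perm` permutations
#' of the response, and the p-values are Bonferroni-adjusted across
#' predictors. The node becomes a leaf if the smallest adjusted p is not
#' below `alpha` (so no pruning is needed); otherwise the winning predictor
#' is split at the cutpoint maximizing the standardized two-sample mean
#' difference, subject to `min_node` rows on both sides, and the children
#' are processed recursively. This is a deliberately simplified linear-
#' statistic variant of the conditional-inference tree algorithm (no
#' quadratic-form/strucchange machinery).
#'
#' @param X Data frame of numeric predictors. Rows with any missing value
#'   are dropped with a message.
#' @param y Numeric response (per-town compositional change).
#' @param alpha Significance level for the split test (default 0.05).
#' @param n_perm Permutations per node (default 9999; must be >= 99).
#' @param min_node Minimum rows per child (default 20).
#' @param seed Optional seed.
#' @return Object of class `change_tree`: recursive node list. Split nodes
#'   carry `predictor`, `threshold` (midpoint between adjacent observed
#'   values), `p_adjusted`, `n`, `left`, `right`; leaves carry `mean`, `n`.
#' @export
fit_change_tree <- function(X, y, alpha = 0.05, n_perm = 9999,
                            min_node = 20, seed = NULL) {
  stopifnot(is.data.frame(X), nrow(X) == length(y))
  if (n_perm < 99) stop("n_perm must be at least 99 for p resolution")
  if (!all(vapply(X, is.numeric, logical(1))))
    stop("all predictors must be numeric")
  keep <- stats::complete.cases(X) & !is.na(y)
  if (any(!keep)) {
    message("dropping ", sum(!keep), " row(s) with missing values")
    X <- X[keep, , drop = FALSE]
    y <- y[keep]
  }
  if (!is.null(seed)) set.seed(seed)
  node <- .grow_node(as.matrix(X), y, alpha, n_perm, min_node)
  structure(list(root = node, alpha = alpha, n_perm = n_perm,
                 min_node = min_node, predictors = colnames(X),
                 n = length(y)),
            class = "change_tree")
}

.node_test <- function(X, y, n_perm) {
  n <- length(y)
  sds <- apply(X, 2, stats::sd)
  usable <- sds > 0
  t_obs <- rep(0, ncol(X))
  t_obs[usable] <- abs(suppressWarnings(
    stats::cor(X[, usable, drop = FALSE], y)))
  # one permutation of y tests all predictors at once
  Yp <- matrix(y[c(replicate(n_perm, sample.int(n)))], nrow = n)
  t_null <- abs(suppressWarnings(
    stats::cor(X[, usable, drop = FALSE], Yp)))
  p <- rep(1, ncol(X))
  p[usable] <- (1 + rowSums(t_null >= t_obs[usable])) / (1 + n_perm)
  list(p_adjusted = pmin(1, p * ncol(X)), statistic = t_obs)
}

.best_cut <- function(x, y, min_node) {
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]
  n <- length(ys)
  csum <- cumsum(ys); csq <- cumsum(ys^2)
  tot <- csum[n]; totsq <- csq[n]
  best <- list(stat = -Inf, threshold = NA_real_)
  for (i in seq_len(n - 1)) {
    if (i < min_node || (n - i) < min_node) next
    if (xs[i] == xs[i + 1]) next  # cannot cut inside a tie
    nl <- i; nr <- n - i
    ml <- csum[i] / nl; mr <- (tot - csum[i]) / nr
    ssl <- csq[i] - nl * ml^2
    ssr <- (totsq - csq[i]) - nr * mr^2
    s2 <- (ssl + ssr) / (n - 2)
    stat <- if (s2 > 0) abs(ml - mr) / sqrt(s2 * (1 / nl + 1 / nr))
            else abs(ml - mr) * Inf
    if (stat > best$stat)
      best <- list(stat = stat, threshold = (xs[i] + xs[i + 1]) / 2)
  }
  best
}

.grow_node <- function(X, y, alpha, n_perm, min_node) {
  n <- length(y)
  leaf <- list(type = "leaf", mean = mean(y), n = n)
  if (n < 2 * min_node || stats::sd(y) == 0) return(leaf)
  test <- .node_test(X, y, n_perm)
  j <- which.min(test$p_adjusted)
  if (test$p_adjusted[j] >= alpha) return(leaf)
  cut <- .best_cut(X[, j], y, min_node)
  if (!is.finite(cut$threshold)) return(leaf)
  left <- X[, j] <= cut$threshold
  list(type = "split", predictor = colnames(X)[j],
       threshold = cut$threshold, p_adjusted = test$p_adjusted[j], n = n,
       left = .grow_node(X[left, , drop = FALSE], y[left], alpha, n_perm,
                         min_node),
       right = .grow_node(X[!left, , drop = FALSE], y[!left], alpha, n_perm,
                          min_node))
}

#' Predict from a fitted change tree
#'
#' Routes each row by the split thresholds (values at a threshold go left,
#' i.e. `<=` goes left) and returns the leaf mean.
#'
#' @param object A `change_tree`.
#' @param newdata Data frame containing every predictor the tree uses.
#' @param ... Unused.
#' @return Numeric vector of fitted leaf means.
#' @export
predict.change_tree <- function(object, newdata, ...) {
  used <- .tree_predictors(object$root)
  miss <- setdiff(used, names(newdata))
  if (length(miss)) stop("newdata lacks predictor(s): ",
                         paste(miss, collapse = ", "))
  vapply(seq_len(nrow(newdata)), function(i) {
    node <- object$root
    while (node$type == "split") {
      node <- if (newdata[[node$predictor]][i] <= node$threshold)
        node$left else node$right
    }
    node$mean
  }, numeric(1))
}

.tree_predictors <- function(node) {
  if (node$type == "leaf") return(character(0))
  unique(c(node$predictor, .tree_predictors(node$left),
           .tree_predictors(node$right)))
}

#' Tabulate the partitions of a fitted change tree
#'
#' @param tree A `change_tree`.
#' @return Data frame in depth-first order: `node`, `depth`, `type`,
#'   `predictor`, `threshold`, `p_adjusted`, `n`, `mean` (leaves only).
#' @export
tree_report <- function(tree) {
  stopifnot(inherits(tree, "change_tree"))
  rows <- list()
  walk <- function(node, depth) {
    i <- length(rows) + 1L
    if (node$type == "leaf") {
      rows[[i]] <<- data.frame(node = i, depth = depth, type = "leaf",
                               predictor = NA_character_,
                               threshold = NA_real_, p_adjusted = NA_real_,
                               n = node$n, mean = node$mean,
                               stringsAsFactors = FALSE)
    } else {
      rows[[i]] <<- data.frame(node = i, depth = depth, type = "split",
                               predictor = node$predictor,
                               threshold = node$threshold,
                               p_adjusted = node$p_adjusted, n = node$n,
                               mean = NA_real_, stringsAsFactors = FALSE)
      walk(node$left, depth + 1L)
      walk(node$right, depth + 1L)
    }
  }
  walk(tree$root, 0L)
  do.call(rbind, rows)
}

#' @export
print.change_tree <- function(x, ...) {
  rep <- tree_report(x)
  n_split <- sum(rep$type == "split")
  cat("Conditional inference change tree:", n_split, "split(s),",
      sum(rep$type == "leaf"), "leaf/leaves, n =", x$n, "\n")
  for (i in seq_len(nrow(rep))) {
    pad <- strrep("  ", rep$depth[i])
    if (rep$type[i] == "split")
      cat(sprintf("%s[%s <= %.4g] p_adj = %.4g, n = %d\n", pad,
                  rep$predictor[i], rep$threshold[i], rep$p_adjusted[i],
                  rep$n[i]))
    else
      cat(sprintf("%s* leaf: mean = %.4f, n = %d\n", pad, rep$mean[i],
                  rep$n[i]))
  }
  invisible(x)
}
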