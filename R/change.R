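#' Abundance-based Sorensen dissimilarity between two composition vectors
#'
#' `sum(|x_i - y_i|) / sum(x_i + y_i)`: 0 for identical composition, 1 for no
#' overlap. With relative abundances the denominator is 2, so this is half
#' the L1 distance on the simplex (the quantitative Sorensen, identical to
#' Bray-Curtis on proportions). A semimetric: symmetric, zero iff equal,
#' bounded by 1; the triangle inequality is not guaranteed.
#'
#' @param x,y Nonnegative numeric vectors of equal length.
#' @return Dissimilarity in `[0, 1]`.
#' @examples
#' sorensen(c(0.6, 0.4), c(0.2, 0.8))  # 0.4
#' @export
sorensen <- function(x, y) {
  if (length(x) != length(y)) stop("vectors differ in length")
  s <- sum(x) + sum(y)
  if (s == 0) stop("both vectors are all-zero")
  sum(abs(x - y)) / s
}

#' Pairwise Sorensen distance matrix for a composition table
#'
#' @param comp Towns x taxa relative-abundance matrix.
#' @return Symmetric matrix with zero diagonal, dimnames from `comp` rows.
#' @export
sorensen_matrix <- function(comp) {
  n <- nrow(comp)
  d <- matrix(0, n, n, dimnames = list(rownames(comp), rownames(comp)))
  rs <- rowSums(comp)
  for (i in seq_len(n - 1)) {
    di <- rowSums(abs(sweep(comp[(i + 1):n, , drop = FALSE], 2, comp[i, ])))
    d[i, (i + 1):n] <- d[(i + 1):n, i] <- di / (rs[(i + 1):n] + rs[i])
  }
  d
}

#' Per-town compositional change between eras
#'
#' For each town, the Sorensen distance from its pre-colonial composition to
#' its modern composition, with regional and per-ecoregion summaries and
#' pairwise ecoregion permutation comparisons.
#'
#' @param pre,mod Composition matrices with identical taxa; towns are matched
#'   by row name (an error lists towns present in one era only).
#' @param ecoregion Optional named vector (by town id) of ecoregion labels.
#' @param n_rand Randomizations for the pairwise ecoregion tests.
#' @param seed Seed for the permutation tests.
#' @return List of class `change_result`: `change` (named per-town vector),
#'   `regional` (mean/sd/min/max), `by_ecoregion` (data frame), and
#'   `ecoregion_pairwise` (p-value matrix) when `ecoregion` is supplied.
#' @export
change_per_town <- function(pre, mod, ecoregion = NULL, n_rand = 10000,
                            seed = NULL) {
  al <- align_compositions(pre, mod)
  ch <- vapply(al$towns, function(t) sorensen(al$pre[t, ], al$mod[t, ]),
               numeric(1))
  out <- list(change = ch,
              regional = c(mean = mean(ch), sd = stats::sd(ch),
                           min = min(ch), max = max(ch)))
  if (!is.null(ecoregion)) {
    eco <- ecoregion[al$towns]
    if (anyNA(eco)) stop("ecoregion labels missing for some towns")
    out$by_ecoregion <- data.frame(
      ecoregion = sort(unique(eco)),
      n = as.vector(table(eco)[sort(unique(eco))]),
      mean = as.vector(tapply(ch, eco, mean)[sort(unique(eco))]),
      sd = as.vector(tapply(ch, eco, stats::sd)[sort(unique(eco))]),
      stringsAsFactors = FALSE)
    out$ecoregion_pairwise <- group_permutation(ch, eco, n_rand = n_rand,
                                                seed = seed)
  }
  class(out) <- "change_result"
  out
}

#' @export
print.change_result <- function(x, ...) {
  cat("Per-town compositional change (Sorensen):", length(x$change),
      "towns\n")
  cat(sprintf("  regional mean %.3f (sd %.3f), range [%.3f, %.3f]\n",
              x$regional["mean"], x$regional["sd"], x$regional["min"],
              x$regional["max"]))
  if (!is.null(x$by_ecoregion)) {
    for (i in seq_len(nrow(x$by_ecoregion)))
      cat(sprintf("  %-8s n=%3d  mean %.3f (sd %.3f)\n",
                  x$by_ecoregion$ecoregion[i], x$by_ecoregion$n[i],
                  x$by_ecoregion$mean[i], x$by_ecoregion$sd[i]))
  }
  invisible(x)
}

#' Paired Monte Carlo test for a mean difference
#'
#' Statistic `|mean(pre - mod)|`; the null is built by independently flipping
#' each pair's labels with probability one half (sign randomization). The
#' p-value uses the add-one convention `(1 + #{null >= observed}) /
#' (1 + n_rand)` so it can never be exactly zero.
#'
#' @param pre,mod Equal-length paired numeric vectors.
#' @param n_rand Number of randomizations (default 10000).
#' @param seed Optional seed.
#' @return List: `statistic`, `p`, `n_rand`.
#' @export
paired_monte_carlo <- function(pre, mod, n_rand = 10000, seed = NULL) {
  if (length(pre) != length(mod)) stop("paired vectors differ in length")
  n <- length(pre)
  if (n < 2) stop("need at least 2 pairs")
  if (!is.null(seed)) set.seed(seed)
  d <- pre - mod
  obs <- abs(mean(d))
  signs <- matrix(sample(c(-1, 1), n * n_rand, replace = TRUE), nrow = n)
  null <- abs(colMeans(d * signs))
  list(statistic = obs, p = (1 + sum(null >= obs)) / (1 + n_rand),
       n_rand = n_rand)
}

#' Pairwise group-difference permutation tests
#'
#' For every pair of group labels, tests `|mean difference|` against a null
#' built by shuffling the pooled labels, with the same add-one p-value
#' convention as [paired_monte_carlo()].
#'
#' @param values Numeric vector.
#' @param labels Group label per value.
#' @param n_rand Number of label shuffles per pair.
#' @param seed Optional seed.
#' @return Symmetric matrix of p-values (diagonal `NA`); pairs where either
#'   group has fewer than 2 members are `NA`.
#' @export
group_permutation <- function(values, labels, n_rand = 10000, seed = NULL) {
  labels <- as.character(labels)
  if (length(values) != length(labels)) stop("values/labels length mismatch")
  groups <- sort(unique(labels))
  if (length(groups) < 2) stop("need at least 2 groups")
  if (!is.null(seed)) set.seed(seed)
  p <- matrix(NA_real_, length(groups), length(groups),
              dimnames = list(groups, groups))
  for (i in seq_along(groups)[-length(groups)]) {
    for (j in (i + 1):length(groups)) {
      vi <- values[labels == groups[i]]
      vj <- values[labels == groups[j]]
      if (length(vi) < 2 || length(vj) < 2) next  # degenerate pair: NA
      pooled <- c(vi, vj)
      ni <- length(vi)
      obs <- abs(mean(vi) - mean(vj))
      null <- vapply(seq_len(n_rand), function(r) {
        idx <- sample.int(length(pooled), ni)
        abs(mean(pooled[idx]) - mean(pooled[-idx]))
      }, numeric(1))
      p[i, j] <- p[j, i] <- (1 + sum(null >= obs)) / (1 + n_rand)
    }
  }
  p
}

#' Beta diversity as mean town-to-town dissimilarity
#'
#' Rooney-style beta diversity: each town's average Sorensen dissimilarity to
#' all other towns in scope, per era, with a permutation comparison of the
#' era means. A lower modern mean than pre-colonial mean indicates biotic
#' homogenization.
#'
#' @param pre,mod Composition matrices (matched towns).
#' @param ecoregion Optional named ecoregion vector; when given, per-town
#'   means are also computed within each ecoregion.
#' @param n_rand Permutations for the era comparison.
#' @param seed Optional seed.
#' @return List of class `beta_diversity_result`: `per_town` data frame
#'   (town, era, mean dissimilarity), `era_summary`, `p_regional`, and,
#'   with ecoregions, `by_ecoregion`.
#' @export
beta_diversity <- function(pre, mod, ecoregion = NULL, n_rand = 10000,
                           seed = NULL) {
  al <- align_compositions(pre, mod)
  if (length(al$towns) < 3) stop("need at least 3 towns")
  mean_off_diag <- function(d) rowSums(d) / (nrow(d) - 1)
  b_pre <- mean_off_diag(sorensen_matrix(al$pre))
  b_mod <- mean_off_diag(sorensen_matrix(al$mod))
  per_town <- data.frame(
    town_id = rep(al$towns, 2),
    era = rep(c("precolonial", "modern"), each = length(al$towns)),
    beta = c(b_pre, b_mod), stringsAsFactors = FALSE)
  p <- group_permutation(per_town$beta, per_town$era, n_rand = n_rand,
                         seed = seed)["precolonial", "modern"]
  out <- list(per_town = per_town,
              era_summary = data.frame(
                era = c("precolonial", "modern"),
                mean = c(mean(b_pre), mean(b_mod)),
                sd = c(stats::sd(b_pre), stats::sd(b_mod))),
              p_regional = p)
  if (!is.null(ecoregion)) {
    eco <- ecoregion[al$towns]
    rows <- lapply(sort(unique(eco)), function(e) {
      ids <- al$towns[eco == e]
      if (length(ids) < 3) return(NULL)
      bp <- mean_off_diag(sorensen_matrix(al$pre[ids, , drop = FALSE]))
      bm <- mean_off_diag(sorensen_matrix(al$mod[ids, , drop = FALSE]))
      pe <- group_permutation(c(bp, bm),
                              rep(c("precolonial", "modern"),
                                  each = length(ids)),
                              n_rand = n_rand)["precolonial", "modern"]
      data.frame(ecoregion = e, n = length(ids), mean_pre = mean(bp),
                 mean_mod = mean(bm), p = pe, stringsAsFactors = FALSE)
    })
    out$by_ecoregion <- do.call(rbind, rows)
  }
  class(out) <- "beta_diversity_result"
  out
}

#' Per-taxon abundance change table
#'
#' Unweighted town means of relative abundance per taxon and era, their
#' difference, and a paired Monte Carlo p-value per taxon. No
#' multiple-testing correction is applied across taxa (each row is reported
#' as its own test).
#'
#' @param pre,mod Composition matrices (matched towns).
#' @param ecoregion Optional named ecoregion vector; when given, the table
#'   is computed per ecoregion as well as for all towns.
#' @param n_rand Randomizations per taxon.
#' @param seed Optional seed.
#' @return Data frame: `scope`, `taxon`, `n_towns`, `mean_pre`, `mean_mod`,
#'   `delta`, `p`.
#' @export
abundance_change_table <- function(pre, mod, ecoregion = NULL,
                                   n_rand = 10000, seed = NULL) {
  al <- align_compositions(pre, mod)
  if (!is.null(seed)) set.seed(seed)
  scopes <- list(ALL = al$towns)
  if (!is.null(ecoregion)) {
    eco <- ecoregion[al$towns]
    for (e in sort(unique(eco))) scopes[[e]] <- al$towns[eco == e]
  }
  rows <- lapply(names(scopes), function(sc) {
    ids <- scopes[[sc]]
    do.call(rbind, lapply(colnames(al$pre), function(tx) {
      x <- al$pre[ids, tx]; y <- al$mod[ids, tx]
      pmc <- paired_monte_carlo(x, y, n_rand = n_rand)
      data.frame(scope = sc, taxon = tx, n_towns = length(ids),
                 mean_pre = mean(x), mean_mod = mean(y),
                 delta = mean(y) - mean(x), p = pmc$p,
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}
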