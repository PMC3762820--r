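#' Build a town x taxon relative-abundance matrix
#'
#' Pools retained stems across each town (witness trees have no plot
#' structure, so pooling keeps the two eras symmetric) and converts counts to
#' proportions. Rows are towns, columns the 24 taxon groups; every row sums
#' to one. Towns with zero retained trees are excluded with a message, and
#' `UNBINNED` records are dropped with a logged count.
#'
#' @param trees Data frame with columns `town_id` and `taxon_code`.
#' @param taxa Character vector of taxon codes defining column order.
#' @return Numeric matrix (towns x taxa) of relative abundances with
#'   `rownames` = town ids. Rows sum to 1 within 1e-9.
#' @export
town_composition <- function(trees, taxa = taxon_codes()) {
  stopifnot(is.data.frame(trees),
            all(c("town_id", "taxon_code") %in% names(trees)))
  n_un <- sum(trees$taxon_code == UNBINNED)
  if (n_un > 0L) {
    message("excluding ", n_un, " UNBINNED tree record(s) from composition")
    trees <- trees[trees$taxon_code != UNBINNED, , drop = FALSE]
  }
  unknown <- setdiff(unique(trees$taxon_code), taxa)
  if (length(unknown))
    stop("taxon codes not in taxa vocabulary: ", paste(unknown, collapse = ", "))
  if (nrow(trees) == 0L) stop("no binned tree records; cannot build composition")
  counts <- table(factor(trees$town_id), factor(trees$taxon_code, levels = taxa))
  counts <- matrix(counts, nrow = nrow(counts), ncol = ncol(counts),
                   dimnames = list(rownames(counts), taxa))
  tot <- rowSums(counts)
  if (any(tot == 0)) {
    message("excluding ", sum(tot == 0), " town(s) with zero retained trees")
    counts <- counts[tot > 0, , drop = FALSE]
    tot <- tot[tot > 0]
  }
  comp <- counts / tot
  validate_composition(comp)
  comp
}

#' Validate a composition matrix
#'
#' @param comp Numeric matrix with values in `[0, 1]` whose rows each sum to
#'   one within `tol`.
#' @param tol Row-sum tolerance.
#' @return `comp`, invisibly, or an error.
#' @export
validate_composition <- function(comp, tol = 1e-9) {
  stopifnot(is.matrix(comp), is.numeric(comp))
  if (any(comp < -tol | comp > 1 + tol))
    stop("composition values must lie in [0, 1]")
  bad <- abs(rowSums(comp) - 1) > tol
  if (any(bad))
    stop("composition rows do not sum to 1: ",
         paste(utils::head(rownames(comp)[bad], 5), collapse = ", "))
  invisible(comp)
}

#' Align two composition tables on a common town set
#'
#' @param pre,mod Composition matrices (rows named by town id).
#' @return List with both matrices restricted and re-ordered to the shared
#'   towns; errors if either era has towns missing from the other.
#' @export
align_compositions <- function(pre, mod) {
  miss_mod <- setdiff(rownames(pre), rownames(mod))
  miss_pre <- setdiff(rownames(mod), rownames(pre))
  if (length(miss_mod) || length(miss_pre))
    stop("towns present in one era only: ",
         paste(utils::head(c(miss_mod, miss_pre), 10), collapse = ", "))
  if (!identical(colnames(pre), colnames(mod)))
    stop("taxa columns differ between eras")
  towns <- rownames(pre)
  list(pre = pre, mod = mod[towns, , drop = FALSE], towns = towns)
}
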