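#' Apply the modern-inventory record filters
#'
#' Reproduces the record-level screening of the modern inventory data:
#' plots must be classed `"Forest"` and contain at least `min_trees` trees of
#' at least `min_dbh_cm` dbh (closed lower bound); all retained trees must
#' themselves be at least `min_dbh_cm`; and towns with fewer than
#' `min_plots_per_town` qualifying plots are dropped entirely. Witness-tree
#' (pre-colonial) records pass through untouched.
#'
#' @param plots Data frame with columns `plot_id`, `town_id`,
#'   `condition_class`.
#' @param trees Data frame with columns `town_id`, `era`, `plot_id`,
#'   `dbh_cm` (dbh required on modern records).
#' @param min_dbh_cm Minimum diameter at breast height in cm (default 12.5).
#' @param min_trees Minimum qualifying trees per plot (default 10).
#' @param min_plots_per_town Minimum qualifying plots per town (default 2).
#' @return List with elements `plots`, `trees`, `towns_dropped`, and `log`
#'   (named counts of exclusions by reason). Idempotent: applying the filter
#'   to its own output changes nothing.
#' @export
filter_modern <- function(plots, trees, min_dbh_cm = 12.5, min_trees = 10,
                          min_plots_per_town = 2) {
  stopifnot(is.data.frame(plots), is.data.frame(trees))
  if (nrow(plots) == 0L || sum(trees$era == "modern") == 0L) {
    warning("no modern plots/trees to filter; returning empty result")
    return(list(plots = plots[0, , drop = FALSE],
                trees = trees[trees$era != "modern", , drop = FALSE],
                towns_dropped = character(0),
                log = c(plots_nonforest = 0L, plots_sparse = 0L,
                        trees_small = 0L, towns_dropped = 0L)))
  }
  modern <- trees[trees$era == "modern", , drop = FALSE]
  if (anyNA(modern$dbh_cm)) stop("modern tree records must carry dbh_cm")
  keep_tree <- modern$dbh_cm >= min_dbh_cm
  n_small <- sum(!keep_tree)
  qualifying <- modern[keep_tree, , drop = FALSE]

  q_per_plot <- table(factor(qualifying$plot_id, levels = plots$plot_id))
  forest <- plots$condition_class == "Forest"
  dense <- as.integer(q_per_plot[as.character(plots$plot_id)]) >= min_trees
  keep_plot <- forest & dense
  n_nonforest <- sum(!forest)
  n_sparse <- sum(forest & !dense)

  plots_kept <- plots[keep_plot, , drop = FALSE]
  per_town <- table(plots_kept$town_id)
  towns_ok <- names(per_town)[per_town >= min_plots_per_town]
  towns_dropped <- sort(setdiff(unique(plots$town_id), towns_ok))
  plots_kept <- plots_kept[plots_kept$town_id %in% towns_ok, , drop = FALSE]

  trees_kept <- qualifying[qualifying$plot_id %in% plots_kept$plot_id, ,
                           drop = FALSE]
  out_trees <- rbind(trees[trees$era != "modern", , drop = FALSE], trees_kept)
  list(plots = plots_kept,
       trees = out_trees,
       towns_dropped = towns_dropped,
       log = c(plots_nonforest = n_nonforest, plots_sparse = n_sparse,
               trees_small = n_small, towns_dropped = length(towns_dropped)))
}
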