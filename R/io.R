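#' Read town polygons from a GeoJSON FeatureCollection
#'
#' Each feature must be a Polygon (outer ring used; holes ignored) with
#' `town_id` and `ecoregion` properties. Geodesic centroids and areas are
#' computed from the ring coordinates.
#'
#' @param path GeoJSON file.
#' @return Data frame: `town_id`, `ecoregion`, `centroid_lon`,
#'   `centroid_lat`, `area_km2`.
#' @export
read_town_geojson <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection" || is.null(gj$features))
    stop("malformed GeoJSON: expected a FeatureCollection in ", path)
  rows <- lapply(gj$features, function(f) {
    if (is.null(f$geometry) || is.null(f$properties$town_id))
      stop("malformed GeoJSON feature: missing geometry or town_id property")
    if (f$geometry$type != "Polygon")
      stop("unsupported geometry type: ", f$geometry$type)
    ring <- f$geometry$coordinates[[1]]
    coords <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    cen <- geosphere::centroid(coords)
    area <- geosphere::areaPolygon(coords) / 1e6
    data.frame(town_id = as.character(f$properties$town_id),
               ecoregion = as.character(f$properties$ecoregion),
               centroid_lon = cen[1], centroid_lat = cen[2],
               area_km2 = area, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (any(out$area_km2 <= 0)) stop("town polygons with non-positive area")
  if (anyDuplicated(out$town_id)) stop("duplicate town_id in GeoJSON")
  rownames(out) <- NULL
  out
}

#' Load a complete dataset from disk
#'
#' Reads the witness-tree CSV (`town_id`, `raw_name`), the modern inventory
#' CSV (`plot_id`, `town_id`, `raw_name`, `dbh_cm`, `condition_class`), the
#' town GeoJSON, and the per-town covariate CSV, validates referential
#' integrity, and assembles the in-memory dataset all analysis stages
#' consume.
#'
#' @param witness_csv,inventory_csv Tree tables, one per era.
#' @param town_geojson Town polygons with `town_id`/`ecoregion` properties.
#' @param covariate_csv Per-town environmental and land-use covariates
#'   (must contain a `town_id` column).
#' @param name_map Raw-name mapping for [bin_taxon()].
#' @return Object of class `forest_dataset`: list with `towns` (polygons
#'   joined to covariates), `plots`, and `trees` (binned, both eras).
#' @export
load_dataset <- function(witness_csv, inventory_csv, town_geojson,
                         covariate_csv, name_map = default_name_map()) {
  wt <- utils::read.csv(witness_csv, stringsAsFactors = FALSE)
  if (nrow(wt) == 0L) stop("no records in ", witness_csv)
  inv <- utils::read.csv(inventory_csv, stringsAsFactors = FALSE)
  if (nrow(inv) == 0L) stop("no records in ", inventory_csv)
  stopifnot(all(c("town_id", "raw_name") %in% names(wt)),
            all(c("plot_id", "town_id", "raw_name", "dbh_cm",
                  "condition_class") %in% names(inv)))
  towns <- read_town_geojson(town_geojson)
  cov <- utils::read.csv(covariate_csv, stringsAsFactors = FALSE)
  stopifnot("town_id" %in% names(cov))
  cov$town_id <- as.character(cov$town_id)

  miss_cov <- setdiff(towns$town_id, cov$town_id)
  if (length(miss_cov))
    stop("covariate file missing town(s): ", paste(miss_cov, collapse = ", "))
  towns <- merge(towns, cov, by = "town_id", sort = TRUE)

  wt$town_id <- as.character(wt$town_id)
  inv$town_id <- as.character(inv$town_id)
  inv$plot_id <- as.character(inv$plot_id)
  orphans <- setdiff(unique(c(wt$town_id, inv$town_id)), towns$town_id)
  if (length(orphans))
    stop("tree records reference unknown town(s): ",
         paste(orphans, collapse = ", "))

  plots <- unique(inv[, c("plot_id", "town_id", "condition_class")])
  if (anyDuplicated(plots$plot_id))
    stop("plot(s) with inconsistent town or condition: ",
         paste(plots$plot_id[duplicated(plots$plot_id)], collapse = ", "))

  trees <- rbind(
    data.frame(town_id = wt$town_id, era = "precolonial",
               raw_name = wt$raw_name, dbh_cm = NA_real_,
               plot_id = NA_character_, stringsAsFactors = FALSE),
    data.frame(town_id = inv$town_id, era = "modern", raw_name = inv$raw_name,
               dbh_cm = inv$dbh_cm, plot_id = inv$plot_id,
               stringsAsFactors = FALSE))
  trees <- bin_trees(trees, name_map)
  structure(list(towns = towns, plots = plots, trees = trees),
            class = "forest_dataset")
}

#' @export
print.forest_dataset <- function(x, ...) {
  cat("forest_dataset:", nrow(x$towns), "towns,", nrow(x$plots), "plots,",
      sum(x$trees$era == "precolonial"), "witness trees,",
      sum(x$trees$era == "modern"), "inventory trees\n")
  invisible(x)
}
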