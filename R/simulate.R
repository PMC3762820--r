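#' Default Gaussian niche parameters along the temperature gradient
#'
#' Each taxon group gets a growing-degree-day optimum, a niche width, and a
#' peak (unnormalized) abundance, chosen to mimic the region's broad
#' composition pattern: oak/hickory/chestnut in the warm south, a central
#' beech-maple-hemlock belt, spruce/fir in the cool north, and a set of
#' low-abundance associates.
#'
#' @return Data frame: `taxon`, `opt_gdd`, `width_gdd`, `peak`.
#' @export
default_niches <- function() {
  d <- rbind(
    c("ASHES",     3400, 700, 0.12),
    c("BASSWOOD",  3200, 450, 0.07),
    c("BEECH",     3100, 600, 0.90),
    c("BIRCHES",   2800, 600, 0.35),
    c("BLACKGUM",  4400, 300, 0.06),
    c("CEDAR",     2500, 400, 0.08),
    c("CHERRIES",  3400, 700, 0.02),
    c("CHESTNUT",  4300, 400, 0.25),
    c("CYPRESS",   4700, 200, 0.02),
    c("ELMS",      3800, 500, 0.08),
    c("FIR",       2150, 350, 0.35),
    c("HEMLOCK",   3100, 550, 0.55),
    c("HICKORIES", 4500, 400, 0.30),
    c("HORNBEAM",  3300, 500, 0.06),
    c("MAGNOLIAS", 4400, 250, 0.03),
    c("MAPLE",     3300, 900, 0.55),
    c("OAK",       4400, 500, 1.00),
    c("PINES",     3500, 800, 0.35),
    c("POPLARS",   3000, 600, 0.04),
    c("SPRUCES",   2300, 400, 0.80),
    c("SYCAMORE",  4500, 250, 0.04),
    c("TAMARACK",  2200, 300, 0.05),
    c("TULIP",     4600, 300, 0.10),
    c("WALNUTS",   4500, 300, 0.05))
  data.frame(taxon = d[, 1], opt_gdd = as.numeric(d[, 2]),
             width_gdd = as.numeric(d[, 3]), peak = as.numeric(d[, 4]),
             stringsAsFactors = FALSE)
}

#' Default era-shift multiplier rules
#'
#' Per-taxon multipliers `pmax(0, a + b * agri)` applied to the pre-colonial
#' profile, where `agri` is the town's peak agricultural proportion. The
#' defaults encode the region's documented trajectory: chestnut extirpated
#' everywhere (multiplier 0); beech, hemlock, and oak declining in proportion
#' to agricultural clearing; maple, cherry, poplar, and birch rising with it;
#' spruce down and fir up in the north.
#'
#' @return Data frame: `taxon`, `a`, `b` (multiplier = `pmax(0, a + b*agri)`;
#'   taxa absent from the table keep multiplier 1).
#' @export
default_shift_rules <- function() {
  d <- rbind(
    c("CHESTNUT",   0.00,   0.0),
    c("BEECH",      1.00,  -0.85),
    c("HEMLOCK",    1.00,  -0.60),
    c("OAK",        1.00,  -0.50),
    c("SPRUCES",    0.55,   0.0),
    c("FIR",        2.20,   0.0),
    c("MAPLE",      1.00,   4.0),
    c("CHERRIES",   1.00,  22.0),
    c("POPLARS",    1.00,   6.0),
    c("BIRCHES",    1.00,   1.5),
    c("ASHES",      1.00,   2.0),
    c("HICKORIES",  0.50,   0.0),
    c("ELMS",       0.50,   0.0),
    c("BASSWOOD",   0.45,   0.0),
    c("WALNUTS",    0.30,   0.0),
    c("SYCAMORE",   0.10,   0.0))
  data.frame(taxon = d[, 1], a = as.numeric(d[, 2]), b = as.numeric(d[, 3]),
             stringsAsFactors = FALSE)
}

# Representative raw species names emitted by the generator, so that the
# binning step is exercised end-to-end.
.species_for <- c(
  ASHES = "Fraxinus americana", BASSWOOD = "Tilia americana",
  BEECH = "Fagus grandifolia", BIRCHES = "Betula alleghaniensis",
  BLACKGUM = "Nyssa sylvatica", CEDAR = "Thuja occidentalis",
  CHERRIES = "Prunus serotina", CHESTNUT = "Castanea dentata",
  CYPRESS = "Taxodium distichum", ELMS = "Ulmus americana",
  FIR = "Abies balsamea", HEMLOCK = "Tsuga canadensis",
  HICKORIES = "Carya ovata", HORNBEAM = "Ostrya virginiana",
  MAGNOLIAS = "Magnolia acuminata", MAPLE = "Acer rubrum",
  OAK = "Quercus rubra", PINES = "Pinus strobus",
  POPLARS = "Populus tremuloides", SPRUCES = "Picea rubens",
  SYCAMORE = "Platanus occidentalis", TAMARACK = "Larix laricina",
  TULIP = "Liriodendron tulipifera", WALNUTS = "Juglans nigra")

#' Configuration for the synthetic landscape generator
#'
#' Towns are tiled on a regular grid over a latitudinal temperature gradient;
#' taxa respond to growing degree days through Gaussian niches; an era-shift
#' operator converts each town's pre-colonial profile into its modern
#' profile as a function of the town's peak agricultural clearing; witness
#' trees are multinomial draws from the pre-colonial profile; inventory
#' plots draw a plot-level profile from a Dirichlet centered on the modern
#' profile (concentration `theta`) and then a multinomial of trees.
#'
#' @param n_x,n_y Grid dimensions; `n_x * n_y` towns.
#' @param lat_range,lon_range Latitude/longitude extent (decimal degrees).
#' @param gdd_range Growing degree days at the southern and northern edge.
#' @param niches Data frame as [default_niches()].
#' @param shift_rules Data frame as [default_shift_rules()].
#' @param agri_slope,agri_field_amp,agri_sd Logit-scale components of the
#'   per-town peak agricultural proportion: a (weak) latitudinal trend
#'   (south more cleared), a smooth low-frequency random field that makes
#'   land-use history spatially clustered yet only partially aligned with
#'   climate, and independent town-level noise. The field is what produces
#'   local clustering of compositional change and the era-specific
#'   weakening of the temperature-composition coupling.
#' @param wt_mean Mean witness trees per town (negative binomial, floor 120).
#' @param plots_mean Mean inventory plots per town (Poisson, floor 3).
#' @param trees_per_plot_mean Mean trees per plot (Poisson, floor 10).
#' @param theta Plot-level Dirichlet concentration (larger = plots closer to
#'   the town profile).
#' @param town_km Side length of each (square) town polygon in km; grid
#'   points span the full lat/lon extent but each town covers only about
#'   `town_km^2` km^2, matching the ~100 km^2 proprietary towns.
#' @param seed Integer; fixes all randomness in the generator.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_x = 6, n_y = 10,
                       lat_range = c(40, 47), lon_range = c(-74.5, -70),
                       gdd_range = c(4600, 2000),
                       niches = default_niches(),
                       shift_rules = default_shift_rules(),
                       agri_slope = 0.3, agri_field_amp = 1.4,
                       agri_sd = 0.3,
                       wt_mean = 250, plots_mean = 6,
                       trees_per_plot_mean = 36, theta = 25, town_km = 10,
                       seed = 1) {
  stopifnot(n_x >= 1, n_y >= 2, all(niches$width_gdd > 0),
            all(niches$peak >= 0), theta > 0)
  structure(list(n_x = n_x, n_y = n_y, lat_range = lat_range,
                 lon_range = lon_range, gdd_range = gdd_range,
                 niches = niches, shift_rules = shift_rules,
                 agri_slope = agri_slope, agri_field_amp = agri_field_amp,
                 agri_sd = agri_sd,
                 wt_mean = wt_mean, plots_mean = plots_mean,
                 trees_per_plot_mean = trees_per_plot_mean,
                 theta = theta, town_km = town_km, seed = as.integer(seed)),
            class = "sim_config")
}

#' Read a generator configuration from a JSON text file
#'
#' Scalar fields map directly onto [sim_config()] arguments; `niches` and
#' `shift_rules`, when present, are arrays of objects with the same columns
#' as [default_niches()] / [default_shift_rules()]. Unknown keys are an
#' error.
#'
#' @param path JSON file.
#' @return A `sim_config`.
#' @export
sim_config_from_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  known <- names(formals(sim_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (f in c("niches", "shift_rules"))
    if (!is.null(raw[[f]])) raw[[f]] <- as.data.frame(raw[[f]])
  do.call(sim_config, raw)
}

#' True relative abundance profile at a given temperature
#'
#' Gaussian niche response: unnormalized abundance
#' `peak * exp(-(gdd - opt)^2 / (2 * width^2))`, normalized to proportions.
#'
#' @param gdd Growing degree days of the town.
#' @param niches Niche table as [default_niches()].
#' @return Named numeric vector over the taxa in `niches`, summing to 1.
#' @export
true_composition <- function(gdd, niches = default_niches()) {
  a <- niches$peak * exp(-(gdd - niches$opt_gdd)^2 / (2 * niches$width_gdd^2))
  if (sum(a) <= 0) stop("all niche abundances zero at gdd = ", gdd)
  stats::setNames(a / sum(a), niches$taxon)
}

#' Apply the era-shift operator to a pre-colonial profile
#'
#' @param pre_profile Named proportion vector summing to 1.
#' @param agri Peak agricultural proportion of the town, in `[0, 1]`.
#' @param shift_rules Data frame as [default_shift_rules()].
#' @return Modern profile: per-taxon multipliers applied then renormalized.
#' @export
era_shift <- function(pre_profile, agri, shift_rules = default_shift_rules()) {
  stopifnot(abs(sum(pre_profile) - 1) < 1e-8, agri >= 0, agri <= 1)
  mult <- rep(1, length(pre_profile))
  names(mult) <- names(pre_profile)
  idx <- match(shift_rules$taxon, names(pre_profile))
  ok <- !is.na(idx)
  mult[idx[ok]] <- pmax(0, shift_rules$a[ok] + shift_rules$b[ok] * agri)
  out <- pre_profile * mult
  if (sum(out) <= 0) stop("era shift annihilated the whole profile")
  out / sum(out)
}

#' Multinomial witness-tree sample from a profile
#'
#' @param profile Named proportion vector.
#' @param n Number of trees to draw.
#' @return Named count vector over taxa.
#' @export
sample_witness_trees <- function(profile, n) {
  stopifnot(n >= 1)
  stats::setNames(as.vector(stats::rmultinom(1, n, profile)), names(profile))
}

#' Dirichlet-multinomial inventory-plot sample
#'
#' Each plot draws its own composition from `Dirichlet(theta * profile)`
#' (emulating within-town clustering of the fixed-radius plot design), then
#' a multinomial of `m_trees` stems from it.
#'
#' @param profile Named proportion vector (the town's modern profile).
#' @param n_plots Number of plots.
#' @param m_trees Trees per plot (scalar or vector of length `n_plots`).
#' @param theta Dirichlet concentration; plot profiles converge to the town
#'   profile as `theta` grows.
#' @return Matrix `n_plots x taxa` of stem counts.
#' @export
sample_fia_plots <- function(profile, n_plots, m_trees, theta = 25) {
  stopifnot(n_plots >= 1, all(m_trees >= 1), theta > 0)
  m_trees <- rep_len(m_trees, n_plots)
  k <- length(profile)
  counts <- matrix(0L, n_plots, k, dimnames = list(NULL, names(profile)))
  for (p in seq_len(n_plots)) {
    g <- stats::rgamma(k, shape = theta * profile)
    if (sum(g) <= 0) g <- profile  # degenerate draw; fall back to the mean
    counts[p, ] <- as.vector(stats::rmultinom(1, m_trees[p], g / sum(g)))
  }
  counts
}

#' Generate a complete synthetic landscape
#'
#' @param config A [sim_config()].
#' @return List of class `sim_landscape`: `dataset` (a `forest_dataset` as
#'   returned by [load_dataset()]) and `truth` (per-town true pre/modern
#'   profiles, gdd and agriculture covariates) for ground-truth checks.
#' @export
simulate_landscape <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nx <- config$n_x; ny <- config$n_y
  n <- nx * ny
  lat_step <- diff(config$lat_range) / ny
  lon_step <- diff(config$lon_range) / nx
  grid <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
  lat_c <- config$lat_range[1] + (grid$iy - 0.5) * lat_step
  lon_c <- config$lon_range[1] + (grid$ix - 0.5) * lon_step
  # each town is a ~town_km x town_km square centered on its grid point
  half_lat <- config$town_km / 111.2 / 2
  half_lon <- config$town_km / (111.2 * cos(lat_c * pi / 180)) / 2
  lat0 <- lat_c - half_lat
  lon0 <- lon_c - half_lon
  town_lat_step <- rep(2 * half_lat, n)
  town_lon_step <- 2 * half_lon
  town_id <- sprintf("T%03d", seq_len(n))

  frac <- (lat_c - config$lat_range[1]) / diff(config$lat_range)
  gdd <- config$gdd_range[1] + frac * diff(config$gdd_range)
  # four equal-width latitudinal ecoregion bands, warm south to cool north
  band <- cut(lat_c, breaks = seq(config$lat_range[1], config$lat_range[2],
                                  length.out = 5),
              include.lowest = TRUE, labels = c("BROAD", "APPAL", "ADIRON",
                                                "LAUREN"))
  # peak agricultural proportion: weak latitudinal trend + smooth random
  # field (3 low-frequency plane waves) + independent noise, on logit scale
  lat_mid <- mean(config$lat_range)
  u <- (lat_c - config$lat_range[1]) / diff(config$lat_range)
  v <- (lon_c - config$lon_range[1]) / diff(config$lon_range)
  field <- 0
  for (w in 1:3) {
    fu <- stats::runif(1, 0.5, 1.5)
    fv <- stats::runif(1, 0.5, 1.5)
    ph <- stats::runif(1, 0, 2 * pi)
    field <- field + sin(2 * pi * (fu * u + fv * v) + ph) / sqrt(3)
  }
  agri <- stats::plogis(config$agri_slope * (lat_mid - lat_c) +
                          config$agri_field_amp * field +
                          stats::rnorm(n, 0, config$agri_sd))

  taxa <- config$niches$taxon
  pre_true <- t(vapply(gdd, true_composition, numeric(length(taxa)),
                       niches = config$niches))
  mod_true <- t(vapply(seq_len(n), function(i)
    era_shift(pre_true[i, ], agri[i], config$shift_rules),
    numeric(length(taxa))))
  rownames(pre_true) <- rownames(mod_true) <- town_id

  wt_n <- 120 + stats::rnbinom(n, size = 5, mu = config$wt_mean - 120)
  plots_n <- 3 + stats::rpois(n, config$plots_mean - 3)

  wt_rows <- vector("list", n)
  inv_rows <- vector("list", n)
  plot_counter <- 0L
  for (i in seq_len(n)) {
    cnt <- sample_witness_trees(pre_true[i, ], wt_n[i])
    wt_rows[[i]] <- data.frame(
      town_id = town_id[i],
      raw_name = rep(.species_for[taxa], cnt),
      stringsAsFactors = FALSE)
    m_trees <- pmax(10L, stats::rpois(plots_n[i], config$trees_per_plot_mean))
    pc <- sample_fia_plots(mod_true[i, ], plots_n[i], m_trees, config$theta)
    pl <- lapply(seq_len(plots_n[i]), function(p) {
      nt <- sum(pc[p, ])
      data.frame(
        plot_id = sprintf("P%05d", plot_counter + p),
        town_id = town_id[i],
        raw_name = rep(.species_for[taxa], pc[p, ]),
        dbh_cm = 12.5 + stats::rgamma(nt, shape = 2, scale = 8),
        condition_class = "Forest",
        stringsAsFactors = FALSE)
    })
    plot_counter <- plot_counter + plots_n[i]
    inv_rows[[i]] <- do.call(rbind, pl)
  }
  wt <- do.call(rbind, wt_rows)
  inv <- do.call(rbind, inv_rows)

  towns <- data.frame(
    town_id = town_id, ecoregion = as.character(band),
    centroid_lon = lon_c, centroid_lat = lat_c,
    area_km2 = vapply(seq_len(n), function(i) {
      ring <- cbind(c(lon0[i], lon0[i] + town_lon_step[i],
                      lon0[i] + town_lon_step[i], lon0[i], lon0[i]),
                    c(lat0[i], lat0[i], lat0[i] + town_lat_step[i],
                      lat0[i] + town_lat_step[i], lat0[i]))
      geosphere::areaPolygon(ring) / 1e6
    }, numeric(1)),
    gdd = gdd,
    precip_mm = 1100 + 320 * frac + stats::rnorm(n, 0, 60),
    elevation_m = pmax(0, stats::rnorm(n, 400, 150)),
    ruggedness_m = abs(stats::rnorm(n, 80, 40)),
    agri_peak = agri,
    agri_peak_year = round(1850 + 80 * stats::runif(n)),
    agri_decline_rate = 0.005 + 0.02 * stats::runif(n),
    canopy_pct = 100 * (1 - 0.6 * agri) + stats::rnorm(n, 0, 5),
    sand_pct = 20 + 40 * stats::runif(n),
    clay_pct = 10 + 20 * stats::runif(n),
    latitude = lat_c, longitude = lon_c,
    lon0 = lon0, lat0 = lat0, lon_step = town_lon_step,
    lat_step = town_lat_step,
    stringsAsFactors = FALSE)

  trees <- rbind(
    data.frame(town_id = wt$town_id, era = "precolonial",
               raw_name = wt$raw_name, dbh_cm = NA_real_,
               plot_id = NA_character_, stringsAsFactors = FALSE),
    data.frame(town_id = inv$town_id, era = "modern", raw_name = inv$raw_name,
               dbh_cm = inv$dbh_cm, plot_id = inv$plot_id,
               stringsAsFactors = FALSE))
  trees <- bin_trees(trees)
  plots <- unique(inv[, c("plot_id", "town_id", "condition_class")])
  dataset <- structure(list(towns = towns, plots = plots, trees = trees),
                       class = "forest_dataset")
  structure(list(dataset = dataset,
                 truth = list(pre = pre_true, mod = mod_true, gdd = gdd,
                              agri = agri, town_id = town_id)),
            class = "sim_landscape")
}

#' Write a synthetic landscape to the on-disk interchange formats
#'
#' Emits exactly the CSV/GeoJSON dialects [load_dataset()] reads:
#' `witness_trees.csv`, `inventory_trees.csv`, `towns.geojson`,
#' `covariates.csv`.
#'
#' @param landscape A `sim_landscape` from [simulate_landscape()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_landscape <- function(landscape, dir) {
  stopifnot(inherits(landscape, "sim_landscape"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ds <- landscape$dataset
  trees <- ds$trees
  wt <- trees[trees$era == "precolonial", c("town_id", "raw_name")]
  inv <- trees[trees$era == "modern",
               c("plot_id", "town_id", "raw_name", "dbh_cm")]
  inv$condition_class <- ds$plots$condition_class[
    match(inv$plot_id, ds$plots$plot_id)]
  paths <- c(witness = file.path(dir, "witness_trees.csv"),
             inventory = file.path(dir, "inventory_trees.csv"),
             towns = file.path(dir, "towns.geojson"),
             covariates = file.path(dir, "covariates.csv"))
  utils::write.csv(wt, paths["witness"], row.names = FALSE)
  utils::write.csv(inv, paths["inventory"], row.names = FALSE)

  tw <- ds$towns
  features <- lapply(seq_len(nrow(tw)), function(i) {
    ring <- list(
      c(tw$lon0[i], tw$lat0[i]),
      c(tw$lon0[i] + tw$lon_step[i], tw$lat0[i]),
      c(tw$lon0[i] + tw$lon_step[i], tw$lat0[i] + tw$lat_step[i]),
      c(tw$lon0[i], tw$lat0[i] + tw$lat_step[i]),
      c(tw$lon0[i], tw$lat0[i]))
    list(type = "Feature",
         properties = list(town_id = tw$town_id[i],
                           ecoregion = tw$ecoregion[i]),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  gj <- list(type = "FeatureCollection", features = features)
  writeLines(jsonlite::toJSON(gj, auto_unbox = TRUE, digits = NA),
             paths["towns"])

  cov_cols <- c("town_id", "gdd", "precip_mm", "elevation_m", "ruggedness_m",
                "agri_peak", "agri_peak_year", "agri_decline_rate",
                "canopy_pct", "sand_pct", "clay_pct", "latitude", "longitude")
  utils::write.csv(tw[, cov_cols], paths["covariates"], row.names = FALSE)
  invisible(paths)
}
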