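test_that("haversine distances match closed-form expectations", {
  towns <- data.frame(town_id = c("A", "B", "C"),
                      centroid_lon = c(-72, -72, -71),
                      centroid_lat = c(42, 43, 42))
  d <- geo_distances(towns)
  expect_equal(unname(d["A", "A"]), 0)
  expect_equal(unname(d["A", "B"]), 6371 * pi / 180, tolerance = 1e-6)
  expect_equal(unname(d["A", "B"]), 111.2, tolerance = 1e-3)
  # third side via an independent spherical law of cosines
  loc <- function(lat1, lon1, lat2, lon2) {
    r <- pi / 180
    6371 * acos(sin(lat1 * r) * sin(lat2 * r) +
                  cos(lat1 * r) * cos(lat2 * r) * cos((lon2 - lon1) * r))
  }
  expect_equal(unname(d["B", "C"]), loc(43, -72, 42, -71), tolerance = 1e-3)
})

test_that("Moran's I matches a hand computation on four towns", {
  # one distance class linking A-B and C-D only
  v <- c(1, 2, 5, 6)
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 1
  w[3, 4] <- w[4, 3] <- 1
  z <- v - mean(v)
  manual <- (4 / 4) * (2 * z[1] * z[2] + 2 * z[3] * z[4]) / sum(z^2)
  expect_equal(morans_i(v, w), manual)
  expect_equal(morans_i(v, w), brute_morans_i(v, w), tolerance = 1e-15)
})

test_that("permutation null of Moran's I centers on -1/(n-1)", {
  set.seed(6)
  n <- 20
  v <- rnorm(n)
  w <- matrix(rbinom(n * n, 1, 0.3), n)
  w <- (w + t(w)) > 0
  diag(w) <- 0
  null <- replicate(3000, morans_i(v[sample(n)], w * 1))
  expect_lt(abs(mean(null) - (-1 / (n - 1))), 0.01)
})

test_that("gradient values give significant positive I in the first class", {
  ls <- simulate_landscape(sim_config(n_x = 5, n_y = 5, seed = 14))
  towns <- ls$dataset$towns
  geo <- geo_distances(towns)
  vals <- towns$centroid_lat + 0.1 * towns$centroid_lon  # smooth gradient
  mc <- morans_correlogram(vals, geo, class_width_km = 90, n_perm = 199,
                           seed = 8)
  first <- which(mc$n_pairs > 0)[1]
  expect_gt(mc$statistic[first], 0)
  expect_true(mc$significant[first])
  expect_error(morans_correlogram(rep(1, nrow(towns)), geo), "constant")
})

test_that("correlogram pair counts are conserved under class refinement", {
  ls <- simulate_landscape(sim_config(n_x = 4, n_y = 4, seed = 15))
  towns <- ls$dataset$towns
  geo <- geo_distances(towns)
  vals <- rnorm(nrow(towns))
  top <- max(geo) + 1
  coarse <- morans_correlogram(vals, geo, class_width_km = 300, n_perm = 9,
                               max_dist_km = top, seed = 1)
  fine <- morans_correlogram(vals, geo, class_width_km = 150, n_perm = 9,
                             max_dist_km = top, seed = 1)
  for (i in seq_len(nrow(coarse))) {
    kids <- fine$n_pairs[fine$lower >= coarse$lower[i] &
                           fine$upper <= coarse$upper[i]]
    expect_equal(sum(kids), coarse$n_pairs[i])
  }
})

test_that("Mantel statistic has its analytic fixed points", {
  set.seed(16)
  comp <- random_composition(8, 6)
  a <- sorensen_matrix(comp)
  expect_equal(mantel_test(a, a, n_perm = 99, seed = 1)$r_m, 1)
  expect_equal(mantel_test(a, a + 0.3, n_perm = 99, seed = 1)$r_m, 1)
  expect_error(mantel_test(a[1:3, 1:3], a[1:3, 1:3]), "at least 4")
})

test_that("Mantel r_M is invariant under joint relabeling", {
  set.seed(17)
  comp <- random_composition(10, 6)
  a <- sorensen_matrix(comp)
  b <- as.matrix(dist(matrix(rnorm(20), 10)))
  perm <- sample(10)
  r1 <- mantel_test(a, b, n_perm = 49, seed = 2)$r_m
  r2 <- mantel_test(a[perm, perm], b[perm, perm], n_perm = 49, seed = 2)$r_m
  expect_equal(r1, r2)
})

test_that("Mantel p is approximately uniform for independent matrices", {
  set.seed(18)
  ps <- replicate(60, {
    a <- as.matrix(dist(rnorm(12)))
    b <- as.matrix(dist(rnorm(12)))
    mantel_test(a, b, n_perm = 99)$p
  })
  expect_gt(mean(ps > 0.5), 0.25)  # not piled near zero
  expect_gt(min(ps), 0.005)
})

test_that("Mantel correlogram recovers the gradient pattern and flags
           degenerate classes", {
  ls <- simulate_landscape(sim_config(seed = 19))
  geo <- geo_distances(ls$dataset$towns)
  d_pre <- sorensen_matrix(ls$truth$pre)
  mc <- mantel_correlogram(d_pre, geo, class_width_km = 80, n_perm = 199,
                           max_dist_km = max(geo) + 1, seed = 3)
  evaluated <- which(!is.na(mc$statistic))
  expect_gt(mc$statistic[evaluated[1]], 0)       # similar at short range
  expect_lt(mc$statistic[max(evaluated)], 0)     # dissimilar at long range
  # a single class covering every pair has constant membership: degenerate
  one <- mantel_correlogram(d_pre, geo, class_width_km = max(geo) + 2,
                            n_perm = 49, max_dist_km = max(geo) + 1)
  expect_true(is.na(one$statistic[1]))
})

test_that("environmental Mantel table ranks the generating gradient first", {
  ls <- simulate_landscape(sim_config(seed = 23))
  towns <- ls$dataset$towns
  towns$noise_cov <- rnorm(nrow(towns))
  d_pre <- sorensen_matrix(ls$truth$pre)
  d_mod <- sorensen_matrix(ls$truth$mod)
  tab <- env_mantel_table(d_pre, d_mod, towns,
                          covariates = c("gdd", "noise_cov"), n_perm = 99,
                          seed = 4)
  r_gdd <- tab$r_m[tab$covariate == "gdd" & tab$era == "precolonial"]
  r_noise <- tab$r_m[tab$covariate == "noise_cov" &
                       tab$era == "precolonial"]
  expect_gt(r_gdd, r_noise)
  expect_warning(env_mantel_table(d_pre, d_mod, towns,
                                  covariates = "absent_cov", n_perm = 49),
                 "skipped")
})
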