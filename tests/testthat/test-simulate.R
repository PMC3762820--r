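test_that("Gaussian niche profiles follow the stated formula", {
  niches <- data.frame(taxon = c("OAK", "MAPLE", "SPRUCES"),
                       opt_gdd = c(4000, 3000, 2200),
                       width_gdd = c(400, 800, 350),
                       peak = c(1, 0.5, 0.8))
  gdd <- 3100
  manual <- niches$peak *
    exp(-(gdd - niches$opt_gdd)^2 / (2 * niches$width_gdd^2))
  manual <- manual / sum(manual)
  expect_equal(unname(true_composition(gdd, niches)), manual)

  # a taxon sitting alone at its optimum gets everything
  lone <- data.frame(taxon = c("OAK", "FIR"), opt_gdd = c(4000, 2000),
                     width_gdd = c(100, 100), peak = c(1, 1))
  p <- true_composition(4000, lone)
  expect_gte(unname(p["OAK"]), 1 - 1e-20)

  # symmetric taxa split evenly at the midpoint
  sym <- data.frame(taxon = c("A", "B"), opt_gdd = c(2800, 3200),
                    width_gdd = c(300, 300), peak = c(0.7, 0.7))
  expect_equal(unname(true_composition(3000, sym)), c(0.5, 0.5))
})

test_that("the era-shift operator multiplies and renormalizes", {
  pre <- c(CHESTNUT = 0.10, OAK = 0.50, MAPLE = 0.40)
  rules <- data.frame(taxon = "CHESTNUT", a = 0, b = 0)
  mod <- era_shift(pre, agri = 0.3, rules)
  expect_equal(unname(mod["CHESTNUT"]), 0)
  expect_equal(unname(mod["OAK"]), 0.5 / 0.9)
  expect_equal(unname(mod["MAPLE"]), 0.4 / 0.9)

  # identity when all multipliers are one
  expect_equal(era_shift(pre, 0.5, data.frame(taxon = character(0),
                                              a = numeric(0),
                                              b = numeric(0))), pre)

  # linear-in-agriculture rule: beech x (1 - 0.8 * 0.5) = x 0.6
  pre2 <- c(BEECH = 0.5, MAPLE = 0.5)
  mod2 <- era_shift(pre2, 0.5, data.frame(taxon = "BEECH", a = 1, b = -0.8))
  expect_equal(unname(mod2["BEECH"]), 0.3 / 0.8)
})

test_that("multinomial witness draws match the profile within 3 SE", {
  set.seed(41)
  profile <- c(OAK = 0.5, MAPLE = 0.3, BEECH = 0.15, FIR = 0.05)
  n <- 1e5
  counts <- sample_witness_trees(profile, n)
  phat <- counts / n
  se <- sqrt(profile * (1 - profile) / n)
  expect_true(all(abs(phat - profile) <= 3 * se))
})

test_that("plot-level variance shrinks monotonically with theta", {
  profile <- c(A = 0.5, B = 0.3, C = 0.2)
  v <- vapply(c(2, 20, 200), function(th) {
    set.seed(17)
    counts <- sample_fia_plots(profile, n_plots = 300, m_trees = 200,
                               theta = th)
    var(counts[, "A"] / rowSums(counts))
  }, numeric(1))
  expect_true(all(diff(v) < 0))
})

test_that("the generator is fully deterministic under a fixed seed", {
  cfg <- sim_config(n_x = 2, n_y = 2, seed = 99)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_landscape(simulate_landscape(cfg), d1)
  write_landscape(simulate_landscape(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("generated landscapes have gradient-driven spatial structure", {
  ls <- simulate_landscape(sim_config(seed = 5))
  geo <- geo_distances(ls$dataset$towns)
  d_pre <- sorensen_matrix(ls$truth$pre)
  mc <- mantel_correlogram(d_pre, geo, class_width_km = 80, n_perm = 999,
                           seed = 2)
  first <- which(mc$n_pairs > 0)[1]
  expect_gt(mc$statistic[first], 0)
  expect_true(mc$significant[first])
})

test_that("a JSON config file reproduces the in-code configuration", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(
    n_x = 2, n_y = 2, seed = 77, theta = 10,
    shift_rules = data.frame(taxon = "CHESTNUT", a = 0, b = 0)),
    auto_unbox = TRUE, digits = NA), path)
  cfg <- sim_config_from_json(path)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$theta, 10)
  expect_equal(cfg$shift_rules$taxon, "CHESTNUT")
  ref <- sim_config(n_x = 2, n_y = 2, seed = 77, theta = 10,
                    shift_rules = data.frame(taxon = "CHESTNUT", a = 0,
                                             b = 0))
  expect_identical(simulate_landscape(cfg)$truth,
                   simulate_landscape(ref)$truth)

  writeLines('{"bogus_key": 1}', path)
  expect_error(sim_config_from_json(path), "bogus_key")
})
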