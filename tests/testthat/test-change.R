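test_that("Sorensen dissimilarity follows the abundance formula", {
  expect_equal(sorensen(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(sorensen(c(1, 0), c(0, 1)), 1)  # disjoint support
  expect_equal(sorensen(c(0.6, 0.4), c(0.2, 0.8)), 0.4)
  expect_error(sorensen(c(1, 0), c(1, 0, 0)), "length")
})

test_that("sorensen is a symmetric bounded semimetric on the simplex", {
  set.seed(20)
  for (r in 1:25) {
    x <- as.vector(random_composition(1, 8))
    y <- as.vector(random_composition(1, 8))
    expect_equal(sorensen(x, y), sorensen(y, x))
    expect_gte(sorensen(x, y), 0)
    expect_lte(sorensen(x, y), 1)
    expect_equal(sorensen(x, x), 0)
  }
})

test_that("pairwise matrix agrees with vegan's Bray-Curtis on proportions", {
  set.seed(21)
  comp <- random_composition(12, 10)
  rownames(comp) <- paste0("T", 1:12)
  d <- sorensen_matrix(comp)
  expect_equal(as.vector(as.dist(d)),
               as.vector(vegan::vegdist(comp, method = "bray")),
               tolerance = 1e-12)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
})

test_that("per-town change has the expected extremes and correlates with
           the configured land-use driver", {
  taxa <- taxon_codes()
  pre <- random_composition(4, 24)
  colnames(pre) <- taxa
  rownames(pre) <- paste0("T", 1:4)
  same <- change_per_town(pre, pre)
  expect_true(all(same$change == 0))

  # full swap of two disjoint taxa gives change 1
  pre2 <- matrix(0, 2, 24, dimnames = list(c("A", "B"), taxa))
  pre2[, "OAK"] <- 1
  mod2 <- matrix(0, 2, 24, dimnames = list(c("A", "B"), taxa))
  mod2[, "MAPLE"] <- 1
  expect_true(all(change_per_town(pre2, mod2)$change == 1))

  # in the synthetic landscape, change rises with agricultural clearing
  ls <- simulate_landscape(sim_config(seed = 13))
  ch <- change_per_town(ls$truth$pre, ls$truth$mod)
  agri <- ls$truth$agri[match(names(ch$change), ls$truth$town_id)]
  expect_gt(cor(ch$change, agri), 0)
})

test_that("paired Monte Carlo test behaves at its logical extremes", {
  x <- runif(20)
  expect_equal(paired_monte_carlo(x, x, n_rand = 99, seed = 1)$p, 1)
  pre <- runif(100) + 0.3
  mod <- pre - 0.3
  out <- paired_monte_carlo(pre, mod, n_rand = 10000, seed = 2)
  expect_equal(out$p, 1 / 10001)
  expect_error(paired_monte_carlo(1, 2), "at least 2")
})

test_that("paired Monte Carlo p is invariant to swapping the columns", {
  set.seed(30)
  a <- rnorm(40)
  b <- rnorm(40, 0.2)
  p1 <- paired_monte_carlo(a, b, n_rand = 999, seed = 7)$p
  p2 <- paired_monte_carlo(b, a, n_rand = 999, seed = 7)$p
  expect_equal(p1, p2)
})

test_that("group permutation tests flag separated groups only", {
  vals <- c(rnorm(15, 0, 1), rnorm(15, 30, 1))  # 10+ sd separation
  labs <- rep(c("a", "b"), each = 15)
  p <- group_permutation(vals, labs, n_rand = 999, seed = 3)
  expect_lte(p["a", "b"], 2 / 1000 + 1e-12)

  same <- rep(c(1, 2, 3, 4, 5), 4)
  p2 <- group_permutation(same, rep(c("a", "b"), each = 10), n_rand = 499,
                          seed = 4)
  expect_equal(p2["a", "b"], 1)

  # degenerate group (singleton) is NA, not an error
  p3 <- group_permutation(c(1, 2, 3, 4, 10), c("a", "a", "a", "a", "b"),
                          n_rand = 99, seed = 5)
  expect_true(is.na(p3["a", "b"]))
})

test_that("beta diversity means match hand arithmetic and detect
           homogenization", {
  # 3 towns with pairwise distances d(1,2)=0.2, d(1,3)=0.4, d(2,3)=0.6:
  # per-town means are 0.3, 0.4, 0.5. Build compositions realizing these
  # L1/2 distances on 4 taxa.
  comp <- rbind(c(0.6, 0.4, 0.0, 0.0),
                c(0.4, 0.4, 0.0, 0.2),
                c(0.6, 0.0, 0.4, 0.0))
  rownames(comp) <- c("A", "B", "C")
  d <- sorensen_matrix(comp)
  expect_equal(unname(d["A", "B"]), 0.2)
  expect_equal(unname(d["A", "C"]), 0.4)
  expect_equal(unname(d["B", "C"]), 0.6)
  bd <- beta_diversity(comp, comp, n_rand = 99)
  got <- bd$per_town$beta[bd$per_town$era == "precolonial"]
  expect_equal(got, c(0.3, 0.4, 0.5))

  # identical towns give all-zero means
  same <- matrix(rep(c(0.25, 0.25, 0.25, 0.25), 3), 3, byrow = TRUE)
  rownames(same) <- c("A", "B", "C")
  expect_true(all(beta_diversity(same, same,
                                 n_rand = 99)$per_town$beta == 0))

  # a shift pushing every town toward maple homogenizes the modern era
  ls <- simulate_landscape(sim_config(seed = 13))
  bd2 <- beta_diversity(ls$truth$pre, ls$truth$mod, n_rand = 199, seed = 1)
  expect_lt(bd2$era_summary$mean[bd2$era_summary$era == "modern"],
            bd2$era_summary$mean[bd2$era_summary$era == "precolonial"])
})

test_that("beta diversity is invariant to town ordering", {
  set.seed(33)
  comp <- random_composition(6, 24)
  colnames(comp) <- taxon_codes()
  rownames(comp) <- paste0("T", 1:6)
  b1 <- beta_diversity(comp, comp, n_rand = 49, seed = 1)$per_town
  perm <- c(4, 2, 6, 1, 3, 5)
  b2 <- beta_diversity(comp[perm, ], comp[perm, ], n_rand = 49,
                       seed = 1)$per_town
  m <- match(b1$town_id[b1$era == "modern"],
             b2$town_id[b2$era == "modern"])
  expect_equal(b1$beta[b1$era == "modern"],
               b2$beta[b2$era == "modern"][m])
})

test_that("abundance change table recovers extirpation and known shifts", {
  taxa <- taxon_codes()
  pre <- random_composition(6, 24)
  colnames(pre) <- taxa
  rownames(pre) <- paste0("T", 1:6)
  mod <- pre
  mod[, "CHESTNUT"] <- 0
  mod <- mod / rowSums(mod)
  tab <- abundance_change_table(pre, mod, n_rand = 199, seed = 2)
  ch_row <- tab[tab$taxon == "CHESTNUT", ]
  expect_equal(ch_row$mean_mod, 0)
  expect_equal(ch_row$delta, -ch_row$mean_pre)
})
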