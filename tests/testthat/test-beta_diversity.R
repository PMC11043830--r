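test_that("Bray-Curtis partition reproduces worked examples", {
  p <- bray_curtis_partition(c(3, 5, 2), c(3, 5, 2))
  expect_equal(c(p$beta_bc, p$beta_bal, p$beta_gra), c(0, 0, 0))

  # pure substitution: disjoint supports, equal totals
  p <- bray_curtis_partition(c(3, 0), c(0, 3))
  expect_equal(p$A, 0)
  expect_equal(c(p$beta_bc, p$beta_bal, p$beta_gra), c(1, 1, 0))

  # pure abundance loss: one plot dominates species-wise
  p <- bray_curtis_partition(c(4, 2), c(2, 2))
  expect_equal(c(p$A, p$B, p$C), c(4, 2, 0))
  expect_equal(c(p$beta_bc, p$beta_bal, p$beta_gra), c(0.2, 0, 0.2))
})

test_that("both-empty pairs give an undefined (NA) partition", {
  p <- bray_curtis_partition(c(0, 0), c(0, 0))
  expect_true(all(is.na(c(p$beta_bc, p$beta_bal, p$beta_gra))))
  expect_error(bray_curtis_partition(c(1, 2), c(1, 2, 3)), "same species")
})

test_that("partition components are additive, bounded, and symmetric", {
  set.seed(99)
  for (i in 1:1000) {
    n <- sample(2:15, 1)
    x <- rpois(n, 3)
    y <- rpois(n, 3)
    if (sum(x) + sum(y) == 0) x[1] <- 1
    p <- bray_curtis_partition(x, y)
    expect_equal(p$beta_bal + p$beta_gra, p$beta_bc, tolerance = 1e-12)
    expect_true(all(c(p$beta_bc, p$beta_bal, p$beta_gra) >= 0))
    expect_true(all(c(p$beta_bc, p$beta_bal, p$beta_gra) <= 1))
    q <- bray_curtis_partition(y, x)
    expect_equal(q$beta_bc, p$beta_bc)
    expect_equal(q$beta_bal, p$beta_bal)
    expect_equal(q$beta_gra, p$beta_gra)
    expect_equal(c(q$B, q$C), c(p$C, p$B))
  }
})

test_that("beta_bc matches the classical Bray-Curtis oracle", {
  set.seed(12)
  for (i in 1:200) {
    x <- rpois(10, 4); y <- rpois(10, 4)
    if (sum(x) + sum(y) == 0) next
    oracle <- sum(abs(x - y)) / sum(x + y)
    expect_equal(bray_curtis_partition(x, y)$beta_bc, oracle,
                 tolerance = 1e-12)
  }
})

test_that("beta_bc agrees with vegan's Bray-Curtis on a random matrix", {
  skip_if_not_installed("vegan")
  set.seed(8)
  m <- matrix(rpois(60, 3) + 1, nrow = 6)
  expect_equal(as.vector(bray_curtis_dist(m)),
               as.vector(vegan::vegdist(m, method = "bray")),
               tolerance = 1e-12)
})

test_that("nestedness and substitution limits hold", {
  set.seed(21)
  for (i in 1:100) {
    x <- rpois(8, 5) + 1
    y <- pmax(x - rpois(8, 2), 0)       # y componentwise <= x
    expect_equal(bray_curtis_partition(x, y)$beta_bal, 0)
    a <- c(rpois(4, 5) + 1, rep(0, 4))
    b <- c(rep(0, 4), rpois(4, 5) + 1)
    b <- b * sum(a) / sum(b)            # disjoint, equal totals
    p <- bray_curtis_partition(a, b)
    expect_equal(p$beta_bal, p$beta_bc, tolerance = 1e-12)
    expect_equal(p$beta_gra, 0, tolerance = 1e-12)
  }
})

test_that("per-unit beta means equal brute-force pairwise row means", {
  # quadrat of identical cells: all dissimilarities zero
  ds <- one_quadrat_dataset()
  pb <- per_unit_beta(aggregate_counts(ds, "cell"))
  expect_equal(pb$units$beta_bc, rep(0, 25))

  # 3 quadrats in one plot vs explicit enumeration of the 3 pairs
  set.seed(5)
  rec <- do.call(rbind, lapply(1:3, function(q)
    make_records(quadrat_id = as.character(q), cell_id = "1",
                 species = c("a", "b", "c"), count = rpois(3, 4) + 1L)))
  cm <- aggregate_counts(community_dataset(rec), "quadrat")
  pb <- per_unit_beta(cm)
  for (j in 1:3) {
    others <- setdiff(1:3, j)
    expected <- mean(sapply(others, function(k)
      bray_curtis_partition(cm$x[j, ], cm$x[k, ])$beta_bc))
    expect_equal(pb$units$beta_bc[j], expected, tolerance = 1e-12)
  }
  expect_equal(pb$units$n_pairs, rep(2, 3))
})

test_that("singleton comparison groups are skipped with a warning", {
  rec <- rbind(make_records(quadrat_id = "1", cell_id = c("1", "2"),
                            count = c(1L, 2L)),
               make_records(quadrat_id = "2", cell_id = "1", count = 3L))
  cm <- aggregate_counts(community_dataset(rec), "cell")
  expect_warning(pb <- per_unit_beta(cm), "size 1")
  expect_equal(nrow(pb$units), 2)  # only the two-cell quadrat remains
})

test_that("homogenization lowers within-treatment quadrat beta", {
  cfg <- small_config(seed = 3, homogenization = 1, richness_effect = 0,
                      evenness_effect = 0, density_multiplier = 1)
  pb <- per_unit_beta(aggregate_counts(simulate_dataset(cfg), "quadrat"))
  m <- pb$summary[pb$summary$statistic == "beta_bal", ]
  expect_lt(m$mean[m$treatment == "presence"],
            m$mean[m$treatment == "absence"])
})

test_that("SCBD is the species share of the total sum of squares", {
  m <- rbind(c(1, 2), c(3, 2))
  colnames(m) <- c("sp1", "sp2")
  out <- scbd(m)
  expect_equal(out$scbd[out$species == "sp1"], 1)
  expect_equal(out$scbd[out$species == "sp2"], 0)

  m2 <- rbind(c(0, 2), c(2, 0))
  colnames(m2) <- c("sp1", "sp2")
  expect_equal(scbd(m2)$scbd, c(0.5, 0.5))

  set.seed(31)
  m3 <- matrix(rpois(80, 3), nrow = 8,
               dimnames = list(NULL, sprintf("s%02d", 1:10)))
  expect_equal(sum(scbd(m3)$scbd), 1, tolerance = 1e-12)
  expect_true(all(scbd(m3)$scbd >= 0 & scbd(m3)$scbd <= 1))

  ident <- matrix(rep(c(1, 2), each = 3), nrow = 3,
                  dimnames = list(NULL, c("a", "b")))
  expect_error(scbd(ident), "sum of squares")
  expect_error(scbd(m3[1, , drop = FALSE]), "2 units")
})
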