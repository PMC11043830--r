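make_groups <- function(seed, n_per = 5, sep = 6) {
  set.seed(seed)
  m <- rbind(matrix(rpois(n_per * 6, 3), n_per),
             matrix(rpois(n_per * 6, 3) + sep, n_per))
  list(d = bray_curtis_dist(m),
       labels = rep(c("g1", "g2"), each = n_per))
}

test_that("PERMANOVA detects well-separated groups at the attainable floor", {
  g <- make_groups(1, sep = 8)
  res <- permanova(g$d, g$labels, n_perm = 999, seed = 10)
  # permutations that map each group onto a group reproduce the observed
  # partition (and F) exactly; with two groups of 5 they are 2 of the 252
  # distinct splits, so the attainable minimum p is about 0.008, not
  # 1 / (n_perm + 1)
  expect_lte(res$p_perm, 0.015)
  expect_gt(res$pseudo_F, 1)
  expect_equal(res$df_between, 1)
  expect_equal(res$df_within, 8)
})

test_that("PERMANOVA pseudo-F is invariant to relabeling and reordering", {
  g <- make_groups(2, sep = 2)
  f1 <- permanova(g$d, g$labels, n_perm = 99, seed = 1)$pseudo_F
  relab <- ifelse(g$labels == "g1", "B", "A")
  expect_equal(permanova(g$d, relab, n_perm = 99, seed = 1)$pseudo_F, f1)
  set.seed(3)
  ord <- sample(length(g$labels))
  d2 <- as.matrix(g$d)[ord, ord]
  expect_equal(permanova(d2, g$labels[ord], n_perm = 99, seed = 1)$pseudo_F,
               f1, tolerance = 1e-12)
})

test_that("PERMANOVA pseudo-F matches vegan::adonis2", {
  skip_if_not_installed("vegan")
  g <- make_groups(6, sep = 3)
  mine <- permanova(g$d, g$labels, n_perm = 99, seed = 4)$pseudo_F
  ref <- vegan::adonis2(g$d ~ grp,
                        data = data.frame(grp = g$labels),
                        permutations = 2)$F[1]
  expect_equal(mine, ref, tolerance = 1e-10)
})

test_that("Monte-Carlo PERMANOVA p approaches the exhaustive-enumeration p", {
  set.seed(9)
  m <- matrix(rpois(36, 4), nrow = 6)
  labels <- rep(c("a", "b"), each = 3)
  d <- bray_curtis_dist(m)
  res <- permanova(d, labels, n_perm = 4999, seed = 77)

  # brute force over all 6! label orderings
  allp <- expand.grid(rep(list(1:6), 6))
  allp <- allp[apply(allp, 1, function(r) length(unique(r)) == 6), ]
  d2 <- as.matrix(d)^2
  n <- 6
  ss_total <- sum(d2[upper.tri(d2)]) / n
  f_of <- function(lab) {
    ssw <- 0
    for (g in unique(lab)) {
      idx <- which(lab == g)
      ssw <- ssw + sum(d2[idx, idx][upper.tri(diag(3))]) / 3
    }
    ((ss_total - ssw) / 1) / (ssw / 4)
  }
  f_obs <- f_of(labels)
  f_all <- apply(allp, 1, function(ord) f_of(labels[as.integer(ord)]))
  exact_p <- mean(f_all >= f_obs - 1e-12)
  expect_equal(res$p_perm, exact_p, tolerance = 0.02)
})

test_that("degenerate distance input raises an error and p is never zero", {
  d0 <- matrix(0, 4, 4)
  expect_error(permanova(d0, rep(c("a", "b"), 2), n_perm = 99, seed = 1),
               "zero")
  g <- make_groups(5, sep = 10)
  res <- permanova(g$d, g$labels, n_perm = 99, seed = 2)
  expect_gte(res$p_perm, 1 / 100)
})

test_that("paired contrast handles the null and a saturating shift", {
  vals <- rep(c(3, 3), 10)
  trt <- rep(c("absence", "presence"), 10)
  blk <- rep(sprintf("b%02d", 1:10), each = 2)
  res <- paired_permutation_contrast(vals, trt, blk, n_perm = 999,
                                     seed = 1)
  expect_equal(res$effect, 0)
  expect_equal(res$p_value, 1)

  shifted <- ifelse(trt == "presence", 4, 3)
  res2 <- paired_permutation_contrast(shifted, trt, blk, n_perm = 999,
                                      seed = 2)
  expect_equal(res2$effect, 1)
  expect_lt(res2$p_value, 0.02)

  expect_error(paired_permutation_contrast(1:3, rep("absence", 3),
                                           c("a", "a", "b"), seed = 1),
               "both treatments")
})

test_that("Monte-Carlo paired contrast p matches 2^3 exhaustive enumeration", {
  vals <- c(5, 3, 4, 4.5, 7, 2)
  trt <- rep(c("presence", "absence"), 3)
  blk <- rep(c("b1", "b2", "b3"), each = 2)
  obs <- mean(vals[trt == "presence"]) - mean(vals[trt == "absence"])
  effs <- sapply(0:7, function(mask) {
    flips <- as.logical(bitwAnd(mask, c(1, 2, 4)))
    t2 <- trt
    for (b in which(flips)) {
      i <- which(blk == unique(blk)[b])
      t2[i] <- rev(t2[i])
    }
    mean(vals[t2 == "presence"]) - mean(vals[t2 == "absence"])
  })
  exact_p <- mean(abs(effs) >= abs(obs) - 1e-12)
  res <- paired_permutation_contrast(vals, trt, blk, n_perm = 9999,
                                     seed = 3)
  expect_equal(res$p_value, exact_p, tolerance = 0.02)
})

test_that("growth-form summaries split shoots and richness by form", {
  rec <- make_records(species = c("a1", "a2", "p1"),
                      count = c(2L, 1L, 1L))
  reg <- data.frame(species = c("a1", "a2", "p1"),
                    genus = c("g1", "g2", "g3"),
                    growth_form = c("acrocarp", "acrocarp", "pleurocarp"))
  gs <- growth_form_summary(community_dataset(rec, reg), "cell")
  u <- gs$units
  expect_equal(u$rel_abundance[u$form == "acrocarp"], 0.75)
  expect_equal(u$rel_abundance[u$form == "pleurocarp"], 0.25)
  expect_equal(u$richness[u$form == "acrocarp"], 2L)
  expect_equal(sum(u$rel_abundance), 1)

  only_acro <- community_dataset(
    make_records(species = c("a1", "a2"), count = c(3L, 2L)),
    reg)
  gs2 <- growth_form_summary(only_acro, "cell")
  expect_equal(gs2$units$rel_abundance[gs2$units$form == "acrocarp"], 1)

  bad_reg <- reg[1:2, ]
  expect_error(growth_form_summary(community_dataset(rec, bad_reg),
                                   "cell"),
               "missing from registry")
  expect_error(growth_form_summary(community_dataset(rec), "cell"),
               "registry")
})

test_that("a 34-acrocarp vs 16-pleurocarp pool gives higher acrocarp richness", {
  ds <- simulate_dataset(synthetic_config(n_pairs = 4, sad_sigma = 0,
                                          seed = 12))
  for (sc in c("cell", "quadrat", "exclosure")) {
    s <- growth_form_summary(ds, sc)$summary
    for (trt in unique(s$treatment))
      expect_gt(s$richness_mean[s$form == "acrocarp" & s$treatment == trt],
                s$richness_mean[s$form == "pleurocarp" &
                                  s$treatment == trt])
  }
})
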