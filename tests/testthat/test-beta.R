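test_that("unweighted UniFrac handles identity, disjoint and oracle cases", {
  tr <- ape::read.tree(text = "((A:1,B:2):1,(C:1,D:1):2);")
  expect_equal(unweighted_unifrac(tr, c("A", "B"), c("A", "B")), 0)
  expect_equal(unweighted_unifrac(tr, c("A", "B"), c("C", "D")), 1)
  expect_error(unweighted_unifrac(tr, character(0), "A"), "empty")
  set.seed(31)
  for (i in 1:60) {
    n <- sample(4:10, 1)
    tree <- random_bl_tree(n, seed = 100 + i)
    a <- sample(tree$tip.label, sample(1:n, 1))
    b <- sample(tree$tip.label, sample(1:n, 1))
    expect_equal(unweighted_unifrac(tree, a, b),
                 oracle_unweighted_unifrac(tree, a, b))
  }
})

test_that("weighted UniFrac matches the branch-enumeration oracle", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  expect_equal(weighted_unifrac(tr, c(A = 5, B = 0), c(A = 0, B = 3)), 1)
  expect_equal(weighted_unifrac(tr, c(A = 2, B = 2), c(A = 4, B = 4)), 0)
  set.seed(77)
  for (i in 1:60) {
    n <- sample(4:10, 1)
    tree <- random_bl_tree(n, seed = 300 + i)
    a <- setNames(rpois(n, 4), tree$tip.label)
    b <- setNames(rpois(n, 4), tree$tip.label)
    if (sum(a) == 0 || sum(b) == 0) next
    for (norm in c(TRUE, FALSE)) {
      expect_equal(weighted_unifrac(tree, a, b, normalized = norm),
                   oracle_weighted_unifrac(tree, a, b, normalized = norm),
                   tolerance = 1e-12)
    }
  }
})

test_that("UniFrac agrees with an independent implementation", {
  skip_if_not_installed("picante")
  sim <- small_sim(n_triplets = 3)
  D <- pairwise_distances(sim$counts, "unweighted-unifrac", tree = sim$tree)
  comm <- t(count_matrix(sim$counts))
  ref <- as.matrix(picante::unifrac(comm, sim$tree))
  expect_equal(unclass(D)[rownames(ref), colnames(ref)], ref,
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("sqrt-JSD matches direct summation, its bound and the triangle inequality", {
  expect_equal(jsd_distance(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(jsd_distance(c(1, 0), c(0, 1)), sqrt(log(2)))
  p <- c(0.5, 0.5); q <- c(0.9, 0.1)
  m <- (p + q) / 2
  direct <- sqrt(0.5 * sum(p * log(p / m)) + 0.5 * sum(q * log(q / m)))
  expect_equal(jsd_distance(p, q), direct)
  expect_error(jsd_distance(c(-0.1, 1.1), c(0.5, 0.5)), "negative")
  set.seed(5)
  for (i in 1:1000) {
    tri <- matrix(rgamma(12, 0.5), 3)
    tri <- tri / rowSums(tri)
    d_ab <- jsd_distance(tri[1, ], tri[2, ])
    d_bc <- jsd_distance(tri[2, ], tri[3, ])
    d_ac <- jsd_distance(tri[1, ], tri[3, ])
    expect_lte(d_ac, d_ab + d_bc + 1e-12)
  }
})

test_that("pairwise_distances reproduces the per-pair operations entrywise", {
  sim <- small_sim(n_triplets = 2, n_otus = 30, n_genera = 10)
  m <- count_matrix(sim$counts)
  Du <- pairwise_distances(sim$counts, "unweighted-unifrac", tree = sim$tree)
  Dw <- pairwise_distances(sim$counts, "weighted-unifrac", tree = sim$tree)
  rel <- to_relative(sim$counts)
  Dj <- pairwise_distances(rel, "sqrt-jsd")
  P <- count_matrix(rel)
  for (i in 1:3) for (j in 4:6) {
    a <- m[, i]; b <- m[, j]
    expect_equal(Du[i, j],
                 unweighted_unifrac(sim$tree, names(a)[a > 0], names(b)[b > 0]),
                 tolerance = 1e-12)
    expect_equal(Dw[i, j], weighted_unifrac(sim$tree, a, b), tolerance = 1e-12)
    expect_equal(Dj[i, j], jsd_distance(P[, i], P[, j]), tolerance = 1e-12)
  }
  # duplicated sample columns are at distance zero
  dup <- sim$counts[, c(1, 2, 2 + 1)]
  names(dup) <- c("taxon_id", "s1", "s2")
  dup$s2 <- dup$s1
  D0 <- pairwise_distances(dup, "weighted-unifrac", tree = sim$tree)
  expect_equal(D0[1, 2], 0)
})

test_that("distance matrices satisfy the metric axioms and ranges", {
  sim <- small_sim(n_triplets = 3)
  for (metric in c("unweighted-unifrac", "weighted-unifrac")) {
    D <- pairwise_distances(sim$counts, metric, tree = sim$tree)
    expect_equal(unclass(D), t(unclass(D)))
    expect_true(all(diag(D) == 0))
    expect_true(all(D >= 0 & D <= 1 + 1e-9))
  }
  rel <- to_relative(sim$counts)
  Dj <- pairwise_distances(rel, "sqrt-jsd")
  expect_true(max(Dj) <= sqrt(log(2)) + 1e-9)
  expect_error(new_beta_dist(matrix(c(0, 1, 2, 0), 2), "unweighted-unifrac"),
               "symmetric|range")
})

test_that("beta group summary bins pairs into six categories with sane inference", {
  sim <- small_sim(n_triplets = 6)
  D <- pairwise_distances(to_relative(sim$counts), "sqrt-jsd")
  bg <- beta_group_summary(D, sim$metadata)
  expect_equal(nrow(bg$summary), 6)
  n <- nrow(D)
  expect_equal(sum(bg$summary$n_pairs), choose(n, 2))
  expect_equal(nrow(bg$tukey), choose(6, 2))
  expect_true(bg$anova$p_value >= 0 && bg$anova$p_value <= 1)
})

test_that("a hand-built two-cluster geometry separates between from within", {
  # two tight triples far apart: within ~0.1-0.2, across 10
  ids <- c("a1", "a2", "a3", "b1", "b2", "b3")
  M <- matrix(10, 6, 6, dimnames = list(ids, ids))
  M[1:3, 1:3] <- 0.1
  M[4:6, 4:6] <- 0.2
  diag(M) <- 0
  D <- new_beta_dist(M, "other")
  md <- tibble::tibble(sample_id = ids,
                       skin_type = factor(rep(c("control", "lesion"), each = 3),
                                          levels = c("control", "unaffected", "lesion")))
  bg <- beta_group_summary(D, md)
  s <- bg$summary
  within_mean <- mean(s$mean[grepl("^within", s$category)])
  between_mean <- s$mean[s$category == "control–lesion"]
  expect_gt(between_mean, within_mean)
  expect_lt(bg$anova$p_value, 0.001)
})
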