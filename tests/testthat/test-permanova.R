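euclid_1d_dist <- function(y, ids = sprintf("s%02d", seq_along(y))) {
  new_beta_dist(as.matrix(dist(y)) |>
                  (\(m) {dimnames(m) <- list(ids, ids); m})(), "euclidean")
}

test_that("pseudo-F on 1-D Euclidean data equals the classical ANOVA F", {
  set.seed(2)
  y <- rnorm(14)
  g <- factor(rep(c("a", "b"), each = 7))
  md <- tibble::tibble(sample_id = sprintf("s%02d", 1:14), grp = g)
  fit <- adonis_dm(euclid_1d_dist(y), md, ~ grp, permutations = 49, seed = 1)
  f_classic <- summary(stats::aov(y ~ g))[[1]]$`F value`[1]
  expect_equal(fit$table$pseudo_F[1], f_classic, tolerance = 1e-10)
  # and for a 3-level factor
  g3 <- factor(rep(c("a", "b", "c"), times = c(5, 4, 5)))
  md3 <- tibble::tibble(sample_id = sprintf("s%02d", 1:14), grp = g3)
  fit3 <- adonis_dm(euclid_1d_dist(y), md3, ~ grp, permutations = 49, seed = 1)
  expect_equal(fit3$table$pseudo_F[1],
               summary(stats::aov(y ~ g3))[[1]]$`F value`[1], tolerance = 1e-10)
})

test_that("sums of squares decompose the total exactly", {
  sim <- small_sim(n_triplets = 5)
  D <- pairwise_distances(to_relative(sim$counts), "sqrt-jsd")
  fit <- adonis_dm(D, sim$metadata, ~ skin_type + body_site,
                   permutations = 19, seed = 2)
  tab <- fit$table
  terms_ss <- sum(tab$sum_of_squares[!tab$term %in% c("Residual", "Total")])
  expect_equal(terms_ss + tab$sum_of_squares[tab$term == "Residual"],
               tab$sum_of_squares[tab$term == "Total"], tolerance = 1e-8)
  n <- nrow(D)
  expect_equal(tab$sum_of_squares[tab$term == "Total"],
               sum(unclass(D)[upper.tri(D)]^2) / n, tolerance = 1e-8)
})

test_that("sequential SS and F agree with vegan's adonis2", {
  skip_if_not_installed("vegan")
  sim <- small_sim(n_triplets = 6)
  D <- pairwise_distances(to_relative(sim$counts), "sqrt-jsd")
  md <- as.data.frame(sim$metadata)
  fit <- adonis_dm(D, md, ~ skin_type + body_site, permutations = 19, seed = 3)
  ref <- vegan::adonis2(as.dist(unclass(D)) ~ skin_type + body_site,
                        data = md, permutations = 19, by = "terms")
  expect_equal(fit$table$sum_of_squares[1:2], ref$SumOfSqs[1:2], tolerance = 1e-8)
  expect_equal(fit$table$pseudo_F[1:2], ref$F[1:2], tolerance = 1e-8)
  expect_equal(fit$table$df[1:2], ref$Df[1:2])
})

test_that("perfectly separated groups attain the minimal permutation p", {
  y <- c(rnorm(10), rnorm(10) + 100)
  md <- tibble::tibble(sample_id = sprintf("s%02d", 1:20),
                       grp = factor(rep(c("a", "b"), each = 10)))
  fit <- adonis_dm(euclid_1d_dist(y), md, ~ grp, permutations = 199, seed = 4)
  expect_equal(fit$table$p_value[1], 1 / 200)
})

test_that("degenerate terms and missing metadata are handled per contract", {
  y <- rnorm(8)
  md <- tibble::tibble(sample_id = sprintf("s%02d", 1:8),
                       grp = factor(rep("a", 8)),
                       g2 = factor(rep(c("a", "b"), 4)))
  expect_error(adonis_dm(euclid_1d_dist(y), md, ~ grp, permutations = 9),
               "single level")
  md2 <- md
  md2$g2[1] <- NA
  expect_message(fit <- adonis_dm(euclid_1d_dist(y), md2, ~ g2, permutations = 9),
                 "dropped 1")
  expect_equal(fit$n, 7)
})

test_that("stratified permutations respect blocks", {
  # term constant within every stratum: permutations cannot change F -> p = 1
  y <- rnorm(12)
  md <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:12),
    subj = rep(sprintf("p%d", 1:6), each = 2),
    grp = factor(rep(c("a", "b"), times = 6)))
  md_const <- md
  md_const$grp <- factor(rep(c("a", "a", "b", "b"), 3))
  # grp constant within each subject-stratum of size 2? make it so:
  md_const$grp <- factor(rep(c("a", "b"), each = 2, length.out = 12))
  fit <- adonis_dm(euclid_1d_dist(y), md_const, ~ grp, permutations = 99,
                   seed = 5, strata = "subj")
  expect_equal(fit$table$p_value[1], 1)

  # confounded design: subject effects drive the signal; stratified testing
  # removes the confounding so p grows
  set.seed(11)
  subj_eff <- rep(rnorm(6, sd = 5), each = 2)
  y2 <- subj_eff + rnorm(12, sd = 0.5)
  md_conf <- md
  md_conf$grp <- factor(rep(c("a", "b"), each = 2, length.out = 12))
  free <- adonis_dm(euclid_1d_dist(y2), md_conf, ~ grp,
                    permutations = 199, seed = 6)
  strat <- adonis_dm(euclid_1d_dist(y2), md_conf, ~ grp,
                     permutations = 199, seed = 6, strata = "subj")
  expect_gte(strat$table$p_value[1], free$table$p_value[1])
})

test_that("pairwise PERMANOVA covers all level pairs and flags the separated one", {
  set.seed(13)
  grp <- rep(c("w", "x", "y", "z"), each = 6)
  y <- rnorm(24) + ifelse(grp == "w", 50, 0)
  md <- tibble::tibble(sample_id = sprintf("s%02d", 1:24), site = factor(grp))
  res <- pairwise_adonis(euclid_1d_dist(y), md, "site",
                         permutations = 199, seed = 7)
  expect_equal(nrow(res), 6)
  sep <- grepl("w", res$comparison)
  expect_true(all(res$p_value[sep] <= 0.01))
  expect_true(all(res$p_value[!sep] > 0.05))
  expect_error(pairwise_adonis(euclid_1d_dist(y),
                               dplyr::mutate(md, site = factor(rep(c("a", "b"), 12))),
                               "site"), "3 levels")
})
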