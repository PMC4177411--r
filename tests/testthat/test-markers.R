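rel_tbl <- function(m) {
  tibble::as_tibble(as.data.frame(m), rownames = "taxon_id")
}

test_that("the abundance filter is inclusive at the threshold", {
  m <- rbind(at = c(0.01, 0.01), mid = c(0.02, 0.04), low = c(0.005, 0.005))
  colnames(m) <- c("s1", "s2")
  keep <- abundant_taxa(rel_tbl(m), 0.01)
  expect_setequal(keep, c("at", "mid"))
  # brute-force scan agreement on a random profile matrix
  set.seed(2)
  r <- matrix(rgamma(60, 0.3), 12, 5,
              dimnames = list(sprintf("t%02d", 1:12), sprintf("s%d", 1:5)))
  r <- sweep(r, 2, colSums(r), "/")
  expect_setequal(abundant_taxa(rel_tbl(r), 0.05),
                  rownames(r)[sapply(rownames(r), function(t) mean(r[t, ]) >= 0.05)])
  expect_warning(abundant_taxa(rel_tbl(r), 0.999), "no taxon")
})

test_that("Kruskal-Wallis table matches the rank formula and flags constants", {
  md <- tibble::tibble(
    sample_id = sprintf("s%d", 1:9),
    skin_type = factor(rep(c("control", "unaffected", "lesion"), each = 3),
                       levels = c("control", "unaffected", "lesion")))
  m <- rbind(ladder = c(1, 2, 3, 4, 5, 6, 7, 8, 9),
             flat = rep(0.1, 9))
  colnames(m) <- md$sample_id
  res <- kruskal_wallis_fdr(rel_tbl(m), md)
  expect_equal(res$statistic[res$taxon_id == "ladder"], 7.2, tolerance = 1e-10)
  expect_true(res$degenerate[res$taxon_id == "flat"])
  expect_equal(res$p_value[res$taxon_id == "flat"], 1)
  expect_equal(res$median_control[res$taxon_id == "ladder"], 2)
  expect_true(all(res$q_value >= res$p_value - 1e-12))
})

test_that("post hoc pairwise tests single out the shifted pair", {
  set.seed(3)
  md <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:60),
    skin_type = factor(rep(c("control", "unaffected", "lesion"), each = 20),
                       levels = c("control", "unaffected", "lesion")))
  v <- c(rnorm(20), rnorm(20), rnorm(20, 3))
  m <- rbind(shifted = (v - min(v)) / sum(v - min(v)))
  colnames(m) <- md$sample_id
  res <- posthoc_pairwise(rel_tbl(m), md, "shifted")
  expect_equal(nrow(res), 3)
  lesion_rows <- grepl("lesion", res$comparison)
  expect_true(all(res$q_value[lesion_rows] < 0.05))
  expect_gt(res$q_value[!lesion_rows], 0.05)
  expect_error(posthoc_pairwise(rel_tbl(m), md, "nope"), "not in table")
})

test_that("combined genera marker sums abundances and finds planted effects", {
  md <- tibble::tibble(
    sample_id = c("s1", "s2", "s3"),
    skin_type = factor(c("control", "unaffected", "lesion"),
                       levels = c("control", "unaffected", "lesion")))
  m <- rbind(Corynebacterium = c(0.10, 0.1, 0.1),
             Propionibacterium = c(0.05, 0.1, 0.1),
             Staphylococcus = c(0.04, 0.1, 0.1),
             Streptococcus = c(0.03, 0.1, 0.1),
             Other = c(0.78, 0.6, 0.6))
  colnames(m) <- md$sample_id
  suppressWarnings(cm <- combined_genera_marker(rel_tbl(m), md))
  expect_equal(cm$four_genus$scores$combined_abundance[1], 0.22)
  expect_equal(cm$three_genus$scores$combined_abundance[1], 0.17)

  sim <- small_sim(n_triplets = 17, cohort_seed = 21)
  rel <- to_relative(collapse_taxonomy(sim$counts, sim$taxonomy, "genus"))
  cm2 <- combined_genera_marker(rel, sim$metadata)
  sc <- cm2$four_genus$scores
  expect_gt(mean(sc$combined_abundance[sc$skin_type == "lesion"]),
            mean(sc$combined_abundance[sc$skin_type == "control"]))
  expect_lt(cm2$four_genus$kruskal$p_value, 0.05)
  expect_gt(cm2$four_genus$roc$auc, 0.5)
})

test_that("prevalence chi-square matches the textbook formula", {
  set.seed(5)
  n <- 51
  md <- tibble::tibble(
    sample_id = sprintf("s%03d", 1:(3 * n)),
    skin_type = factor(rep(c("control", "unaffected", "lesion"), each = n),
                       levels = c("control", "unaffected", "lesion")))
  pres <- c(runif(n) < 0.8, runif(n) < 0.6, runif(n) < 0.4)
  m <- rbind(tx = ifelse(pres, 3L, 0L), all = 1L)
  colnames(m) <- md$sample_id
  res <- prevalence_chi2(as_count_tbl(m), md)
  # hand Pearson chi-square on the realized 2x3 table
  tab <- table(pres, md$skin_type)
  exp_tab <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi2 <- sum((tab - exp_tab)^2 / exp_tab)
  expect_equal(res$statistic[res$taxon_id == "tx"], chi2, tolerance = 1e-10)
  expect_true(res$degenerate[res$taxon_id == "all"])
})

test_that("odds ratios follow the estimator conventions", {
  or <- odds_ratio(30, 21, 15, 36)
  expect_equal(or$sample_or, (30 * 36) / (21 * 15))
  # conditional MLE shrinks toward 1 relative to the cross-product
  expect_true(abs(log(or$estimate)) <= abs(log(or$sample_or)) + 1e-9)
  expect_true(or$conf_low <= or$estimate && or$estimate <= or$conf_high)
  set.seed(6)
  for (i in 1:20) {
    cells <- rpois(4, 15) + 1
    o <- odds_ratio(cells[1], cells[2], cells[3], cells[4])
    expect_true(abs(log(o$estimate)) <= abs(log(o$sample_or)) + 1e-9,
                label = "CMLE between sample OR and 1")
  }
  eq <- odds_ratio(20, 31, 20, 31)
  expect_equal(eq$sample_or, 1)
  expect_equal(eq$estimate, 1, tolerance = 1e-6)
})

test_that("double-positive predictor reports rates and group-pair odds ratios", {
  sim <- small_sim(n_triplets = 17, cohort_seed = 31)
  dp <- double_positive_predictor(sim$counts, sim$metadata,
                                  c("OTU3855", "OTU13613"))
  expect_equal(nrow(dp$rates), 3)
  expect_true(all(dp$rates$pct_double_positive <=
                    pmin(dp$rates[[3]], dp$rates[[4]]) + 1e-9))
  expect_named(dp$odds_ratios,
               c("lesion_vs_control", "unaffected_vs_control",
                 "lesion_vs_unaffected"))
  # markers are depleted in lesion -> OR below 1
  expect_lt(dp$odds_ratios$lesion_vs_control$estimate, 1)
  expect_error(double_positive_predictor(sim$counts, sim$metadata,
                                         c("OTU3855", "nope")), "not in table")
})

test_that("AUC equals brute-force pair concordance", {
  expect_equal(roc_auc(c(5, 6, 7), c(1, 2, 3))$auc, 1)
  expect_equal(roc_auc(c(1, 2, 3), c(2, 3, 4))$auc, oracle_auc(c(1, 2, 3), c(2, 3, 4)))
  set.seed(7)
  for (i in 1:25) {
    n1 <- sample(3:20, 1); n2 <- sample(3:20, 1)
    cases <- sample(1:10, n1, replace = TRUE)
    controls <- sample(1:10, n2, replace = TRUE)
    r <- roc_auc(cases, controls)
    expect_equal(r$auc, oracle_auc(cases, controls), tolerance = 1e-12)
    expect_equal(r$auc, r$U / (n1 * n2))
  }
  expect_error(roc_auc(numeric(0), 1:3), "empty")
})

test_that("severity correlations use lesion samples with tie-corrected rho", {
  md <- tibble::tibble(
    sample_id = sprintf("s%d", 1:12),
    skin_type = factor(rep(c("control", "lesion"), each = 6),
                       levels = c("control", "unaffected", "lesion")),
    PASI = c(rep(NA, 6), 2, 4, 6, 8, 10, 12),
    BSA = c(rep(NA, 6), rep(5, 6)),
    PGA = c(rep(NA, 6), 1, 1, 2, 2, 3, 3))
  m <- rbind(dec = c(rep(0.1, 6), 6:1 / 21),
             tied = c(rep(0.1, 6), c(2, 2, 1, 1, 3, 3) / 12))
  colnames(m) <- md$sample_id
  res <- severity_correlation(rel_tbl(m), md)
  expect_equal(res$rho[res$taxon_id == "dec" & res$score == "PASI"], -1)
  # constant score flagged undefined
  expect_true(all(res$undefined[res$score == "BSA"]))
  # tie-corrected rho equals the rank-formula value
  a <- c(2, 2, 1, 1, 3, 3) / 12
  v <- c(1, 1, 2, 2, 3, 3)
  manual <- stats::cor(rank(a), rank(v))
  expect_equal(res$rho[res$taxon_id == "tied" & res$score == "PGA"], manual,
               tolerance = 1e-12)
})

test_that("chimera QC reports flagged fraction and per-sample abundance", {
  m <- rbind(a = c(10, 0), b = c(5, 5), c = c(0, 10))
  colnames(m) <- c("s1", "s2")
  x <- as_count_tbl(m)
  flags <- c(a = TRUE, b = FALSE, c = FALSE)
  qc <- chimera_qc_summary(x, flags)
  expect_equal(qc$pct_flagged, 33.3)
  expect_equal(qc$per_sample$flagged_abundance, c(10 / 15, 0))
  qc0 <- chimera_qc_summary(x, c(a = FALSE, b = FALSE, c = FALSE))
  expect_equal(qc0$pct_flagged, 0)
  expect_error(chimera_qc_summary(x, c(TRUE, FALSE)), "length mismatch")
  # masked-sum oracle on random flags
  set.seed(8)
  y <- random_count_tbl(n_taxa = 10, n_samples = 4, seed = 9)
  fl <- setNames(runif(10) < 0.4, y$taxon_id)
  qc2 <- chimera_qc_summary(y, fl)
  my <- count_matrix(y)
  expect_equal(qc2$per_sample$flagged_abundance,
               unname(colSums(my[fl, , drop = FALSE]) / colSums(my)))
})
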