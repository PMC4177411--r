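test_that("the generator is deterministic under fixed seeds", {
  a <- small_sim()
  b <- small_sim()
  expect_identical(a$counts, b$counts)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$truth$samples, b$truth$samples)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
})

test_that("simulated trees have the right tips and monophyletic genera", {
  tr1 <- make_tree(10, tree_seed = 3)
  tr2 <- make_tree(10, tree_seed = 3)
  expect_identical(ape::write.tree(tr1), ape::write.tree(tr2))
  expect_equal(length(tr1$tip.label), 10)
  expect_true(all(tr1$edge.length >= 0))

  sim <- small_sim()
  for (g in unique(sim$taxonomy$genus)) {
    tips <- sim$taxonomy$taxon_id[sim$taxonomy$genus == g]
    if (length(tips) > 1) {
      expect_true(ape::is.monophyletic(sim$tree, tips),
                  label = paste("genus clade", g))
    }
  }
})

test_that("cohort structure matches the triplet design", {
  sim <- small_sim()
  md <- sim$metadata
  expect_equal(nrow(md), 18)
  per_triplet <- table(md$triplet_id, md$skin_type)
  expect_true(all(per_triplet == 1))
  # lesion and unaffected share a subject; controls are distinct people
  for (tid in unique(md$triplet_id)) {
    sub <- md[md$triplet_id == tid, ]
    expect_equal(sub$subject_id[sub$skin_type == "lesion"],
                 sub$subject_id[sub$skin_type == "unaffected"])
    expect_false(sub$subject_id[sub$skin_type == "control"] %in%
                   sub$subject_id[sub$skin_type != "control"])
  }
  expect_true(all(is.na(md$PASI[md$skin_type == "control"])))
  expect_true(all(md$PASI[md$skin_type == "lesion"] > 0))
})

test_that("double-positive marker rates match the configured prevalences", {
  cfg <- simulation_config(n_triplets = 51, cohort_seed = 99, tree_seed = 98)
  sim <- simulate_cohort(cfg)
  tr <- sim$truth$samples
  target <- cfg$marker_double_prevalence
  for (ty in names(target)) {
    rate <- mean(tr$double_positive[tr$skin_type == ty])
    half_width <- 3 * sqrt(target[[ty]] * (1 - target[[ty]]) / 51)
    expect_lt(abs(rate - target[[ty]]), half_width + 1e-9)
  }
  # presence in the count table agrees with the truth ledger
  m <- count_matrix(sim$counts)
  dp_obs <- m["OTU3855", ] >= 1 & m["OTU13613", ] >= 1
  # absence is structural (probability zeroed) so table can only under-call
  expect_true(all(dp_obs[!tr$double_positive &
                           !(tr$marker_gp4 & tr$marker_schlegelella)] == FALSE))
})

test_that("sequencing depth is lognormal around the configured median", {
  sim <- simulate_cohort(simulation_config(n_triplets = 51, cohort_seed = 5))
  d <- sample_depths(sim$counts)$depth
  expect_gt(stats::median(d), 8621 * 0.8)
  expect_lt(stats::median(d), 8621 * 1.25)
})

test_that("the null configuration makes skin types exchangeable", {
  # p values of the combined-genera KW test over repeated null cohorts are
  # uniform (KS test at alpha = 0.01)
  ps <- vapply(1:200, function(s) {
    sim <- simulate_cohort(null_simulation_config(
      n_triplets = 6, n_otus = 40, n_genera = 10,
      cohort_seed = 10000 + s, tree_seed = 77))
    rel <- to_relative(collapse_taxonomy(sim$counts, sim$taxonomy, "genus"))
    suppressWarnings(
      combined_genera_marker(rel, sim$metadata)$four_genus$kruskal$p_value)
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("longitudinal cohorts share subjects, attrit 17/17/9 and shrink effects", {
  cfg <- simulation_config(n_triplets = 17, n_otus = 40, n_genera = 10,
                           cohort_seed = 12, tree_seed = 13)
  lng <- simulate_longitudinal(cfg, treatment_effect = 1)
  expect_named(lng, c("0", "12", "36"))
  n_triplets <- vapply(lng, function(s) length(unique(s$metadata$triplet_id)),
                       numeric(1))
  expect_equal(unname(n_triplets), c(17, 17, 9))
  # subjects persist across weeks
  expect_true(all(unique(lng[["36"]]$metadata$subject_id) %in%
                    unique(lng[["0"]]$metadata$subject_id)))
  # full treatment effect: multipliers collapse to the control value
  expect_equal(unname(lng[["12"]]$truth$multiplier["lesion"]),
               unname(cfg$skin_genera_multiplier["control"]))
  expect_equal(unname(lng[["36"]]$truth$multiplier["unaffected"]),
               unname(cfg$skin_genera_multiplier["control"]))
  # week 0 keeps the configured effect
  expect_equal(unname(lng[["0"]]$truth$multiplier["lesion"]), 1.6)
  expect_error(simulate_longitudinal(cfg, weeks = c(0, 24)), "subset")
})

test_that("the transient overshoot only bumps unaffected at week 12", {
  cfg <- simulation_config(n_triplets = 5, n_otus = 40, n_genera = 10,
                           cohort_seed = 3, tree_seed = 4)
  with_o <- simulate_longitudinal(cfg, treatment_effect = 0.5, overshoot = 0.8)
  without <- simulate_longitudinal(cfg, treatment_effect = 0.5, overshoot = 0)
  expect_gt(with_o[["12"]]$truth$multiplier["unaffected"],
            without[["12"]]$truth$multiplier["unaffected"])
  expect_equal(with_o[["36"]]$truth$multiplier["unaffected"],
               without[["36"]]$truth$multiplier["unaffected"])
})

test_that("written cohorts can be read back through the io layer", {
  sim <- small_sim()
  dir <- withr::local_tempdir()
  write_cohort(sim, dir)
  x <- read_count_table(file.path(dir, "otu_table.tsv"))
  expect_equal(count_matrix(x), count_matrix(sim$counts))
  tr <- read_tree(file.path(dir, "tree.nwk"))
  expect_setequal(tr$tip.label, sim$counts$taxon_id)
  md <- read_sample_metadata(file.path(dir, "metadata.tsv"))
  expect_equal(as.character(md$skin_type), as.character(sim$metadata$skin_type))
  tax <- read_taxonomy(file.path(dir, "taxonomy.tsv"))
  expect_equal(tax$genus, sim$taxonomy$genus)
})
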