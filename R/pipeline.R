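#' Run the full downstream analysis on a cohort
#'
#' Orchestrates the standard stages on one cohort — alpha diversity
#' (rarefaction + group trend), beta diversity (distance matrix + intragroup
#' / intergroup summary), Cailliez-corrected PCoA with axis tests,
#' PERMANOVA, community typing with phenotype association, and the marker
#' battery — and optionally writes each stage's tables plus a manifest to a
#' directory. Stage seeds are derived from `seed` by fixed offsets so one
#' stage's stream never perturbs another. Failure of a downstream stage is
#' recorded in the report without aborting the others.
#'
#' @param sim A `cohort_simulation` (or a list with `counts`, `metadata`,
#'   `taxonomy`, `tree`).
#' @param out_dir Optional output directory for TSV tables and the JSON
#'   manifest.
#' @param seed Master integer seed.
#' @param depths Rarefaction depth grid.
#' @param trend_depth Depth for the alpha group test.
#' @param metric Distance metric for the beta/ordination/PERMANOVA stages.
#' @param k_range Candidate cluster numbers for typing.
#' @param permutations PERMANOVA permutation count.
#' @param otu_pair OTU ids for the double-positive predictor (NULL = skip).
#' @return List of class `pipeline_report` with one element per stage.
#' @export
run_pipeline <- function(sim, out_dir = NULL, seed = 1,
                         depths = c(500, 1000, 2000), trend_depth = 2000,
                         metric = "weighted-unifrac", k_range = 2:10,
                         permutations = 199,
                         otu_pair = c("OTU3855", "OTU13613")) {
  for (el in c("counts", "metadata", "taxonomy", "tree")) {
    if (is.null(sim[[el]])) stop("input lacks '", el, "'", call. = FALSE)
  }
  report <- list(seed = seed)
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      warning("stage '", name, "' failed: ", conditionMessage(e))
      structure(list(stage = name, message = conditionMessage(e)),
                class = "pipeline_stage_error")
    })
  }
  counts <- sim$counts
  md <- sim$metadata
  genus <- collapse_taxonomy(counts, sim$taxonomy, "genus")
  genus_rel <- to_relative(genus)

  report$alpha <- stage("alpha", {
    curve <- rarefaction_curve(counts, depths, reps = 5, seed = seed + 11L)
    list(curve = curve,
         trend = group_alpha_trend(curve, md, depth = trend_depth),
         sharing = taxa_sharing(counts, md))
  })
  report$beta <- stage("beta", {
    d <- pairwise_distances(counts, metric = metric, tree = sim$tree)
    list(dist = d, summary = beta_group_summary(d, md))
  })
  report$ordination <- stage("ordination", {
    ord <- pcoa_dm(report$beta$dist, correction = "cailliez")
    list(ordination = ord, axis_tests = axis_group_test(ord, md, axes = 1:2))
  })
  report$permanova <- stage("permanova", {
    adonis_dm(report$beta$dist, md, ~ skin_type + body_site,
              permutations = permutations, seed = seed + 13L)
  })
  report$typing <- stage("typing", {
    d_jsd <- pairwise_distances(genus_rel, metric = "sqrt-jsd")
    ty <- choose_k(d_jsd, k_range = k_range)
    assoc <- if (ty$k >= 2) cutaneotype_association(ty, md) else NULL
    list(typing = ty, association = assoc)
  })
  report$markers <- stage("markers", {
    rel <- to_relative(counts)
    keep <- abundant_taxa(rel)
    out <- list(
      kruskal = kruskal_wallis_fdr(rel, md, taxa = keep),
      combined_genera = combined_genera_marker(genus_rel, md),
      severity = severity_correlation(genus_rel, md,
                                      taxa = abundant_taxa(genus_rel)))
    if (!is.null(otu_pair) && all(otu_pair %in% counts$taxon_id)) {
      out$double_positive <- double_positive_predictor(counts, md, otu_pair)
      out$prevalence <- prevalence_chi2(counts, md,
                                        taxa = intersect(keep, counts$taxon_id))
    }
    out
  })
  class(report) <- "pipeline_report"
  if (!is.null(out_dir)) write_pipeline_report(report, sim, out_dir)
  report
}

write_pipeline_report <- function(report, sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ok <- function(x) !inherits(x, "pipeline_stage_error")
  if (ok(report$alpha)) {
    write_tsv_table(report$alpha$curve, file.path(out_dir, "alpha_curves.tsv"))
    write_tsv_table(report$alpha$sharing, file.path(out_dir, "taxa_sharing.tsv"))
  }
  if (ok(report$beta)) {
    utils::write.table(unclass(report$beta$dist),
                       file.path(out_dir, "distances.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    write_tsv_table(report$beta$summary$summary,
                    file.path(out_dir, "beta_groups.tsv"))
  }
  if (ok(report$ordination)) {
    write_tsv_table(report$ordination$ordination$coordinates,
                    file.path(out_dir, "pcoa_coordinates.tsv"))
  }
  if (ok(report$permanova)) {
    write_tsv_table(report$permanova$table, file.path(out_dir, "permanova.tsv"))
  }
  if (ok(report$typing)) {
    write_tsv_table(tidy.community_typing(report$typing$typing),
                    file.path(out_dir, "cutaneotypes.tsv"))
    write_tsv_table(report$typing$typing$ch_curve,
                    file.path(out_dir, "ch_curve.tsv"))
  }
  if (ok(report$markers)) {
    write_tsv_table(report$markers$kruskal, file.path(out_dir, "kruskal_fdr.tsv"))
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("cutaneotyper")),
    seed = report$seed,
    n_samples = ncol(sim$counts) - 1,
    n_taxa = nrow(sim$counts),
    stages = names(report)[-1],
    failed = names(report)[vapply(report, inherits, TRUE,
                                  what = "pipeline_stage_error")])
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(out_dir)
}

#' Longitudinal trend report over visits
#'
#' For each week: triplet-relative Shannon diversity (lesion/unaffected
#' minus their triplet's control), intragroup beta-diversity means,
#' cutaneotype-2 prevalence per skin type (cluster 2 = the lesion-enriched
#' PAM cluster at k = 2 on genus sqrt-JSD profiles) with pairwise Fisher
#' exact tests, and combined skin-genera abundance (mean +/- SEM) per skin
#' type.
#'
#' @param sims Named list of per-week `cohort_simulation` objects (names =
#'   weeks), e.g. from [simulate_longitudinal()].
#' @return List of class `longitudinal_summary` with tibbles
#'   `relative_alpha`, `beta_intragroup`, `cutaneotype_prevalence`,
#'   `cutaneotype_tests`, `combined_genera`.
#' @export
longitudinal_summary <- function(sims) {
  ra <- bi <- cp <- ctst <- cg <- list()
  for (w in names(sims)) {
    sim <- sims[[w]]
    md <- sim$metadata
    genus <- collapse_taxonomy(sim$counts, sim$taxonomy, "genus")
    genus_rel <- to_relative(genus)
    m <- count_matrix(sim$counts)

    sh <- tibble::tibble(sample_id = colnames(m),
                         value = apply(m, 2, shannon_index))
    rel <- relative_alpha(sh, md)
    rel$week <- as.numeric(w)
    ra[[w]] <- rel

    d <- pairwise_distances(genus_rel, metric = "sqrt-jsd")
    bs <- beta_group_summary(d, md)
    s <- bs$summary[grepl("^within-", bs$summary$category), ]
    s$week <- as.numeric(w)
    bi[[w]] <- s

    ty <- pam_dm(d, 2)
    assoc <- cutaneotype_association(ty$labels, md)
    in2 <- ty$labels == assoc$enriched_cluster
    mdw <- md[match(names(ty$labels), md$sample_id), ]
    cp[[w]] <- dplyr::bind_rows(lapply(skin_type_levels(), function(ty_) {
      sel <- mdw$skin_type == ty_
      tibble::tibble(week = as.numeric(w), skin_type = ty_,
                     n = sum(sel), prevalence_type2 = mean(in2[sel]))
    }))
    prs <- utils::combn(skin_type_levels(), 2, simplify = FALSE)
    ctst[[w]] <- dplyr::bind_rows(lapply(prs, function(pr) {
      sel <- mdw$skin_type %in% pr
      tb <- table(in2[sel], droplevels(factor(mdw$skin_type[sel])))
      p <- if (all(dim(tb) == c(2, 2))) stats::fisher.test(tb)$p.value else NA_real_
      tibble::tibble(week = as.numeric(w),
                     comparison = paste(pr, collapse = " vs "), p_value = p)
    }))

    cm <- combined_genera_marker(genus_rel, md)
    sc <- cm$four_genus$scores
    cg[[w]] <- dplyr::summarise(
      dplyr::group_by(sc, .data$skin_type),
      mean = mean(.data$combined_abundance),
      sem = stats::sd(.data$combined_abundance) / sqrt(dplyr::n()),
      .groups = "drop")
    cg[[w]]$week <- as.numeric(w)
  }
  structure(list(relative_alpha = dplyr::bind_rows(ra),
                 beta_intragroup = dplyr::bind_rows(bi),
                 cutaneotype_prevalence = dplyr::bind_rows(cp),
                 cutaneotype_tests = dplyr::bind_rows(ctst),
                 combined_genera = dplyr::bind_rows(cg)),
            class = "longitudinal_summary")
}
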