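#' Odds ratio for a 2x2 incidence table
#'
#' Table layout: rows are the two groups, columns positive/negative, i.e.
#' `a` = group-1 positive, `b` = group-1 negative, `c` = group-2 positive,
#' `d` = group-2 negative. The default point estimate is the conditional
#' maximum likelihood estimate with exact 95% CI and two-sided exact p value
#' (via [stats::fisher.test()]); the sample cross-product estimate
#' `(a d)/(b c)` is co-reported. The conditional MLE shrinks toward 1
#' relative to the cross-product whenever all cells are positive.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return List of class `odds_ratio_result`: `estimate` (conditional MLE),
#'   `conf_low`, `conf_high`, `sample_or`, `p_value`, `counts`.
#' @examples
#' odds_ratio(30, 21, 15, 36)  # sample OR = (30*36)/(21*15)
#' @export
odds_ratio <- function(a, b, c, d) {
  m <- matrix(c(a, b, c, d), 2, 2, byrow = TRUE)
  if (any(m < 0)) stop("negative cell counts", call. = FALSE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    warning("zero margin: CI from the exact method only")
  }
  ft <- stats::fisher.test(m)
  structure(list(
    estimate = unname(ft$estimate),
    conf_low = ft$conf.int[1], conf_high = ft$conf.int[2],
    sample_or = (a * d) / (b * c),
    p_value = ft$p.value,
    counts = c(a = a, b = b, c = c, d = d)), class = "odds_ratio_result")
}

#' @export
print.odds_ratio_result <- function(x, ...) {
  cat(sprintf("OR (conditional MLE) %.3f (95%% CI %.3f to %.3f); sample OR %.3f; exact p = %.3g\n",
              x$estimate, x$conf_low, x$conf_high, x$sample_or, x$p_value))
  invisible(x)
}

#' @method tidy odds_ratio_result
#' @export
tidy.odds_ratio_result <- function(x, ...) {
  tibble::tibble(estimate = x$estimate, conf_low = x$conf_low,
                 conf_high = x$conf_high, sample_or = x$sample_or,
                 p_value = x$p_value)
}

#' Highly abundant taxa
#'
#' Taxa whose mean relative abundance across all samples is at least
#' `threshold` (inclusive; default 1%).
#'
#' @param profiles Relative-abundance tibble.
#' @param threshold Mean-abundance cut-off in (0, 1).
#' @return Character vector of taxon ids.
#' @export
abundant_taxa <- function(profiles, threshold = 0.01) {
  stopifnot(threshold > 0, threshold < 1)
  m <- count_matrix(profiles)
  out <- rownames(m)[rowMeans(m) >= threshold]
  if (!length(out)) warning("no taxon passes the abundance filter")
  out
}

#' Kruskal-Wallis differential abundance with BH correction
#'
#' Per-taxon Kruskal-Wallis test (tie-corrected, via
#' [stats::kruskal.test()]) of relative abundance across the three skin
#' types, with per-group medians and Benjamini-Hochberg q values across the
#' tested taxa (one BH family per call — collapse to one taxonomic level per
#' call). Constant taxa get `p = 1` and are flagged.
#'
#' @param profiles Relative-abundance tibble.
#' @param metadata Sample metadata with `sample_id` and `skin_type`.
#' @param taxa Taxa to test (default: all rows).
#' @return Tibble: `taxon_id`, `statistic`, `df`, per-group medians,
#'   `p_value`, `q_value`, `degenerate`.
#' @export
kruskal_wallis_fdr <- function(profiles, metadata, taxa = NULL) {
  m <- count_matrix(profiles)
  if (!is.null(taxa)) m <- m[intersect(taxa, rownames(m)), , drop = FALSE]
  md <- metadata[match(colnames(m), metadata$sample_id), ]
  g <- factor(md$skin_type, levels = skin_type_levels())
  if (any(table(g) < 2)) stop("each skin type needs n >= 2", call. = FALSE)
  rows <- lapply(rownames(m), function(tx) {
    v <- m[tx, ]
    if (stats::sd(v) == 0) {
      stat <- 0; df <- nlevels(g) - 1; p <- 1; deg <- TRUE
    } else {
      kw <- stats::kruskal.test(v, g)
      stat <- unname(kw$statistic); df <- unname(kw$parameter)
      p <- kw$p.value; deg <- FALSE
    }
    tibble::tibble(
      taxon_id = tx, statistic = stat, df = df,
      median_control = stats::median(v[g == "control"]),
      median_unaffected = stats::median(v[g == "unaffected"]),
      median_lesion = stats::median(v[g == "lesion"]),
      p_value = p, degenerate = deg)
  })
  out <- dplyr::bind_rows(rows)
  out$q_value <- stats::p.adjust(out$p_value, "BH")
  out[, c("taxon_id", "statistic", "df", "median_control", "median_unaffected",
          "median_lesion", "p_value", "q_value", "degenerate")]
}

#' Post hoc pairwise rank-sum tests for omnibus-significant taxa
#'
#' Wilcoxon rank-sum tests on each of the three skin-type pairs, BH-adjusted
#' within each taxon's three pairs.
#'
#' @param profiles Relative-abundance tibble.
#' @param metadata Sample metadata.
#' @param taxa Taxa to test (typically the omnibus-significant ones).
#' @param alternative Passed to [stats::wilcox.test()]; order of groups in a
#'   pair is (first, second) of the comparison label.
#' @return Tibble: `taxon_id`, `comparison`, `p_value`, `q_value`.
#' @export
posthoc_pairwise <- function(profiles, metadata, taxa,
                             alternative = "two.sided") {
  m <- count_matrix(profiles)
  missing <- setdiff(taxa, rownames(m))
  if (length(missing)) stop("taxa not in table: ", paste(missing, collapse = ", "),
                            call. = FALSE)
  md <- metadata[match(colnames(m), metadata$sample_id), ]
  g <- as.character(md$skin_type)
  pairs <- utils::combn(skin_type_levels(), 2, simplify = FALSE)
  rows <- list()
  for (tx in taxa) {
    v <- m[tx, ]
    ps <- vapply(pairs, function(pr) {
      suppressWarnings(stats::wilcox.test(v[g == pr[1]], v[g == pr[2]],
                                          alternative = alternative)$p.value)
    }, numeric(1))
    rows[[tx]] <- tibble::tibble(
      taxon_id = tx,
      comparison = vapply(pairs, paste, "", collapse = " vs "),
      p_value = ps, q_value = stats::p.adjust(ps, "BH"))
  }
  dplyr::bind_rows(rows)
}

match_genus_rows <- function(profiles, genera) {
  ids <- profiles$taxon_id
  short <- vapply(strsplit(ids, ";", fixed = TRUE), function(p) p[length(p)], "")
  idx <- lapply(genera, function(g) which(ids == g | short == g))
  names(idx) <- genera
  idx
}

#' Combined skin-genera abundance marker
#'
#' Sums the per-sample relative abundance of the four classical skin genera
#' (Corynebacterium, Propionibacterium, Staphylococcus, Streptococcus),
#' tests the sum across skin types (Kruskal-Wallis plus pairwise post hoc),
#' and reports the lesion-vs-control AUC. Both the 4-genus sum and the
#' 3-genus variant without Propionibacterium are computed. Genera absent
#' from the table contribute zero with a warning.
#'
#' @param profiles Genus-level relative-abundance tibble (ids may be bare
#'   genus names or `;`-joined lineages ending in the genus).
#' @param metadata Sample metadata.
#' @param genera The four genera to combine.
#' @return List of class `combined_genera_marker` with per-variant `scores`
#'   tibble, KW test, post hoc tibble and `roc` ([roc_auc()] result).
#' @export
combined_genera_marker <- function(profiles, metadata,
                                   genera = skin_genera()) {
  idx <- match_genus_rows(profiles, genera)
  absent <- names(idx)[lengths(idx) == 0]
  if (length(absent)) {
    warning("genus(era) absent, contributing 0: ", paste(absent, collapse = ", "))
  }
  m <- count_matrix(profiles)
  md <- metadata[match(colnames(m), metadata$sample_id), ]
  g <- factor(md$skin_type, levels = skin_type_levels())
  variant <- function(gset) {
    rows <- unlist(idx[gset])
    score <- if (length(rows)) colSums(m[rows, , drop = FALSE]) else
      stats::setNames(numeric(ncol(m)), colnames(m))
    kw <- stats::kruskal.test(score, g)
    scores <- tibble::tibble(sample_id = colnames(m), skin_type = g,
                             combined_abundance = unname(score))
    roc <- roc_auc(score[g == "lesion"], score[g == "control"])
    ph <- dplyr::bind_rows(lapply(utils::combn(levels(g), 2, simplify = FALSE),
      function(pr) tibble::tibble(
        comparison = paste(pr, collapse = " vs "),
        p_value = suppressWarnings(
          stats::wilcox.test(score[g == pr[1]], score[g == pr[2]])$p.value))))
    ph$q_value <- stats::p.adjust(ph$p_value, "BH")
    list(scores = scores,
         kruskal = list(statistic = unname(kw$statistic), df = unname(kw$parameter),
                        p_value = kw$p.value),
         posthoc = ph, roc = roc)
  }
  structure(list(
    four_genus = variant(genera),
    three_genus = variant(setdiff(genera, "Propionibacterium")),
    genera = genera), class = "combined_genera_marker")
}

#' @method glance combined_genera_marker
#' @export
glance.combined_genera_marker <- function(x, ...) {
  tibble::tibble(
    variant = c("four_genus", "three_genus"),
    kw_p = c(x$four_genus$kruskal$p_value, x$three_genus$kruskal$p_value),
    auc_lesion_vs_control = c(x$four_genus$roc$auc, x$three_genus$roc$auc))
}

#' Prevalence chi-square tests across skin types
#'
#' Per-taxon Pearson chi-square on the 2 x 3 presence/absence (count >= 1)
#' by skin-type table, BH-adjusted across taxa. Taxa present or absent
#' everywhere are degenerate (`p = 1`, flagged).
#'
#' @param x Count-table tibble.
#' @param metadata Sample metadata.
#' @param taxa Taxa to test (default all).
#' @return Tibble: `taxon_id`, per-group presence rates, `statistic`,
#'   `p_value`, `q_value`, `degenerate`.
#' @export
prevalence_chi2 <- function(x, metadata, taxa = NULL) {
  m <- count_matrix(validate_count_tbl(x)) >= 1
  if (!is.null(taxa)) m <- m[intersect(taxa, rownames(m)), , drop = FALSE]
  md <- metadata[match(colnames(m), metadata$sample_id), ]
  g <- factor(md$skin_type, levels = skin_type_levels())
  rows <- lapply(rownames(m), function(tx) {
    pres <- m[tx, ]
    deg <- all(pres) || !any(pres)
    if (deg) {
      stat <- 0; p <- 1
    } else {
      ct <- suppressWarnings(stats::chisq.test(table(pres, g)))
      stat <- unname(ct$statistic); p <- ct$p.value
    }
    tibble::tibble(
      taxon_id = tx,
      rate_control = mean(pres[g == "control"]),
      rate_unaffected = mean(pres[g == "unaffected"]),
      rate_lesion = mean(pres[g == "lesion"]),
      statistic = stat, p_value = p, degenerate = deg)
  })
  out <- dplyr::bind_rows(rows)
  out$q_value <- stats::p.adjust(out$p_value, "BH")
  out
}

#' Incidence-based double-positive predictor
#'
#' A sample is double-positive when both designated OTUs have at least one
#' read. Reports per-skin-type single- and double-positive percentages and
#' the double-positive odds ratios for each group pair (conditional MLE with
#' exact CI as the headline estimate, sample cross-product co-reported).
#'
#' @param x Count-table tibble containing both OTUs.
#' @param metadata Sample metadata.
#' @param otu_pair Character vector of the two OTU ids.
#' @return List of class `double_positive_predictor`: `rates` tibble
#'   (percentages), `odds_ratios` (named list of `odds_ratio_result`,
#'   comparisons `lesion_vs_control`, `unaffected_vs_control`,
#'   `lesion_vs_unaffected`).
#' @export
double_positive_predictor <- function(x, metadata, otu_pair) {
  stopifnot(length(otu_pair) == 2)
  m <- count_matrix(validate_count_tbl(x))
  missing <- setdiff(otu_pair, rownames(m))
  if (length(missing)) stop("OTU(s) not in table: ", paste(missing, collapse = ", "),
                            call. = FALSE)
  pres <- m[otu_pair, , drop = FALSE] >= 1
  dp <- pres[1, ] & pres[2, ]
  md <- metadata[match(colnames(m), metadata$sample_id), ]
  g <- factor(md$skin_type, levels = skin_type_levels())
  rates <- dplyr::bind_rows(lapply(levels(g), function(ty) {
    sel <- g == ty
    tibble::tibble(skin_type = ty, n = sum(sel),
                   pct_positive_1 = 100 * mean(pres[1, sel]),
                   pct_positive_2 = 100 * mean(pres[2, sel]),
                   pct_double_positive = 100 * mean(dp[sel]))
  }))
  names(rates)[3:4] <- paste0("pct_positive_", otu_pair)
  pair_or <- function(g1, g2) {
    odds_ratio(sum(dp[g == g1]), sum(!dp[g == g1]),
               sum(dp[g == g2]), sum(!dp[g == g2]))
  }
  structure(list(
    rates = rates,
    odds_ratios = list(
      lesion_vs_control = pair_or("lesion", "control"),
      unaffected_vs_control = pair_or("unaffected", "control"),
      lesion_vs_unaffected = pair_or("lesion", "unaffected")),
    otu_pair = otu_pair), class = "double_positive_predictor")
}

#' @method glance double_positive_predictor
#' @export
glance.double_positive_predictor <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(comparison = names(x$odds_ratios)),
    dplyr::bind_rows(lapply(x$odds_ratios, tidy.odds_ratio_result)))
}

#' ROC AUC by rank statistics
#'
#' `AUC = (concordant pairs + 0.5 * ties) / (n1 * n2)`, identically
#' `U / (n1 * n2)` for the Mann-Whitney U of cases over controls; the p
#' value is the two-sided Mann-Whitney test.
#'
#' @param cases Scores of the positive class.
#' @param controls Scores of the negative class.
#' @return List of class `roc_result`: `auc`, `U`, `p_value`, `n_cases`,
#'   `n_controls`.
#' @export
roc_auc <- function(cases, controls) {
  if (!length(cases) || !length(controls)) stop("one class is empty", call. = FALSE)
  wt <- suppressWarnings(stats::wilcox.test(cases, controls))
  u <- unname(wt$statistic)
  structure(list(auc = u / (length(cases) * length(controls)), U = u,
                 p_value = wt$p.value,
                 n_cases = length(cases), n_controls = length(controls)),
            class = "roc_result")
}

#' Spearman correlation of taxon abundance with severity scores
#'
#' Lesion samples only; tie-corrected Spearman rho of each taxon against
#' each recorded severity score, BH-adjusted within each score across taxa.
#' Constant scores or abundances are flagged undefined.
#'
#' @param profiles Relative-abundance tibble.
#' @param metadata Sample metadata with severity columns.
#' @param taxa Taxa to test (default all).
#' @param scores Severity columns to use.
#' @return Tibble: `taxon_id`, `score`, `rho`, `p_value`, `q_value`,
#'   `undefined`.
#' @export
severity_correlation <- function(profiles, metadata, taxa = NULL,
                                 scores = c("PASI", "BSA", "PGA")) {
  m <- count_matrix(profiles)
  if (!is.null(taxa)) m <- m[intersect(taxa, rownames(m)), , drop = FALSE]
  md <- metadata[match(colnames(m), metadata$sample_id), ]
  lesion <- which(md$skin_type == "lesion")
  rows <- list()
  for (sc in scores) {
    v <- md[[sc]][lesion]
    ok <- !is.na(v)
    for (tx in rownames(m)) {
      a <- m[tx, lesion][ok]
      und <- stats::sd(v[ok]) == 0 || stats::sd(a) == 0 || sum(ok) < 3
      if (und) {
        rho <- NA_real_; p <- NA_real_
      } else {
        ct <- suppressWarnings(stats::cor.test(a, v[ok], method = "spearman"))
        rho <- unname(ct$estimate); p <- ct$p.value
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        taxon_id = tx, score = sc, rho = rho, p_value = p, undefined = und)
    }
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::group_by(out, .data$score)
  out <- dplyr::mutate(out, q_value = stats::p.adjust(.data$p_value, "BH"))
  dplyr::ungroup(out)
}

#' Chimera QC summary
#'
#' Summarises OTUs flagged as potentially chimeric by an upstream checker:
#' the flagged fraction of all OTUs, per-sample relative abundance of
#' flagged OTUs, and Kruskal-Wallis comparisons of that abundance across
#' skin types (and body sites / microenvironments when available). Flagged
#' OTUs are reported, not removed.
#'
#' @param x Count-table tibble.
#' @param chimera_flags Named logical vector over the table's taxa.
#' @param metadata Optional sample metadata for the group comparisons.
#' @return List of class `chimera_qc`: `n_flagged`, `n_total`,
#'   `pct_flagged` (one decimal), `per_sample` tibble, `tests` tibble.
#' @export
chimera_qc_summary <- function(x, chimera_flags, metadata = NULL) {
  m <- count_matrix(validate_count_tbl(x))
  if (is.null(names(chimera_flags))) {
    if (length(chimera_flags) != nrow(m)) stop("flag length mismatch", call. = FALSE)
    names(chimera_flags) <- rownames(m)
  }
  missing <- setdiff(rownames(m), names(chimera_flags))
  if (length(missing)) stop("flags missing for ", length(missing), " taxa", call. = FALSE)
  fl <- chimera_flags[rownames(m)]
  pct <- round(100 * sum(fl) / length(fl), 1)
  ab <- colSums(m[fl, , drop = FALSE]) / colSums(m)
  per_sample <- tibble::tibble(sample_id = colnames(m),
                               flagged_abundance = unname(ab))
  tests <- NULL
  if (!is.null(metadata)) {
    md <- metadata[match(colnames(m), metadata$sample_id), ]
    tests <- dplyr::bind_rows(lapply(
      intersect(c("skin_type", "body_site", "microenvironment"), names(md)),
      function(f) {
        g <- factor(md[[f]])
        if (nlevels(g) < 2) return(NULL)
        kw <- stats::kruskal.test(ab, g)
        tibble::tibble(factor = f, statistic = unname(kw$statistic),
                       p_value = kw$p.value)
      }))
  }
  structure(list(n_flagged = sum(fl), n_total = length(fl), pct_flagged = pct,
                 per_sample = per_sample, tests = tests), class = "chimera_qc")
}
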