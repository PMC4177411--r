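#' Sample-by-sample distance matrices
#'
#' `beta_dist` objects are square symmetric matrices with a `metric`
#' attribute. [tidy()][generics::tidy] converts one to a long tibble of
#' unordered sample pairs.
#'
#' @param m Square numeric matrix with matching dimnames.
#' @param metric Metric tag (`"unweighted-unifrac"`, `"weighted-unifrac"`,
#'   `"sqrt-jsd"`, `"euclidean"`, `"other"`).
#' @return A `beta_dist` matrix.
#' @export
new_beta_dist <- function(m, metric = "other") {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (any(!is.finite(m))) stop("non-finite distances", call. = FALSE)
  if (max(abs(m - t(m))) > 1e-8) stop("distance matrix not symmetric", call. = FALSE)
  if (max(abs(diag(m))) > 1e-8) stop("nonzero diagonal", call. = FALSE)
  if (min(m) < -1e-12) stop("negative distances", call. = FALSE)
  upper <- switch(metric,
                  "unweighted-unifrac" = 1, "weighted-unifrac" = 1,
                  "sqrt-jsd" = sqrt(log(2)), Inf)
  if (max(m) > upper + 1e-8) {
    stop("distances exceed the range of metric '", metric, "'", call. = FALSE)
  }
  m <- (m + t(m)) / 2
  diag(m) <- 0
  structure(m, metric = metric, class = c("beta_dist", "matrix", "array"))
}

#' @method tidy beta_dist
#' @export
tidy.beta_dist <- function(x, ...) {
  ids <- rownames(x)
  idx <- which(upper.tri(x), arr.ind = TRUE)
  tibble::tibble(sample_a = ids[idx[, 1]], sample_b = ids[idx[, 2]],
                 distance = x[idx])
}

#' @export
print.beta_dist <- function(x, ...) {
  cat("<beta_dist> ", nrow(x), " samples, metric = ", attr(x, "metric"), "\n", sep = "")
  print(unclass(x)[seq_len(min(5, nrow(x))), seq_len(min(5, ncol(x)))])
  invisible(x)
}

# Per-edge read masses: matrix (n_edge x n_samples) of reads under each
# branch, by postorder accumulation. `counts` rows must be tree tips.
edge_masses <- function(tree, counts) {
  n_tip <- length(tree$tip.label)
  extra <- setdiff(rownames(counts)[rowSums(counts) > 0], tree$tip.label)
  if (length(extra)) {
    stop("OTUs absent from the tree: ", paste(utils::head(extra, 5), collapse = ", "),
         call. = FALSE)
  }
  tr <- stats::reorder(tree, "postorder")
  node_mass <- matrix(0, n_tip + tr$Nnode, ncol(counts))
  hit <- intersect(rownames(counts), tr$tip.label)
  node_mass[match(hit, tr$tip.label), ] <- counts[hit, , drop = FALSE]
  for (e in seq_len(nrow(tr$edge))) {
    node_mass[tr$edge[e, 1], ] <- node_mass[tr$edge[e, 1], ] + node_mass[tr$edge[e, 2], ]
  }
  list(mass = node_mass[tr$edge[, 2], , drop = FALSE],
       length = tr$edge.length, tree = tr)
}

as_presence_ids <- function(x) {
  if (is.character(x)) return(unique(x))
  if (is.null(names(x))) stop("presence vector must be named or character", call. = FALSE)
  names(x)[x > 0]
}

#' Unweighted UniFrac distance between two samples
#'
#' Fraction of observed branch length leading exclusively to tips of one
#' sample: `sum(b_e unique) / sum(b_e in either)`, with branches subtending
#' no observed tip excluded.
#'
#' @param tree Rooted `phylo` tree with branch lengths.
#' @param a,b Character vectors of present OTU ids (or named count vectors,
#'   presence = count > 0).
#' @return Distance in \[0, 1\].
#' @export
unweighted_unifrac <- function(tree, a, b) {
  a <- as_presence_ids(a); b <- as_presence_ids(b)
  if (!length(a) || !length(b)) stop("empty sample", call. = FALSE)
  ids <- union(a, b)
  counts <- cbind(A = as.numeric(ids %in% a), B = as.numeric(ids %in% b))
  rownames(counts) <- ids
  em <- edge_masses(check_tree(tree), counts)
  inA <- em$mass[, 1] > 0; inB <- em$mass[, 2] > 0
  sum(em$length[xor(inA, inB)]) / sum(em$length[inA | inB])
}

#' Weighted UniFrac distance between two samples
#'
#' Raw form `sum_e b_e * |A_e/A_T - B_e/B_T|`; the normalised form divides by
#' `sum_tips depth(root, tip) * (A_tip/A_T + B_tip/B_T)` so values lie in
#' \[0, 1\].
#'
#' @param tree Rooted `phylo` tree with branch lengths.
#' @param a,b Named non-negative count vectors (names = OTU ids).
#' @param normalized Divide by the abundance-weighted tip-depth scaling.
#' @return Distance (in \[0, 1\] when normalised).
#' @export
weighted_unifrac <- function(tree, a, b, normalized = TRUE) {
  if (sum(a) <= 0 || sum(b) <= 0) stop("empty sample", call. = FALSE)
  ids <- union(names(a)[a > 0], names(b)[b > 0])
  counts <- cbind(A = as.numeric(a[ids]), B = as.numeric(b[ids]))
  counts[is.na(counts)] <- 0
  rownames(counts) <- ids
  tree <- check_tree(tree)
  em <- edge_masses(tree, counts)
  pa <- em$mass[, 1] / sum(a); pb <- em$mass[, 2] / sum(b)
  raw <- sum(em$length * abs(pa - pb))
  if (!normalized) return(raw)
  depth <- ape::node.depth.edgelength(em$tree)[seq_along(em$tree$tip.label)]
  names(depth) <- em$tree$tip.label
  tip_pa <- tip_pb <- stats::setNames(numeric(length(depth)), names(depth))
  tip_pa[ids] <- counts[, 1] / sum(a)
  tip_pb[ids] <- counts[, 2] / sum(b)
  raw / sum(depth * (tip_pa + tip_pb))
}

xlogx <- function(p) ifelse(p > 0, p * log(p), 0)

#' Square-root Jensen-Shannon distance between two probability vectors
#'
#' `sqrt(0.5 KL(p||m) + 0.5 KL(q||m))` with `m = (p+q)/2`, natural log and
#' the `0 log 0 = 0` convention; a true metric bounded by `sqrt(log 2)`.
#'
#' @param p,q Probability vectors on the same support (each sums to 1).
#' @return Distance in \[0, sqrt(log 2)\].
#' @export
jsd_distance <- function(p, q) {
  if (any(p < 0) || any(q < 0)) stop("negative entries", call. = FALSE)
  stopifnot(length(p) == length(q),
            abs(sum(p) - 1) < 1e-6, abs(sum(q) - 1) < 1e-6)
  m <- (p + q) / 2
  jsd <- -sum(xlogx(m)) + (sum(xlogx(p)) + sum(xlogx(q))) / 2
  sqrt(max(jsd, 0))
}

#' All pairwise distances for a count table
#'
#' Computes a [new_beta_dist()] matrix for every unordered sample pair under
#' the chosen metric. UniFrac metrics require `tree`; `sqrt-jsd` and
#' `euclidean` operate on per-sample relative abundances derived from the
#' counts.
#'
#' @param x Count-table tibble.
#' @param metric One of `"unweighted-unifrac"`, `"weighted-unifrac"`,
#'   `"sqrt-jsd"`, `"euclidean"`.
#' @param tree `phylo` tree (UniFrac metrics only).
#' @param normalized Normalise weighted UniFrac (default TRUE).
#' @return A `beta_dist` matrix.
#' @export
pairwise_distances <- function(x, metric = c("unweighted-unifrac",
                                             "weighted-unifrac",
                                             "sqrt-jsd", "euclidean"),
                               tree = NULL, normalized = TRUE) {
  metric <- match.arg(metric)
  m <- count_matrix(validate_abundance_tbl(x))
  n <- ncol(m)
  ids <- colnames(m)
  depths <- colSums(m)
  if (any(depths <= 0)) {
    stop("empty sample(s): ", paste(ids[depths <= 0], collapse = ", "), call. = FALSE)
  }
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  if (metric %in% c("unweighted-unifrac", "weighted-unifrac")) {
    if (is.null(tree)) stop("UniFrac metrics require a tree", call. = FALSE)
    em <- edge_masses(check_tree(tree), m)
    len <- em$length
    if (metric == "unweighted-unifrac") {
      P <- em$mass > 0
      for (j in seq_len(n)) {
        both <- P & P[, j]           # recycled columnwise
        either <- P | P[, j]
        D[, j] <- colSums(len * (either & !both)) / colSums(len * either)
      }
    } else {
      A <- sweep(em$mass, 2, depths, "/")
      depth_tip <- ape::node.depth.edgelength(em$tree)[seq_along(em$tree$tip.label)]
      tip_rows <- match(em$tree$tip.label, rownames(m))
      Tp <- sweep(m[tip_rows, , drop = FALSE], 2, depths, "/")
      tipsum <- colSums(depth_tip * Tp)
      for (j in seq_len(n)) {
        raw <- colSums(len * abs(A - A[, j]))
        D[, j] <- if (normalized) raw / (tipsum + tipsum[j]) else raw
      }
      diag(D) <- 0
    }
  } else if (metric == "sqrt-jsd") {
    P <- sweep(m, 2, depths, "/")
    H <- apply(P, 2, function(p) -sum(xlogx(p)))
    for (j in seq_len(n)) {
      M <- (P + P[, j]) / 2
      Hm <- apply(M, 2, function(p) -sum(xlogx(p)))
      D[, j] <- sqrt(pmax(Hm - (H + H[j]) / 2, 0))
    }
  } else {
    P <- sweep(m, 2, depths, "/")
    D <- as.matrix(stats::dist(t(P)))
  }
  new_beta_dist(D, metric)
}

#' Intragroup/intergroup beta-diversity decomposition
#'
#' Bins all pairwise distances into the six categories of the three-group
#' design (within each skin type; between each pair of skin types), reports
#' mean +/- SEM per category, and tests for category differences with
#' one-way ANOVA plus Tukey HSD. Note: pairwise distances sharing a sample
#' are not independent; the ANOVA ignores this, which inflates nominal
#' significance — interpret p values as descriptive.
#'
#' @param dist A `beta_dist` matrix.
#' @param metadata Sample metadata with `sample_id` and `skin_type`.
#' @return List of class `beta_group_summary`: `summary` tibble, `anova`
#'   (F, df, p), `tukey` tibble of pairwise adjusted p values, `pairs` (the
#'   underlying long tibble).
#' @export
beta_group_summary <- function(dist, metadata) {
  pairs <- tidy.beta_dist(dist)
  md <- stats::setNames(as.character(metadata$skin_type), metadata$sample_id)
  ga <- md[pairs$sample_a]; gb <- md[pairs$sample_b]
  if (anyNA(ga) || anyNA(gb)) stop("samples missing from metadata", call. = FALSE)
  pairs$category <- ifelse(
    ga == gb, paste0("within-", ga),
    paste(pmin(ga, gb), pmax(ga, gb), sep = "–"))
  tab <- table(pairs$category)
  small <- names(tab)[tab < 2]
  if (length(small)) {
    warning("category(ies) with < 2 pairs dropped: ", paste(small, collapse = ", "))
    pairs <- pairs[!pairs$category %in% small, ]
  }
  pairs$category <- factor(pairs$category)
  if (nlevels(pairs$category) < 2) {
    stop("fewer than two pair categories with >= 2 pairs; cannot compare",
         call. = FALSE)
  }
  fit <- stats::aov(distance ~ category, data = pairs)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$category
  summary <- dplyr::summarise(
    dplyr::group_by(pairs, .data$category),
    n_pairs = dplyr::n(), mean = mean(.data$distance),
    sem = stats::sd(.data$distance) / sqrt(dplyr::n()), .groups = "drop")
  structure(list(
    summary = summary,
    anova = list(F = an$`F value`[1], df = an$Df[1:2], p_value = an$`Pr(>F)`[1]),
    tukey = tibble::as_tibble(as.data.frame(tk), rownames = "comparison"),
    pairs = tibble::as_tibble(pairs)), class = "beta_group_summary")
}

#' @method tidy beta_group_summary
#' @export
tidy.beta_group_summary <- function(x, ...) x$summary

#' @method glance beta_group_summary
#' @export
glance.beta_group_summary <- function(x, ...) {
  tibble::tibble(statistic = x$anova$F, df = x$anova$df[1],
                 df_residual = x$anova$df[2], p_value = x$anova$p_value)
}

#' @method autoplot beta_group_summary
#' @export
autoplot.beta_group_summary <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$category, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           width = 0.25) +
    ggplot2::labs(x = NULL, y = "mean pairwise distance ± SEM") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
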