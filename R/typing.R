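#' Partitioning around medoids on a precomputed distance matrix
#'
#' Small instances (at most `exact_limit` candidate medoid sets) are solved
#' exactly by enumeration; larger ones use the classic BUILD initialisation
#' followed by SWAP descent to a local optimum of the total
#' distance-to-medoid objective. Fully deterministic: all ties break toward
#' the lowest sample index, so reruns and sample-order permutations give the
#' same partition up to relabelling.
#'
#' @param dist A `beta_dist` (or square symmetric) matrix.
#' @param k Number of clusters, `1 <= k < n`.
#' @param exact_limit Enumerate all medoid sets exactly when `choose(n, k)`
#'   is at most this.
#' @return List: `labels` (named integer vector, 1..k by medoid order),
#'   `medoids` (sample ids), `objective` (total distance to medoids).
#' @export
pam_dm <- function(dist, k, exact_limit = 2000) {
  D <- unclass(dist)
  n <- nrow(D)
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k < n", call. = FALSE)
  ids <- rownames(D) %||% as.character(seq_len(n))

  if (choose(n, k) <= exact_limit) {
    best <- Inf
    med <- NULL
    for (cand in utils::combn(n, k, simplify = FALSE)) {
      obj <- sum(apply(D[, cand, drop = FALSE], 1, min))
      if (obj < best - 1e-12) {  # strict: ties keep the earlier (lower) set
        best <- obj
        med <- cand
      }
    }
    Dm <- D[, med, drop = FALSE]
    n1 <- apply(Dm, 1, which.min)
    return(list(labels = stats::setNames(as.integer(n1), ids),
                medoids = ids[med], objective = best))
  }

  # BUILD: greedy medoid addition maximising the decrease in total distance
  med <- which.min(colSums(D))
  dmin <- D[, med]
  while (length(med) < k) {
    gain <- colSums(pmax(dmin - D, 0))
    gain[med] <- -Inf
    best <- which.max(gain)
    med <- c(med, best)
    dmin <- pmin(dmin, D[, best])
  }
  med <- sort(med)

  if (k >= 2) {
    repeat {
      Dm <- D[, med, drop = FALSE]
      n1 <- apply(Dm, 1, which.min)       # index into med; ties -> lowest
      d1 <- Dm[cbind(seq_len(n), n1)]
      d2 <- apply(Dm, 1, function(r) sort(r, partial = 2)[2])
      best_delta <- -1e-12
      best_swap <- NULL
      nonmed <- setdiff(seq_len(n), med)
      for (im in seq_len(k)) {
        loses <- n1 == im
        for (h in nonmed) {
          dh <- D[, h]
          delta <- sum(pmin(dh[loses], d2[loses]) - d1[loses]) +
            sum(pmin(dh[!loses] - d1[!loses], 0))
          if (delta < best_delta) {
            best_delta <- delta
            best_swap <- c(im, h)
          }
        }
      }
      if (is.null(best_swap)) break
      med[best_swap[1]] <- best_swap[2]
      med <- sort(med)
    }
  }
  Dm <- D[, med, drop = FALSE]
  n1 <- apply(Dm, 1, which.min)
  labels <- stats::setNames(as.integer(n1), ids)
  list(labels = labels, medoids = ids[med],
       objective = sum(Dm[cbind(seq_len(n), n1)]))
}

#' Distance-based Calinski-Harabasz index
#'
#' `CH = (B_k / (k - 1)) / (W_k / (n - k))` with the within dispersion
#' computed directly from the distance matrix,
#' `W_k = sum_clusters sum_(i<j in cluster) d(i,j)^2 / n_cluster` and
#' `B_k = T - W_k`, `T = sum_(i<j) d(i,j)^2 / n`. For Euclidean distances
#' this equals the classical centroid-based index; for arbitrary metrics it
#' avoids projecting onto ordination axes.
#'
#' @param dist A `beta_dist` (or square symmetric) matrix.
#' @param labels Cluster labels aligned with the matrix rows.
#' @return The index (larger = better-separated clustering).
#' @export
calinski_harabasz <- function(dist, labels) {
  D2 <- unclass(dist)^2
  n <- nrow(D2)
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2) stop("Calinski-Harabasz requires k >= 2", call. = FALSE)
  if (length(unique(labels)) != k) stop("empty cluster", call. = FALSE)
  total <- sum(D2[upper.tri(D2)]) / n
  W <- 0
  for (c in seq_len(k)) {
    idx <- which(labels == c)
    if (length(idx) > 1) {
      sub <- D2[idx, idx]
      W <- W + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  B <- total - W
  (B / (k - 1)) / (W / (n - k))
}

# within-cluster dispersion used by the gap statistic (same form as CH's W)
within_dispersion <- function(D, labels) {
  D2 <- unclass(D)^2
  W <- 0
  for (c in unique(labels)) {
    idx <- which(labels == c)
    if (length(idx) > 1) {
      sub <- D2[idx, idx]
      W <- W + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  W
}

#' Select the number of community types by the Calinski-Harabasz curve
#'
#' Runs [pam_dm()] at each `k` and records the distance-based CH index; the
#' chosen `k` is the argmax (ties toward smaller `k`). A flat or low curve is
#' flagged as weak structure rather than silently typed.
#'
#' @param dist A `beta_dist` matrix.
#' @param k_range Candidate cluster numbers (default 2:20, capped below n).
#' @param weak_threshold CH value below which the best clustering is flagged
#'   `weak_structure`.
#' @return List of class `community_typing`: `k`, `labels`, `medoids`,
#'   `ch_curve` tibble, `weak_structure`.
#' @export
choose_k <- function(dist, k_range = 2:20, weak_threshold = 0) {
  n <- nrow(dist)
  k_range <- k_range[k_range >= 2 & k_range < n]
  if (!length(k_range)) stop("no admissible k in range", call. = FALSE)
  fits <- lapply(k_range, function(k) pam_dm(dist, k))
  ch <- vapply(seq_along(k_range), function(i)
    calinski_harabasz(dist, fits[[i]]$labels), numeric(1))
  best <- which.max(ch)  # ties -> first, i.e. smaller k
  structure(list(
    k = k_range[best],
    labels = fits[[best]]$labels,
    medoids = fits[[best]]$medoids,
    ch_curve = tibble::tibble(k = k_range, calinski_harabasz = ch),
    weak_structure = ch[best] < weak_threshold), class = "community_typing")
}

#' @method tidy community_typing
#' @export
tidy.community_typing <- function(x, ...) {
  tibble::tibble(sample_id = names(x$labels), cutaneotype = unname(x$labels))
}

#' @method glance community_typing
#' @export
glance.community_typing <- function(x, ...) {
  tibble::tibble(k = x$k, max_ch = max(x$ch_curve$calinski_harabasz),
                 weak_structure = x$weak_structure)
}

#' @method autoplot community_typing
#' @export
autoplot.community_typing <- function(object, ...) {
  ggplot2::ggplot(object$ch_curve,
                  ggplot2::aes(x = .data$k, y = .data$calinski_harabasz)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "number of clusters", y = "Calinski-Harabasz index")
}

#' Gap statistic for the number of clusters
#'
#' `Gap(k) = E*[log W_k] - log W_k`, with reference data sets drawn
#' uniformly over the bounding box of the profiles' sqrt-JSD PCoA
#' coordinates (Tibshirani's simple reference) and clustered the same way
#' (PAM, Euclidean distance in the box). The selected `k` is the smallest
#' with `Gap(k) >= Gap(k+1) - s_(k+1)`; `k = 1` is admissible and signals no
#' cluster structure.
#'
#' @param profiles Relative-abundance tibble (`taxon_id` + sample columns).
#' @param k_range Candidate `k` values (k = 1 is always prepended).
#' @param B_ref Number of reference data sets (>= 10).
#' @param seed Integer seed.
#' @return List of class `gap_curve`: `curve` tibble (k, gap, s, log_W),
#'   `k`.
#' @export
gap_statistic <- function(profiles, k_range = 2:10, B_ref = 50, seed = 1) {
  stopifnot(B_ref >= 10)
  D <- pairwise_distances(profiles, metric = "sqrt-jsd")
  ord <- pcoa_dm(D)
  coords <- as.matrix(ord$coordinates[, -1, drop = FALSE])
  lo <- apply(coords, 2, min); hi <- apply(coords, 2, max)
  if (any(hi - lo <= 0)) stop("degenerate reference bounding box", call. = FALSE)
  n <- nrow(coords)
  ks <- sort(unique(c(1L, k_range)))
  ks <- ks[ks < n]
  cluster_W <- function(M, k) {
    Dm <- new_beta_dist(as.matrix(stats::dist(M)), "euclidean")
    if (k == 1) return(within_dispersion(Dm, rep(1L, nrow(M))))
    within_dispersion(Dm, pam_dm(Dm, k)$labels)
  }
  log_W <- vapply(ks, function(k) {
    if (k == 1) log(within_dispersion(D, rep(1L, n)))
    else log(within_dispersion(D, pam_dm(D, k)$labels))
  }, numeric(1))
  ref <- with_seed(seed, {
    sapply(seq_len(B_ref), function(b) {
      M <- sapply(seq_along(lo), function(j) stats::runif(n, lo[j], hi[j]))
      vapply(ks, function(k) log(cluster_W(M, k)), numeric(1))
    })
  })
  gap <- rowMeans(ref) - log_W
  s <- apply(ref, 1, stats::sd) * sqrt(1 + 1 / B_ref)
  sel <- NA_integer_
  for (i in seq_len(length(ks) - 1)) {
    if (gap[i] >= gap[i + 1] - s[i + 1]) { sel <- ks[i]; break }
  }
  if (is.na(sel)) sel <- ks[length(ks)]
  structure(list(curve = tibble::tibble(k = ks, gap = gap, s = s, log_W = log_W),
                 k = sel, B_ref = B_ref, seed = seed), class = "gap_curve")
}

#' Association of community types with clinical skin type
#'
#' Cross-tabulates cluster labels against skin type, tests the association
#' (Pearson chi-square; Fisher's exact test when any expected cell count
#' falls below 1), and reports the lesion-vs-control odds ratio of membership
#' in the lesion-enriched cluster. The odds-ratio point estimate is the
#' conditional MLE with exact 95% CI (via [stats::fisher.test()]); the sample
#' cross-product estimate is co-reported.
#'
#' @param labels Named cluster labels (names = sample ids) or a
#'   `community_typing` object.
#' @param metadata Sample metadata with `sample_id` and `skin_type`.
#' @return List of class `cutaneotype_assoc`: `contingency`, `test`
#'   (`method`, `statistic`, `p_value`), `enriched_cluster`, `odds_ratio`
#'   (an `odds_ratio_result`).
#' @export
cutaneotype_association <- function(labels, metadata) {
  if (inherits(labels, "community_typing")) labels <- labels$labels
  md <- metadata[match(names(labels), metadata$sample_id), ]
  tab <- table(cutaneotype = labels, skin_type = md$skin_type)
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    stop("need >= 2 clusters and >= 2 skin types", call. = FALSE)
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 1)) {
    message("expected cell count < 1; using Fisher's exact test")
    ft <- stats::fisher.test(tab)
    test <- list(method = "fisher", statistic = NA_real_, p_value = ft$p.value)
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab))
    test <- list(method = "chi-squared", statistic = unname(ct$statistic),
                 p_value = ct$p.value)
  }
  # lesion-enriched cluster: highest lesion share relative to cluster size
  lesion_share <- tab[, "lesion"] / rowSums(tab)
  enriched <- rownames(tab)[which.max(lesion_share)]
  in_c <- labels == as.integer(enriched)
  lesion <- md$skin_type == "lesion"
  control <- md$skin_type == "control"
  or <- odds_ratio(a = sum(in_c & lesion), b = sum(!in_c & lesion),
                   c = sum(in_c & control), d = sum(!in_c & control))
  structure(list(contingency = tab, test = test,
                 enriched_cluster = as.integer(enriched), odds_ratio = or),
            class = "cutaneotype_assoc")
}

#' @method glance cutaneotype_assoc
#' @export
glance.cutaneotype_assoc <- function(x, ...) {
  tibble::tibble(method = x$test$method, statistic = x$test$statistic,
                 p_value = x$test$p_value,
                 enriched_cluster = x$enriched_cluster,
                 odds_ratio = x$odds_ratio$estimate,
                 or_low = x$odds_ratio$conf_low,
                 or_high = x$odds_ratio$conf_high)
}
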