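# Shared fixtures and independent oracles used across the suite.
# Oracles are written from first principles (direct enumeration / classical
# formulas) so they stay independent of the package's implementation path.

small_sim <- function(n_triplets = 6, n_otus = 40, n_genera = 10,
                      cohort_seed = 42, tree_seed = 7, ...) {
  simulate_cohort(simulation_config(
    n_triplets = n_triplets, n_otus = n_otus, n_genera = n_genera,
    cohort_seed = cohort_seed, tree_seed = tree_seed, ...))
}

random_count_tbl <- function(n_taxa = 12, n_samples = 6, seed = 1, lambda = 30) {
  set.seed(seed)
  m <- matrix(rpois(n_taxa * n_samples, lambda), n_taxa, n_samples,
              dimnames = list(sprintf("t%02d", seq_len(n_taxa)),
                              sprintf("s%02d", seq_len(n_samples))))
  as_count_tbl(m)
}

random_bl_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, tip.label = sprintf("T%02d", seq_len(n)))
  tr$edge.length <- runif(nrow(tr$edge), 0.1, 2)
  tr
}

# tips descending from each edge's child node, by direct recursion
edge_tip_sets <- function(tree) {
  n_tip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  desc <- function(node) {
    if (node <= n_tip) return(tree$tip.label[node])
    unlist(lapply(kids[[as.character(node)]], desc))
  }
  lapply(tree$edge[, 2], desc)
}

oracle_unweighted_unifrac <- function(tree, a, b) {
  sets <- edge_tip_sets(tree)
  len <- tree$edge.length
  in_a <- vapply(sets, function(s) any(s %in% a), logical(1))
  in_b <- vapply(sets, function(s) any(s %in% b), logical(1))
  sum(len[xor(in_a, in_b)]) / sum(len[in_a | in_b])
}

oracle_weighted_unifrac <- function(tree, a, b, normalized = TRUE) {
  sets <- edge_tip_sets(tree)
  len <- tree$edge.length
  pa <- vapply(sets, function(s) sum(a[intersect(s, names(a))]) / sum(a), numeric(1))
  pb <- vapply(sets, function(s) sum(b[intersect(s, names(b))]) / sum(b), numeric(1))
  raw <- sum(len * abs(pa - pb))
  if (!normalized) return(raw)
  tips <- tree$tip.label
  depth <- vapply(tips, function(t)
    sum(len[vapply(sets, function(s) t %in% s, logical(1))]), numeric(1))
  pat <- ifelse(is.na(a[tips]), 0, a[tips]) / sum(a)
  pbt <- ifelse(is.na(b[tips]), 0, b[tips]) / sum(b)
  raw / sum(depth * (pat + pbt))
}

gower_center_oracle <- function(D2) {
  n <- nrow(D2)
  J <- diag(n) - 1 / n
  -0.5 * J %*% D2 %*% J
}

min_gower_eigen <- function(D, cc) {
  Dc <- D + cc
  diag(Dc) <- 0
  ev <- eigen(gower_center_oracle(Dc^2), symmetric = TRUE, only.values = TRUE)$values
  min(ev) / max(abs(ev))
}

oracle_cailliez_bisect <- function(D, tol = 1e-7) {
  lo <- 0
  hi <- 4 * max(D)
  while (min_gower_eigen(D, hi) < -1e-9) hi <- hi * 2
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (min_gower_eigen(D, mid) >= -1e-9) hi <- mid else lo <- mid
  }
  hi
}

# classical centroid-based Calinski-Harabasz from coordinates
oracle_ch_classic <- function(X, labels) {
  X <- as.matrix(X)
  n <- nrow(X)
  lv <- unique(labels)
  k <- length(lv)
  gm <- colMeans(X)
  B <- W <- 0
  for (c in lv) {
    Xi <- X[labels == c, , drop = FALSE]
    ci <- colMeans(Xi)
    B <- B + nrow(Xi) * sum((ci - gm)^2)
    W <- W + sum(sweep(Xi, 2, ci)^2)
  }
  (B / (k - 1)) / (W / (n - k))
}

oracle_pam_exhaustive <- function(D, k) {
  n <- nrow(D)
  best <- Inf
  for (med in utils::combn(n, k, simplify = FALSE)) {
    obj <- sum(apply(D[, med, drop = FALSE], 1, min))
    if (obj < best) best <- obj
  }
  best
}

oracle_bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

oracle_auc <- function(cases, controls) {
  conc <- 0
  for (x in cases) for (y in controls) {
    conc <- conc + (x > y) + 0.5 * (x == y)
  }
  conc / (length(cases) * length(controls))
}

same_partition <- function(a, b) {
  tab <- table(a, b)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}
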