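gower_center <- function(D2) {
  n <- nrow(D2)
  J <- diag(n) - matrix(1 / n, n, n)
  -0.5 * J %*% D2 %*% J
}

#' Cailliez correction of a non-Euclidean distance matrix
#'
#' Finds the smallest constant `c` such that adding `c` to every
#' off-diagonal distance makes the matrix Euclidean-embeddable (all
#' eigenvalues of the Gower-centred matrix non-negative). `c` is the largest
#' eigenvalue of the standard 2n x 2n companion matrix; already-Euclidean
#' input returns `c = 0`.
#'
#' @param dist A `beta_dist` (or square symmetric) matrix, n >= 3.
#' @return List with `dist` (corrected `beta_dist`) and `constant`.
#' @export
cailliez_correct <- function(dist) {
  D <- unclass(dist)
  n <- nrow(D)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  delta1 <- gower_center(D^2)
  delta2 <- gower_center(D)
  comp <- rbind(cbind(matrix(0, n, n), 2 * delta1),
                cbind(-diag(n), -4 * delta2))
  ev <- eigen(comp, only.values = TRUE)$values
  cc <- max(Re(ev))
  # numerically-zero constants on already-Euclidean input are clamped
  if (cc < 1e-8 * max(D)) cc <- 0
  out <- D + cc
  diag(out) <- 0
  list(dist = new_beta_dist(out, metric = "other"), constant = cc)
}

#' Principal coordinates analysis
#'
#' Gower double-centring of `-0.5 d^2` followed by eigendecomposition;
#' coordinates are eigenvectors scaled by `sqrt(lambda)`. Axes with
#' non-positive eigenvalues are dropped; negative eigenvalues within
#' `-1e-8 * max(lambda)` are clamped to zero. Variance explained is reported
#' over the positive eigenvalues. With `correction = "cailliez"` the
#' distances are made Euclidean first and the additive constant is recorded.
#'
#' @param dist A `beta_dist` (or square symmetric) matrix.
#' @param n_axes Number of axes to keep (default: all positive).
#' @param correction `"none"` or `"cailliez"`.
#' @return List of class `skin_pcoa`: `coordinates` tibble (`sample_id`,
#'   `PC1`, ...), `eigenvalues`, `prop_explained`, `cailliez_constant`.
#' @export
pcoa_dm <- function(dist, n_axes = NULL, correction = c("none", "cailliez")) {
  correction <- match.arg(correction)
  cc <- 0
  if (correction == "cailliez") {
    corr <- cailliez_correct(dist)
    dist <- corr$dist
    cc <- corr$constant
  }
  D <- unclass(dist)
  if (all(D == 0)) stop("degenerate distance matrix (all zeros)", call. = FALSE)
  B <- gower_center(D^2)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  lambda <- e$values
  lambda[lambda < 0 & lambda > -1e-8 * max(lambda)] <- 0
  pos <- which(lambda > 0)
  if (!length(pos)) stop("no positive eigenvalues", call. = FALSE)
  keep <- if (is.null(n_axes)) pos else pos[seq_len(min(n_axes, length(pos)))]
  coords <- sweep(e$vectors[, keep, drop = FALSE], 2, sqrt(lambda[keep]), "*")
  colnames(coords) <- paste0("PC", seq_along(keep))
  coord_tbl <- tibble::as_tibble(as.data.frame(coords))
  coord_tbl <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(D)), coord_tbl)
  structure(list(
    coordinates = coord_tbl,
    eigenvalues = lambda,
    prop_explained = lambda[pos] / sum(lambda[pos]),
    cailliez_constant = cc), class = "skin_pcoa")
}

#' @method tidy skin_pcoa
#' @export
tidy.skin_pcoa <- function(x, ...) x$coordinates

#' @method glance skin_pcoa
#' @export
glance.skin_pcoa <- function(x, ...) {
  tibble::tibble(
    n_axes = ncol(x$coordinates) - 1,
    prop_PC1 = x$prop_explained[1],
    prop_PC2 = if (length(x$prop_explained) >= 2) x$prop_explained[2] else NA_real_,
    cailliez_constant = x$cailliez_constant)
}

#' @method autoplot skin_pcoa
#' @export
autoplot.skin_pcoa <- function(object, metadata = NULL, ...) {
  d <- object$coordinates
  if (!is.null(metadata)) {
    d <- dplyr::left_join(d, metadata[, c("sample_id", "skin_type")], by = "sample_id")
    p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                         colour = .data$skin_type))
  } else {
    p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  }
  pe <- round(100 * object$prop_explained[1:2], 1)
  p + ggplot2::geom_point() +
    ggplot2::labs(x = paste0("PC1 (", pe[1], "%)"),
                  y = paste0("PC2 (", pe[2], "%)"))
}

#' Test ordination axes for skin-type differences
#'
#' One-way ANOVA of each requested principal coordinate against skin type,
#' with Tukey HSD pairwise comparisons.
#'
#' @param ordination A [pcoa_dm()] result.
#' @param metadata Sample metadata with `sample_id` and `skin_type`.
#' @param axes Integer axes to test (default 1:2).
#' @return Tibble: `axis`, `F`, `p_value`, plus one `tukey` list-column of
#'   pairwise adjusted p values.
#' @export
axis_group_test <- function(ordination, metadata, axes = 1:2) {
  d <- dplyr::inner_join(ordination$coordinates,
                         metadata[, c("sample_id", "skin_type")], by = "sample_id")
  d$skin_type <- droplevels(factor(d$skin_type))
  if (nlevels(d$skin_type) < 2) stop("need at least 2 groups", call. = FALSE)
  out <- list()
  for (ax in axes) {
    col <- paste0("PC", ax)
    if (!col %in% names(d)) stop("axis ", ax, " not present", call. = FALSE)
    y <- d[[col]]
    if (stats::sd(y) == 0) stop("axis ", ax, " has constant coordinates", call. = FALSE)
    fit <- stats::aov(y ~ skin_type, data = d)
    an <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit)$skin_type
    out[[length(out) + 1]] <- tibble::tibble(
      axis = ax, F = an$`F value`[1], p_value = an$`Pr(>F)`[1],
      tukey = list(tibble::as_tibble(as.data.frame(tk), rownames = "comparison")))
  }
  dplyr::bind_rows(out)
}
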