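#' Shannon diversity of a count vector
#'
#' `H = -sum(p_i log p_i)` over taxa with positive counts; natural log by
#' default (the vegan convention), so `H` is in nats and bounded by `log(S)`.
#'
#' @param x Non-negative count (or proportion) vector.
#' @param base Logarithm base.
#' @return Scalar diversity.
#' @examples
#' shannon_index(c(1, 1, 1, 1))  # log(4)
#' @export
shannon_index <- function(x, base = exp(1)) {
  if (any(x < 0)) stop("negative counts", call. = FALSE)
  if (sum(x) <= 0) stop("all-zero count vector", call. = FALSE)
  p <- x[x > 0] / sum(x)
  -sum(p * log(p, base = base))
}

richness_index <- function(x) sum(x > 0)

# Subsample a count vector to exactly `d` reads without replacement
# (multivariate hypergeometric draw).
rarefy_counts <- function(x, d) {
  stopifnot(d <= sum(x))
  reads <- rep.int(seq_along(x), x)
  picked <- sample(reads, d, replace = FALSE)
  tabulate(picked, nbins = length(x))
}

#' Rarefaction curves for richness and Shannon diversity
#'
#' For each sample and each depth `d <= N_j`, subsamples `reps` times without
#' replacement and averages both indices. Depths exceeding a sample's read
#' count yield `NA` for that sample.
#'
#' @param x Count-table tibble.
#' @param depths Ascending vector of subsampling depths (> 0).
#' @param reps Subsampling replicates per depth.
#' @param seed Integer seed for the subsampler.
#' @return A tibble of class `rarefaction_curve`: `sample_id`, `depth`,
#'   `index` (`"richness"`/`"shannon"`), `mean`, `sd`.
#' @export
rarefaction_curve <- function(x, depths, reps = 10, seed = 1) {
  stopifnot(reps >= 1)
  if (any(depths <= 0)) stop("depths must be positive", call. = FALSE)
  depths <- sort(depths)
  m <- count_matrix(validate_count_tbl(x))
  out <- with_seed(seed, {
    res <- list()
    for (j in seq_len(ncol(m))) {
      cnt <- m[, j]
      for (d in depths) {
        if (sum(cnt) < d) {
          rich <- sh <- rep(NA_real_, reps)
        } else if (sum(cnt) == d) {
          rich <- rep(richness_index(cnt), reps)
          sh <- rep(shannon_index(cnt), reps)
        } else {
          sub <- replicate(reps, rarefy_counts(cnt, d))
          rich <- apply(sub, 2, richness_index)
          sh <- apply(sub, 2, shannon_index)
        }
        res[[length(res) + 1]] <- tibble::tibble(
          sample_id = colnames(m)[j], depth = d,
          index = c("richness", "shannon"),
          mean = c(mean(rich), mean(sh)),
          sd = c(stats::sd(rich), stats::sd(sh)))
      }
    }
    dplyr::bind_rows(res)
  })
  class(out) <- c("rarefaction_curve", class(out))
  out
}

#' Test an alpha-diversity trend across skin types at a fixed depth
#'
#' Summarises a rarefaction curve per skin type at one depth (mean +/- SEM)
#' and tests for a group difference with the Kruskal-Wallis test.
#'
#' @param curve A [rarefaction_curve()] result.
#' @param metadata Sample metadata with `sample_id` and `skin_type`.
#' @param depth Depth at which to test (must be in the curve).
#' @param index `"shannon"` or `"richness"`.
#' @return List of class `alpha_trend`: `summary` tibble (per-group n, mean,
#'   sem), `statistic`, `p_value`, `depth`, `index`.
#' @export
group_alpha_trend <- function(curve, metadata, depth = 2000, index = "shannon") {
  index <- match.arg(index, c("shannon", "richness"))
  sub <- curve[curve$depth == depth & curve$index == index & !is.na(curve$mean), ]
  if (!nrow(sub)) stop("depth ", depth, " not present in curve", call. = FALSE)
  sub <- dplyr::inner_join(sub, metadata[, c("sample_id", "skin_type")],
                           by = "sample_id")
  counts <- table(sub$skin_type)
  empty <- names(counts)[counts == 0]
  if (length(empty)) {
    warning("group(s) with no sample at depth ", depth, ": ",
            paste(empty, collapse = ", "), " dropped")
    sub$skin_type <- droplevels(sub$skin_type)
    counts <- table(sub$skin_type)
  }
  if (any(counts < 2)) {
    stop("each group needs n >= 2 at the tested depth", call. = FALSE)
  }
  kw <- stats::kruskal.test(sub$mean, sub$skin_type)
  summary <- dplyr::summarise(
    dplyr::group_by(sub, .data$skin_type),
    n = dplyr::n(), mean = mean(.data$mean),
    sem = stats::sd(.data$mean) / sqrt(dplyr::n()), .groups = "drop")
  structure(list(summary = summary,
                 statistic = unname(kw$statistic), df = unname(kw$parameter),
                 p_value = kw$p.value, depth = depth, index = index),
            class = "alpha_trend")
}

#' Triplet-relative alpha diversity
#'
#' Subtracts each triplet's control value from its lesion and unaffected
#' values, removing between-triplet level differences so longitudinal trends
#' emerge from otherwise highly variable data. Control members (identically
#' zero) are not emitted; incomplete triplets are excluded with a warning.
#'
#' @param values Tibble with `sample_id` and `value` (an alpha-diversity
#'   index per sample).
#' @param metadata Sample metadata with `sample_id`, `skin_type`,
#'   `triplet_id`.
#' @return Tibble: `sample_id`, `triplet_id`, `skin_type`, `value`,
#'   `relative` (value minus the triplet's control value).
#' @export
relative_alpha <- function(values, metadata) {
  d <- dplyr::inner_join(values, metadata[, c("sample_id", "skin_type", "triplet_id")],
                         by = "sample_id")
  complete <- dplyr::summarise(
    dplyr::group_by(d, .data$triplet_id),
    ok = all(skin_type_levels() %in% .data$skin_type), .groups = "drop")
  bad <- complete$triplet_id[!complete$ok]
  if (length(bad)) {
    warning("incomplete triplet(s) excluded: ", paste(bad, collapse = ", "))
    d <- d[!d$triplet_id %in% bad, ]
  }
  ctrl <- d[d$skin_type == "control", c("triplet_id", "value")]
  names(ctrl)[2] <- "control_value"
  out <- dplyr::inner_join(d[d$skin_type != "control", ], ctrl, by = "triplet_id")
  out$relative <- out$value - out$control_value
  out[, c("sample_id", "triplet_id", "skin_type", "value", "relative")]
}

#' Taxa-sharing analysis across skin types
#'
#' Classifies each taxon by the set of skin types in which it occurs
#' (presence = at least one read), after excluding taxa present in fewer than
#' `min_samples` samples overall.
#'
#' @param x Count-table tibble (at any taxonomic level).
#' @param metadata Sample metadata with `sample_id` and `skin_type`.
#' @param min_samples Minimum number of samples a taxon must occur in.
#' @return Tibble: `taxon_id`, `n_samples`, `skin_types`
#'   (comma-joined), `shared_by` (1 = unique to one skin type, 3 = shared by
#'   all).
#' @export
taxa_sharing <- function(x, metadata, min_samples = 3) {
  m <- count_matrix(validate_count_tbl(x)) > 0
  md <- metadata[match(colnames(m), metadata$sample_id), ]
  keep <- rowSums(m) >= min_samples
  m <- m[keep, , drop = FALSE]
  types <- skin_type_levels()
  pres <- sapply(types, function(ty)
    rowSums(m[, md$skin_type == ty, drop = FALSE]) > 0)
  if (!is.matrix(pres)) pres <- matrix(pres, nrow = 1, dimnames = list(rownames(m), types))
  tibble::tibble(
    taxon_id = rownames(m),
    n_samples = unname(rowSums(m)),
    skin_types = unname(apply(pres, 1, function(r) paste(types[r], collapse = ","))),
    shared_by = unname(rowSums(pres)))
}

#' @method autoplot rarefaction_curve
#' @export
autoplot.rarefaction_curve <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$depth, y = .data$mean,
                               group = .data$sample_id)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = "sequences per sample", y = "diversity index")
}
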