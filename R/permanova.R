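#' Distance-based permutational MANOVA (adonis-style)
#'
#' Partitions the Gower-centred matrix of squared pairwise distances into
#' sequential (Type I) sums of squares over the model terms in the order
#' given, forms a pseudo-F per term
#' `(SS_term / df_term) / (SS_resid / df_resid)`, and calibrates significance
#' by permuting samples — freely, or within `strata` when the design is
#' blocked (e.g. by subject). The permutation p value uses the add-one rule
#' `(#\{F* >= F\} + 1) / (B + 1)` and is never reported as zero. Bonferroni
#' (capped at 1) and Benjamini-Hochberg adjusted p values across terms are
#' both reported.
#'
#' @param dist A `beta_dist` (or square symmetric) distance matrix.
#' @param data Sample metadata tibble with `sample_id` matching `dist`.
#' @param formula Right-hand-side formula over columns of `data`, e.g.
#'   `~ skin_type + body_site` or `~ skin_type * body_site`. Term order
#'   matters (sequential SS).
#' @param permutations Number of permutations `B`.
#' @param seed Integer seed for the permutation stream.
#' @param strata Optional column name in `data`; permutations are then
#'   restricted within its levels.
#' @return List of class `permanova`: `table` tibble (term, df, SS, pseudo-F,
#'   raw and adjusted p; Residual and Total rows), `permutations`, `seed`,
#'   `strata`.
#' @export
adonis_dm <- function(dist, data, formula, permutations = 999, seed = 1,
                      strata = NULL) {
  D <- unclass(dist)
  ids <- rownames(D)
  data <- as.data.frame(data)
  rownames(data) <- data$sample_id
  missing_ids <- setdiff(ids, data$sample_id)
  if (length(missing_ids)) {
    stop("samples absent from metadata: ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  }
  data <- data[ids, , drop = FALSE]
  vars <- all.vars(formula)
  use <- stats::complete.cases(data[, vars, drop = FALSE])
  if (any(!use)) {
    message("adonis_dm: dropped ", sum(!use), " sample(s) with missing factor levels: ",
            paste(ids[!use], collapse = ", "))
    data <- data[use, , drop = FALSE]
    D <- D[use, use, drop = FALSE]
    ids <- ids[use]
  }
  n <- nrow(D)
  data <- droplevels(data)
  for (v in vars) {
    col <- data[[v]]
    if ((is.factor(col) || is.character(col)) && length(unique(col)) < 2) {
      stop("term '", v, "' has a single level", call. = FALSE)
    }
  }
  mf <- stats::model.frame(formula, data)
  X <- stats::model.matrix(formula, mf)
  assign <- attr(X, "assign")
  term_labels <- attr(stats::terms(formula, data = data), "term.labels")

  G <- gower_center(D^2)
  total_ss <- sum(diag(G))

  # Projection bases for the nested sequence of models (intercept, +term1, ...)
  hats <- list()
  prev_rank <- 1L  # intercept
  dfs <- integer(length(term_labels))
  for (j in seq_along(term_labels)) {
    Xj <- X[, assign <= j, drop = FALSE]
    qrj <- qr(Xj)
    Q <- qr.Q(qrj)[, seq_len(qrj$rank), drop = FALSE]
    hats[[j]] <- tcrossprod(Q)
    dfs[j] <- qrj$rank - prev_rank
    prev_rank <- qrj$rank
  }
  if (any(dfs == 0)) {
    stop("term(s) contribute no degrees of freedom: ",
         paste(term_labels[dfs == 0], collapse = ", "), call. = FALSE)
  }
  # intercept-only hat (for the first term's increment)
  h0 <- matrix(1 / n, n, n)
  df_resid <- n - prev_rank
  if (df_resid <= 0) stop("model saturates the data (no residual df)", call. = FALSE)

  ss_terms <- function(Gp) {
    tr <- vapply(hats, function(H) sum(H * Gp), numeric(1))
    tr0 <- sum(h0 * Gp)
    ss <- diff(c(tr0, tr))
    res <- sum(diag(Gp)) - tr[length(tr)]
    list(ss = ss, resid = res)
  }
  obs <- ss_terms(G)
  f_obs <- (obs$ss / dfs) / (obs$resid / df_resid)

  strata_idx <- NULL
  if (!is.null(strata)) {
    sv <- data[[strata]]
    if (anyNA(sv)) stop("strata undefined for some samples", call. = FALSE)
    strata_idx <- split(seq_len(n), sv)
    singles <- names(strata_idx)[lengths(strata_idx) == 1]
    if (length(singles)) {
      warning("stratum(a) of size 1 contribute no permutation: ",
              paste(singles, collapse = ", "))
    }
  }
  perm_one <- function() {
    if (is.null(strata_idx)) return(sample.int(n))
    p <- seq_len(n)
    for (idx in strata_idx) if (length(idx) > 1) p[idx] <- idx[sample.int(length(idx))]
    p
  }
  exceed <- rep(0L, length(term_labels))
  with_seed(seed, {
    for (b in seq_len(permutations)) {
      p <- perm_one()
      Gp <- G[p, p]
      st <- ss_terms(Gp)
      f_p <- (st$ss / dfs) / (st$resid / df_resid)
      exceed <- exceed + (f_p >= f_obs - 1e-12)
    }
  })
  p_raw <- (exceed + 1) / (permutations + 1)
  tab <- tibble::tibble(
    term = term_labels, df = dfs, sum_of_squares = obs$ss,
    pseudo_F = f_obs, p_value = p_raw,
    p_bonferroni = pmin(p_raw * length(p_raw), 1),
    p_BH = stats::p.adjust(p_raw, "BH"))
  tab <- dplyr::bind_rows(
    tab,
    tibble::tibble(term = "Residual", df = df_resid, sum_of_squares = obs$resid,
                   pseudo_F = NA_real_, p_value = NA_real_,
                   p_bonferroni = NA_real_, p_BH = NA_real_),
    tibble::tibble(term = "Total", df = n - 1, sum_of_squares = total_ss,
                   pseudo_F = NA_real_, p_value = NA_real_,
                   p_bonferroni = NA_real_, p_BH = NA_real_))
  structure(list(table = tab, permutations = permutations, seed = seed,
                 strata = strata, n = n), class = "permanova")
}

#' @method tidy permanova
#' @export
tidy.permanova <- function(x, ...) x$table

#' @method glance permanova
#' @export
glance.permanova <- function(x, ...) {
  tot <- x$table$sum_of_squares[x$table$term == "Total"]
  res <- x$table$sum_of_squares[x$table$term == "Residual"]
  tibble::tibble(n = x$n, total_ss = tot, r_squared = 1 - res / tot,
                 permutations = x$permutations)
}

#' @export
print.permanova <- function(x, ...) {
  cat("Distance-based PERMANOVA (", x$permutations, " permutations",
      if (!is.null(x$strata)) paste0(", stratified by ", x$strata), ")\n", sep = "")
  print(x$table, n = Inf)
  invisible(x)
}

#' Post hoc pairwise PERMANOVA over the levels of one factor
#'
#' Runs a one-factor [adonis_dm()] on every pair of levels and adjusts the
#' permutation p values across pairs (Bonferroni capped at 1, and BH).
#'
#' @param dist A `beta_dist` matrix.
#' @param data Sample metadata.
#' @param factor_name Column of `data` with >= 3 levels.
#' @param permutations,seed Passed to [adonis_dm()].
#' @param min_n Minimum samples per level within a pair (smaller pairs are
#'   skipped with a warning).
#' @return Tibble: one row per level pair with df, SS, pseudo-F, raw and
#'   adjusted p values.
#' @export
pairwise_adonis <- function(dist, data, factor_name, permutations = 999,
                            seed = 1, min_n = 3) {
  lv <- unique(as.character(data[[factor_name]]))
  lv <- lv[!is.na(lv)]
  if (length(lv) < 3) stop("factor must have at least 3 levels", call. = FALSE)
  combos <- utils::combn(sort(lv), 2, simplify = FALSE)
  rows <- list()
  for (cb in combos) {
    keep <- data$sample_id[as.character(data[[factor_name]]) %in% cb]
    keep <- intersect(rownames(dist), keep)
    sub_md <- data[data$sample_id %in% keep, , drop = FALSE]
    sizes <- table(as.character(sub_md[[factor_name]]))
    if (any(sizes < min_n)) {
      warning("pair ", paste(cb, collapse = "/"), " skipped (level with < ",
              min_n, " samples)")
      next
    }
    sub <- new_beta_dist(unclass(dist)[keep, keep], attr(dist, "metric"))
    f <- stats::as.formula(paste("~", factor_name))
    fit <- adonis_dm(sub, sub_md, f, permutations = permutations, seed = seed)
    r <- fit$table[1, ]
    rows[[length(rows) + 1]] <- tibble::tibble(
      comparison = paste(cb, collapse = "/"), df = r$df,
      sum_of_squares = r$sum_of_squares, pseudo_F = r$pseudo_F,
      p_value = r$p_value)
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out)) {
    out$p_bonferroni <- pmin(out$p_value * nrow(out), 1)
    out$p_BH <- stats::p.adjust(out$p_value, "BH")
  }
  out
}

#' PERMANOVA with permutations restricted within subjects
#'
#' Convenience wrapper for matched designs: tests `term` while permuting
#' only within each stratum (by default the subject), removing
#' between-subject confounding from the permutation null.
#'
#' @param dist A `beta_dist` matrix.
#' @param data Sample metadata.
#' @param term Column of `data` to test.
#' @param strata Stratifying column (default `"subject_id"`).
#' @param permutations,seed Passed to [adonis_dm()].
#' @return A `permanova` object.
#' @export
stratified_adonis <- function(dist, data, term, strata = "subject_id",
                              permutations = 999, seed = 1) {
  adonis_dm(dist, data, stats::as.formula(paste("~", term)),
            permutations = permutations, seed = seed, strata = strata)
}
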