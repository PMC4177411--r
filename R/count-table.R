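#' Construct and validate an OTU count table
#'
#' A count table is a wide tibble: a `taxon_id` character column followed by
#' one non-negative integer column per sample. Taxa are rows, samples are
#' columns, matching the usual OTU-table orientation. All analysis functions
#' in the package accept this shape.
#'
#' @param x A matrix (taxa x samples, with dimnames) or a data frame whose
#'   first column is `taxon_id`.
#' @return A validated count-table tibble.
#' @examples
#' m <- matrix(c(5L, 0L, 3L, 2L), 2, 2,
#'             dimnames = list(c("OTU1", "OTU2"), c("s1", "s2")))
#' as_count_tbl(m)
#' @export
as_count_tbl <- function(x) {
  if (is.matrix(x)) {
    if (is.null(rownames(x)) || is.null(colnames(x))) {
      stop("count matrix must have taxon rownames and sample colnames", call. = FALSE)
    }
    x <- tibble::as_tibble(as.data.frame(x), rownames = "taxon_id")
  }
  x <- tibble::as_tibble(x)
  if (names(x)[1] != "taxon_id") names(x)[1] <- "taxon_id"
  x$taxon_id <- as.character(x$taxon_id)
  validate_count_tbl(x)
}

#' @rdname as_count_tbl
#' @export
validate_count_tbl <- function(x) {
  stopifnot(is.data.frame(x), ncol(x) >= 2)
  if (anyDuplicated(x$taxon_id)) {
    stop("duplicate taxon ids: ",
         paste(unique(x$taxon_id[duplicated(x$taxon_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(names(x))) {
    stop("duplicate sample ids: ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "),
         call. = FALSE)
  }
  for (j in seq(2, ncol(x))) {
    v <- x[[j]]
    if (!is.numeric(v)) stop("column '", names(x)[j], "' is not numeric", call. = FALSE)
    bad <- which(is.na(v) | v < 0 | abs(v - round(v)) > 1e-8)
    if (length(bad)) {
      stop("non-negative integer counts required; offending cell: taxon '",
           x$taxon_id[bad[1]], "', sample '", names(x)[j], "' (value ",
           v[bad[1]], ")", call. = FALSE)
    }
  }
  x
}

# Laxer check for relative-abundance tables: numeric, non-negative, unique ids.
validate_abundance_tbl <- function(x) {
  stopifnot(is.data.frame(x), ncol(x) >= 2)
  if (anyDuplicated(x[[1]])) stop("duplicate taxon ids", call. = FALSE)
  for (j in seq(2, ncol(x))) {
    v <- x[[j]]
    if (!is.numeric(v) || anyNA(v) || any(v < 0)) {
      stop("column '", names(x)[j], "' must be non-negative numeric", call. = FALSE)
    }
  }
  x
}

#' Extract the numeric matrix from a count or relative-abundance table
#'
#' @param x A count-table tibble (`taxon_id` + sample columns).
#' @return Numeric matrix, taxa x samples, with dimnames.
#' @export
count_matrix <- function(x) {
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x$taxon_id
  m
}

#' Per-sample sequencing depth
#'
#' @param x A count-table tibble.
#' @return Tibble with `sample_id` and `depth` (column sums).
#' @export
sample_depths <- function(x) {
  m <- count_matrix(x)
  tibble::tibble(sample_id = colnames(m), depth = unname(colSums(m)))
}

#' Read and write OTU count tables
#'
#' TSV dialect: taxa as rows, first column the taxon id, header row of sample
#' ids. BIOM support covers the version 1.0 JSON format (sparse or dense),
#' via the biomformat package.
#'
#' @param path File path.
#' @param format `"tsv"` or `"biom"`; guessed from the extension by default.
#' @return `read_count_table()`: a count-table tibble. `write_count_table()`:
#'   the input, invisibly.
#' @export
read_count_table <- function(path, format = c("auto", "tsv", "biom")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.biom$|\\.json$", path, ignore.case = TRUE)) "biom" else "tsv"
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "tsv") {
    tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                             colClasses = "character")
    names(tab)[1] <- "taxon_id"
    for (j in seq(2, ncol(tab))) {
      v <- suppressWarnings(as.numeric(tab[[j]]))
      bad <- which(is.na(v))
      if (length(bad)) {
        stop("non-numeric count in sample '", names(tab)[j], "', taxon '",
             tab$taxon_id[bad[1]], "': \"", tab[[j]][bad[1]], "\"", call. = FALSE)
      }
      tab[[j]] <- v
    }
    as_count_tbl(tab)
  } else {
    b <- biomformat::read_biom(path)
    as_count_tbl(as(biomformat::biom_data(b), "matrix"))
  }
}

#' @rdname read_count_table
#' @param x A count-table tibble.
#' @export
write_count_table <- function(x, path, format = c("auto", "tsv", "biom")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.biom$|\\.json$", path, ignore.case = TRUE)) "biom" else "tsv"
  }
  x <- validate_count_tbl(x)
  if (format == "tsv") {
    out <- x
    names(out)[1] <- "#OTU ID"
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    b <- biomformat::make_biom(count_matrix(x))
    biomformat::write_biom(b, path)
  }
  invisible(x)
}

#' Read a rooted phylogenetic tree with branch lengths
#'
#' Thin wrapper over [ape::read.tree()] that enforces the contract UniFrac
#' needs: branch lengths present, finite and non-negative, unique tip labels.
#'
#' @param path Newick file path.
#' @return An [ape::phylo] object.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tr <- ape::read.tree(path)
  check_tree(tr)
}

check_tree <- function(tr) {
  if (is.null(tr$edge.length)) {
    stop("tree has no branch lengths; UniFrac requires them", call. = FALSE)
  }
  if (any(!is.finite(tr$edge.length)) || any(tr$edge.length < 0)) {
    stop("branch lengths must be finite and non-negative", call. = FALSE)
  }
  if (anyDuplicated(tr$tip.label)) stop("duplicate tip labels", call. = FALSE)
  tr
}

#' @rdname read_tree
#' @param tree An `ape::phylo` tree.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(tree)
}

#' Read taxonomy and sample-metadata tables
#'
#' Both are tab-delimited with a header. The taxonomy table has columns
#' `taxon_id`, `phylum`, `class`, `order`, `family`, `genus`; unassigned ranks
#' may be empty or NA and are normalised to `"Other"`. The metadata table is
#' keyed by `sample_id` and carries the study factors (skin type, triplet and
#' subject ids, body site, microenvironment, demographics, severity scores,
#' longitudinal week).
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_taxonomy <- function(path) {
  tab <- tibble::as_tibble(utils::read.delim(path, check.names = FALSE,
                                             stringsAsFactors = FALSE))
  names(tab)[1] <- "taxon_id"
  normalize_taxonomy(tab)
}

#' @rdname read_taxonomy
#' @export
read_sample_metadata <- function(path) {
  tab <- tibble::as_tibble(utils::read.delim(path, check.names = FALSE,
                                             stringsAsFactors = FALSE))
  names(tab)[1] <- "sample_id"
  if ("skin_type" %in% names(tab)) {
    tab$skin_type <- factor(tab$skin_type, levels = skin_type_levels())
  }
  tab
}

#' @export
#' @rdname read_taxonomy
#' @param x A table to write.
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}

skin_type_levels <- function() c("control", "unaffected", "lesion")

taxonomy_ranks <- function() c("phylum", "class", "order", "family", "genus")

# Fill unassigned ranks with "Other" so collapsed lineage ids stay unique
# (e.g. an unassigned genus under family Gp4 becomes lineage ".;Gp4;Other").
normalize_taxonomy <- function(taxonomy) {
  for (r in taxonomy_ranks()) {
    if (!r %in% names(taxonomy)) stop("taxonomy lacks rank column '", r, "'", call. = FALSE)
    v <- as.character(taxonomy[[r]])
    v[is.na(v) | v == ""] <- "Other"
    taxonomy[[r]] <- v
  }
  taxonomy
}

#' Drop samples sequenced below a depth threshold
#'
#' Retains samples whose total read count is strictly greater than
#' `min_depth` (default 1,000 reads), the usual adequacy cut-off for matched
#' triplet designs. Removed sample ids are reported via a message.
#'
#' @param x Count-table tibble.
#' @param min_depth Depth threshold (strict `>`).
#' @return Filtered count-table tibble.
#' @export
filter_low_depth <- function(x, min_depth = 1000) {
  stopifnot(min_depth >= 1)
  x <- validate_count_tbl(x)
  d <- sample_depths(x)
  keep <- d$sample_id[d$depth > min_depth]
  drop <- setdiff(d$sample_id, keep)
  if (!length(keep)) stop("all samples removed by depth filter (min_depth = ",
                          min_depth, ")", call. = FALSE)
  if (length(drop)) {
    message("filter_low_depth: removed ", length(drop), " sample(s): ",
            paste(drop, collapse = ", "))
  }
  x[, c("taxon_id", keep)]
}

#' Convert counts to relative abundances
#'
#' Divides each sample column by its total read count, so columns sum to 1.
#'
#' @param x Count-table tibble.
#' @return Tibble of the same shape holding per-sample proportions.
#' @export
to_relative <- function(x) {
  x <- validate_count_tbl(x)
  m <- count_matrix(x)
  depths <- colSums(m)
  if (any(depths == 0)) {
    stop("zero-depth sample(s): ",
         paste(colnames(m)[depths == 0], collapse = ", "), call. = FALSE)
  }
  out <- sweep(m, 2, depths, "/")
  tibble::as_tibble(as.data.frame(out), rownames = "taxon_id")
}

#' Collapse an OTU table to a higher taxonomic rank
#'
#' Sums OTU rows by their lineage prefix through `rank`; the joined lineage
#' string (ranks separated by `";"`) becomes the new taxon id. Per-sample
#' totals are preserved. `rank = "otu"` is the identity.
#'
#' @param x Count-table tibble with OTU rows.
#' @param taxonomy Taxonomy tibble covering every OTU in `x`.
#' @param rank One of `"phylum"`, `"class"`, `"order"`, `"family"`,
#'   `"genus"`, `"otu"`.
#' @return Collapsed count-table tibble.
#' @export
collapse_taxonomy <- function(x, taxonomy, rank) {
  rank <- match.arg(rank, c(taxonomy_ranks(), "otu"))
  x <- validate_count_tbl(x)
  if (rank == "otu") return(x)
  taxonomy <- normalize_taxonomy(taxonomy)
  missing <- setdiff(x$taxon_id, taxonomy$taxon_id)
  if (length(missing)) {
    stop("OTUs missing from taxonomy: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ranks <- taxonomy_ranks()[seq_len(match(rank, taxonomy_ranks()))]
  tx <- taxonomy[match(x$taxon_id, taxonomy$taxon_id), , drop = FALSE]
  lineage <- do.call(paste, c(tx[ranks], sep = ";"))
  m <- count_matrix(x)
  out <- rowsum(m, group = lineage, reorder = TRUE)
  as_count_tbl(tibble::as_tibble(as.data.frame(out), rownames = "taxon_id"))
}
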