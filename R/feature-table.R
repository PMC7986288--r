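#' Construct a feature table
#'
#' A feature table holds non-negative counts (or relative abundances) of
#' features — OTU-like taxa or gene families — per sample, optionally with a
#' semicolon-delimited taxonomic lineage per feature. It is stored as a
#' tibble with features as rows: a `feature_id` column, an optional
#' `lineage` column, and one numeric column per sample, mirroring the
#' on-disk TSV layout. All matrix operations downstream are label-driven.
#'
#' @param counts Numeric matrix, samples x features, with unique dimnames
#'   (rows = sample ids, columns = feature ids), all values non-negative.
#' @param lineage Optional character vector of lineages, one per feature
#'   (semicolon-delimited ranks, kingdom to genus).
#' @return A `feature_table` (tibble subclass).
#' @export
#' @examples
#' m <- matrix(c(5, 1, 0, 0, 2, 7), nrow = 2,
#'             dimnames = list(c("s1", "s2"), c("fA", "fB", "fC")))
#' feature_table(m)
feature_table <- function(counts, lineage = NULL) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    abort("`counts` must be a numeric matrix (samples x features).")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("`counts` must carry sample ids as rownames and feature ids as colnames.")
  }
  if (anyDuplicated(rownames(counts))) {
    abort(paste0("Duplicate sample id: ",
                 rownames(counts)[duplicated(rownames(counts))][1]))
  }
  if (anyDuplicated(colnames(counts))) {
    abort(paste0("Duplicate feature id: ",
                 colnames(counts)[duplicated(colnames(counts))][1]))
  }
  if (anyNA(counts) || any(counts < 0)) {
    abort("Counts must be non-negative and non-missing.")
  }
  if (!is.null(lineage) && length(lineage) != ncol(counts)) {
    abort("`lineage` must have one entry per feature.")
  }
  out <- tibble(feature_id = colnames(counts))
  if (!is.null(lineage)) out$lineage <- as.character(lineage)
  out <- dplyr::bind_cols(out, as_tibble(t(counts)))
  class(out) <- c("feature_table", class(out))
  out
}

#' Test for a feature table
#' @param x Object.
#' @return Logical scalar.
#' @export
is_feature_table <- function(x) inherits(x, "feature_table")

#' Extract the sample-by-feature count matrix
#'
#' @param ft A [feature_table()].
#' @return Numeric matrix, samples x features, with dimnames.
#' @export
ft_counts <- function(ft) {
  stopifnot(is_feature_table(ft))
  cols <- ft_samples(ft)
  m <- t(as.matrix(ft[, cols, drop = FALSE]))
  dimnames(m) <- list(cols, ft$feature_id)
  m
}

#' @rdname ft_counts
#' @return `ft_samples()`: character vector of sample ids.
#' @export
ft_samples <- function(ft) {
  setdiff(names(ft), c("feature_id", "lineage"))
}

#' @rdname ft_counts
#' @return `ft_lineage()`: named character vector of lineages, or `NULL`.
#' @export
ft_lineage <- function(ft) {
  if (!"lineage" %in% names(ft)) return(NULL)
  setNames(ft$lineage, ft$feature_id)
}

#' Convert counts to relative abundances
#'
#' Divides each sample's counts by that sample's total so every sample sums
#' to one. Idempotent on already-normalized input.
#'
#' @param ft A [feature_table()].
#' @return A `feature_table` of relative abundances.
#' @export
relative_abundance <- function(ft) {
  m <- ft_counts(ft)
  tot <- rowSums(m)
  if (any(tot <= 0)) {
    abort(paste0("Sample with zero total count: ",
                 rownames(m)[tot <= 0][1]))
  }
  feature_table(m / tot, lineage = ft_lineage(ft))
}

#' Aggregate features by taxonomic rank
#'
#' Sums counts of features sharing the same label at the requested rank of
#' their semicolon-delimited lineage. Features with no label at that rank
#' (missing lineage, too-shallow lineage, or an empty rank field) are
#' pooled under `"Unassigned"`. Per-sample totals are conserved.
#'
#' @param ft A [feature_table()] with a `lineage` column.
#' @param rank Rank name, one of kingdom, phylum, class, order, family,
#'   genus.
#' @return A `feature_table` whose feature ids are rank labels.
#' @export
aggregate_taxonomy <- function(ft, rank = c("order", "genus", "kingdom",
                                            "phylum", "class", "family")) {
  rank <- match.arg(rank)
  lin <- ft_lineage(ft)
  if (is.null(lin)) abort("Feature table has no `lineage` column.")
  depth <- match(rank, c("kingdom", "phylum", "class", "order", "family",
                         "genus"))
  parts <- strsplit(lin, ";", fixed = TRUE)
  label <- vapply(parts, function(p) {
    if (length(p) < depth) return("Unassigned")
    lab <- trimws(p[depth])
    if (!nzchar(lab)) "Unassigned" else lab
  }, character(1))
  m <- ft_counts(ft)
  agg <- rowsum(t(m), group = label)        # features x samples summed
  feature_table(t(agg))
}

#' Most abundant taxa by mean relative abundance
#'
#' @param ft A [feature_table()].
#' @param n Number of features to return.
#' @return Character vector of feature ids, ordered from most to least
#'   abundant by mean relative abundance across samples.
#' @export
top_taxa <- function(ft, n = 12) {
  rel <- ft_counts(relative_abundance(ft))
  mu <- colMeans(rel)
  names(sort(mu, decreasing = TRUE))[seq_len(min(n, length(mu)))]
}

#' Read and write feature tables as TSV
#'
#' The TSV dialect is features as rows and samples as columns, tab
#' delimited, first header cell `#FeatureID`, with an optional `lineage`
#' column immediately after the feature ids. Writing then re-reading
#' preserves ids, lineages and counts exactly.
#'
#' @param path File path.
#' @param format `"tsv"` (canonical) or `"biom"` (optional, read-only,
#'   requires the biomformat package).
#' @return `read_feature_table()`: a [feature_table()].
#' @export
read_feature_table <- function(path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      abort("BIOM input requires the `biomformat` package.")
    }
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")   # features x samples
    return(feature_table(t(m)))
  }
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !nzchar(first)) {
    abort(paste0("Not a feature table (empty file): ", path))
  }
  if (!startsWith(first, "#FeatureID")) {
    abort("Malformed feature table: first header cell must be '#FeatureID'.")
  }
  header <- strsplit(first, "\t", fixed = TRUE)[[1]]
  spec <- if ("lineage" %in% header) {
    readr::cols(`#FeatureID` = "c", lineage = "c", .default = "d")
  } else {
    readr::cols(`#FeatureID` = "c", .default = "d")
  }
  raw <- readr::read_tsv(path, col_types = spec)
  names(raw)[1] <- "feature_id"
  lineage <- if ("lineage" %in% names(raw)) raw$lineage
  samples <- setdiff(names(raw), c("feature_id", "lineage"))
  if (length(samples) == 0L) abort("Feature table has no sample columns.")
  if (anyDuplicated(raw$feature_id)) {
    abort(paste0("Duplicate feature id: ",
                 raw$feature_id[duplicated(raw$feature_id)][1]))
  }
  m <- as.matrix(raw[, samples, drop = FALSE])
  rownames(m) <- raw$feature_id
  feature_table(t(m), lineage = lineage)
}

#' @rdname read_feature_table
#' @param ft A [feature_table()] to write.
#' @return `write_feature_table()`: `path`, invisibly.
#' @export
write_feature_table <- function(ft, path) {
  stopifnot(is_feature_table(ft))
  out <- as_tibble(ft)
  names(out)[1] <- "#FeatureID"
  readr::write_tsv(out, path)
  invisible(path)
}
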