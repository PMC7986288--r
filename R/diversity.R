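#' Pairwise community dissimilarities
#'
#' From-scratch implementations of the two non-phylogenetic beta-diversity
#' metrics used throughout the screen. Both take two named, equally-indexed
#' non-negative count (or relative-abundance) vectors.
#'
#' `jaccard_distance()` is the presence/absence metric
#' `1 - |A intersect B| / |A union B|` with presence defined as count > 0;
#' two all-zero samples have distance 0 by convention. It is invariant to
#' count scaling.
#'
#' `bray_curtis_distance()` is `1 - 2 * sum(min(a, b)) / sum(a + b)`;
#' undefined (an error) when both samples are all-zero.
#'
#' @param a,b Non-negative numeric vectors over the same features. If both
#'   are named, features are matched by name and must agree as sets.
#' @return A number in \[0, 1\].
#' @export
#' @examples
#' jaccard_distance(c(x = 1, y = 2, z = 0), c(x = 0, y = 5, z = 3))  # 2/3
#' bray_curtis_distance(c(6, 4), c(2, 8))                            # 0.4
jaccard_distance <- function(a, b) {
  v <- align_features(a, b)
  pa <- v$a > 0
  pb <- v$b > 0
  union <- sum(pa | pb)
  if (union == 0) return(0)
  1 - sum(pa & pb) / union
}

#' @rdname jaccard_distance
#' @export
bray_curtis_distance <- function(a, b) {
  v <- align_features(a, b)
  tot <- sum(v$a) + sum(v$b)
  if (tot == 0) abort("Bray-Curtis is undefined for two all-zero samples.")
  1 - 2 * sum(pmin(v$a, v$b)) / tot
}

align_features <- function(a, b) {
  if (anyNA(a) || anyNA(b) || any(a < 0) || any(b < 0)) {
    abort("Count vectors must be non-negative and non-missing.")
  }
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b))) {
      abort("Samples are indexed over different feature sets.")
    }
    b <- b[names(a)]
  } else if (length(a) != length(b)) {
    abort("Unnamed count vectors must have equal length.")
  }
  list(a = as.numeric(a), b = as.numeric(b))
}

#' Alpha diversity of a single sample
#'
#' `observed_features()` counts features with count > 0.
#' `pielou_evenness()` is the Shannon entropy (natural log) of the
#' relative abundances divided by `log(S)` where `S` is the number of
#' observed features; it is defined as 0 for a single-feature sample and
#' errors on an all-zero sample.
#'
#' @param counts Non-negative numeric vector.
#' @return A scalar: an integer count, or a number in \[0, 1\].
#' @export
#' @examples
#' observed_features(c(5, 0, 2))   # 2
#' pielou_evenness(c(50, 50))      # 1
observed_features <- function(counts) {
  if (anyNA(counts) || any(counts < 0)) {
    abort("Counts must be non-negative and non-missing.")
  }
  sum(counts > 0)
}

#' @rdname observed_features
#' @export
pielou_evenness <- function(counts) {
  if (anyNA(counts) || any(counts < 0)) {
    abort("Counts must be non-negative and non-missing.")
  }
  pos <- counts[counts > 0]
  s <- length(pos)
  if (s == 0) abort("Evenness is undefined for an all-zero sample.")
  if (s == 1) return(0)
  p <- pos / sum(pos)
  -sum(p * log(p)) / log(s)
}

#' Rarefy a sample to even depth
#'
#' Subsamples reads without replacement to the requested depth; used as an
#' optional pre-step before presence/absence metrics.
#'
#' @param counts Non-negative integer vector.
#' @param depth Target depth, at most `sum(counts)`.
#' @return Integer vector of rarefied counts.
#' @export
rarefy_counts <- function(counts, depth) {
  total <- sum(counts)
  if (depth > total) abort("Rarefaction depth exceeds sample total.")
  pool <- rep(seq_along(counts), times = counts)
  keep <- sample(pool, depth, replace = FALSE)
  out <- tabulate(keep, nbins = length(counts))
  names(out) <- names(counts)
  out
}
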