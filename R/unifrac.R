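#' UniFrac phylogenetic beta diversity
#'
#' From-scratch UniFrac between two samples over a rooted, branch-length
#' annotated tree whose leaves cover all present features. Unrooted input
#' trees are midpoint-rooted on entry.
#'
#' Unweighted UniFrac is the branch length unique to one sample's leaf set
#' divided by the branch length covered by either leaf set. Weighted
#' UniFrac first converts each sample to relative abundance; the raw
#' variant is `sum(b_e * |P_a(e) - P_b(e)|)` over branches `e` of length
#' `b_e`, where `P_x(e)` is the fraction of sample `x`'s abundance on
#' leaves descending `e`; the normalized variant divides by
#' `sum(b_e * (P_a(e) + P_b(e)))` so values lie in \[0, 1\].
#'
#' @param a,b Non-negative named numeric vectors over the same features.
#' @param tree An [ape::phylo] with branch lengths; leaves must include
#'   every feature with a positive count.
#' @return A non-negative number (in \[0, 1\] for unweighted and normalized
#'   weighted variants).
#' @export
unweighted_unifrac <- function(a, b, tree) {
  v <- align_features(a, b)
  ids <- names(a) %||% names(b)
  br <- branch_incidence(tree, ids, present = (v$a > 0) | (v$b > 0))
  da <- as.numeric((v$a > 0) %*% br$inc) > 0   # branch has a descendant in a
  db <- as.numeric((v$b > 0) %*% br$inc) > 0
  either <- da | db
  if (!any(either)) return(0)
  sum(br$len[xor(da, db)]) / sum(br$len[either])
}

#' @rdname unweighted_unifrac
#' @param normalized Divide the weighted sum by its maximum attainable
#'   value so the distance lies in \[0, 1\] (default `TRUE`).
#' @export
weighted_unifrac <- function(a, b, tree, normalized = TRUE) {
  v <- align_features(a, b)
  ids <- names(a) %||% names(b)
  if (sum(v$a) == 0 || sum(v$b) == 0) {
    abort("Weighted UniFrac needs positive totals in both samples.")
  }
  br <- branch_incidence(tree, ids, present = (v$a > 0) | (v$b > 0))
  pa <- as.numeric((v$a / sum(v$a)) %*% br$inc)
  pb <- as.numeric((v$b / sum(v$b)) %*% br$inc)
  raw <- sum(br$len * abs(pa - pb))
  if (!normalized) return(raw)
  denom <- sum(br$len * (pa + pb))
  if (denom == 0) return(0)
  raw / denom
}

# Rooted tree -> per-branch leaf incidence over `ids`.
# Returns inc: length(ids) x n_edges 0/1 matrix (rows follow `ids`) and
# len: edge lengths. Errors if a present feature is missing from the tree.
branch_incidence <- function(tree, ids, present = NULL) {
  tree <- ensure_rooted(tree)
  missing <- if (is.null(present)) setdiff(ids, tree$tip.label) else
    setdiff(ids[present], tree$tip.label)
  if (length(missing) > 0) {
    abort(paste0("Feature absent from tree: ", missing[1]))
  }
  ntip <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  nedge <- nrow(po$edge)
  # accumulate the tip set below each node, then below each edge's child
  below <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- i
  edge_tips <- vector("list", nedge)
  for (e in seq_len(nedge)) {
    child <- po$edge[e, 2]
    edge_tips[[e]] <- below[[child]]
    parent <- po$edge[e, 1]
    below[[parent]] <- c(below[[parent]], below[[child]])
  }
  inc_tips <- matrix(0, nrow = ntip, ncol = nedge,
                     dimnames = list(tree$tip.label, NULL))
  for (e in seq_len(nedge)) inc_tips[edge_tips[[e]], e] <- 1
  inc <- matrix(0, nrow = length(ids), ncol = nedge)
  hit <- ids %in% tree$tip.label
  inc[hit, ] <- inc_tips[ids[hit], , drop = FALSE]
  list(inc = inc, len = po$edge.length)
}

ensure_rooted <- function(tree) {
  if (ape::is.rooted(tree)) return(tree)
  if (!requireNamespace("phangorn", quietly = TRUE)) {
    abort("Midpoint rooting of an unrooted tree requires `phangorn`.")
  }
  phangorn::midpoint(tree)
}

#' All pairwise distances of a feature table
#'
#' Computes the full symmetric distance matrix of a feature table under one
#' of the four supported metrics, delegating each pair to the corresponding
#' single-pair operation's formula (vectorized over branches/features).
#'
#' @param ft A [feature_table()].
#' @param metric One of `"jaccard"`, `"bray_curtis"`,
#'   `"unweighted_unifrac"`, `"weighted_unifrac"`.
#' @param tree Rooted [ape::phylo]; required for the UniFrac metrics.
#' @param normalized For `"weighted_unifrac"` only (default `TRUE`).
#' @return A symmetric numeric matrix with zero diagonal and sample ids as
#'   dimnames, classed `"mbra_dist"` with a `metric` attribute.
#' @export
distance_matrix <- function(ft, metric = c("jaccard", "bray_curtis",
                                           "unweighted_unifrac",
                                           "weighted_unifrac"),
                            tree = NULL, normalized = TRUE) {
  metric <- match.arg(metric)
  m <- ft_counts(ft)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  if (metric %in% c("unweighted_unifrac", "weighted_unifrac")) {
    if (is.null(tree)) abort("UniFrac metrics require `tree`.")
    br <- branch_incidence(tree, colnames(m),
                           present = colSums(m) > 0)
    if (metric == "unweighted_unifrac") {
      pres <- (m > 0) %*% br$inc > 0           # samples x edges
      for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        either <- pres[i, ] | pres[j, ]
        d[i, j] <- d[j, i] <- if (!any(either)) 0 else
          sum(br$len[xor(pres[i, ], pres[j, ])]) / sum(br$len[either])
      }
    } else {
      tot <- rowSums(m)
      if (any(tot == 0)) abort("Weighted UniFrac needs positive sample totals.")
      p <- (m / tot) %*% br$inc                # samples x edges fractions
      for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        raw <- sum(br$len * abs(p[i, ] - p[j, ]))
        d[i, j] <- d[j, i] <- if (!normalized) raw else {
          denom <- sum(br$len * (p[i, ] + p[j, ]))
          if (denom == 0) 0 else raw / denom
        }
      }
    }
  } else if (metric == "jaccard") {
    pres <- m > 0
    inter <- tcrossprod(pres * 1)
    nfeat <- diag(inter)
    union <- outer(nfeat, nfeat, "+") - inter
    dj <- 1 - inter / union
    dj[union == 0] <- 0
    d[] <- dj
    diag(d) <- 0
  } else {
    tot <- rowSums(m)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (tot[i] + tot[j] == 0) {
        abort("Bray-Curtis is undefined for two all-zero samples.")
      }
      d[i, j] <- d[j, i] <-
        1 - 2 * sum(pmin(m[i, ], m[j, ])) / (tot[i] + tot[j])
    }
  }
  structure(d, class = c("mbra_dist", "matrix"), metric = metric)
}

#' @export
as_tibble.mbra_dist <- function(x, ...) {
  ids <- rownames(x)
  pairs <- which(upper.tri(x), arr.ind = TRUE)
  tibble(sample_a = ids[pairs[, 1]],
         sample_b = ids[pairs[, 2]],
         distance = x[pairs])
}

#' Write a distance matrix as labeled square TSV
#'
#' @param d An `"mbra_dist"` matrix from [distance_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(d, path) {
  out <- as_tibble(as.data.frame(unclass(d)))
  out <- dplyr::bind_cols(tibble(sample_id = rownames(d)), out)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Principal coordinate analysis (classical metric scaling)
#'
#' Double-centered Gower-matrix eigendecomposition via [stats::cmdscale()].
#' Negative eigenvalues are dropped; the proportion of variance explained is
#' computed over the positive eigenvalues only.
#'
#' @param d A symmetric distance matrix (an `"mbra_dist"` or plain matrix).
#' @param n_axes Number of axes requested; silently truncated (with a
#'   warning) to the number of positive eigenvalues.
#' @return List with `coordinates` (tibble: `sample_id` plus `PC1`, ...,
#'   one column per retained axis) and `prop_explained` (numeric per axis).
#' @export
pcoa <- function(d, n_axes = 2) {
  d <- unclass(d)
  n <- nrow(d)
  fit <- suppressWarnings(cmdscale(stats::as.dist(d), k = max(1, n - 1),
                                   eig = TRUE))
  pos <- fit$eig > sqrt(.Machine$double.eps) * max(abs(fit$eig), 1)
  rank <- sum(pos)
  if (rank == 0) {
    coords <- matrix(0, n, n_axes,
                     dimnames = list(rownames(d),
                                     paste0("PC", seq_len(n_axes))))
    return(list(
      coordinates = dplyr::bind_cols(tibble(sample_id = rownames(d)),
                                     as_tibble(coords)),
      prop_explained = rep(0, n_axes)))
  }
  if (n_axes > rank) {
    warn(paste0("Only ", rank, " positive eigenvalue(s); axes truncated."))
    n_axes <- rank
  }
  coords <- fit$points[, seq_len(n_axes), drop = FALSE]
  colnames(coords) <- paste0("PC", seq_len(n_axes))
  prop <- fit$eig[pos][seq_len(n_axes)] / sum(fit$eig[pos])
  list(coordinates = dplyr::bind_cols(tibble(sample_id = rownames(d)),
                                      as_tibble(coords)),
       prop_explained = prop)
}
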