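# Independent brute-force UniFrac oracle: for every edge, the set of
# descendant tips is found by walking each tip's path to the root through a
# parent map (no postorder accumulation), and the metric is assembled with
# explicit per-edge loops.
brute_unifrac <- function(a, b, tree, weighted = FALSE, normalized = TRUE) {
  stopifnot(ape::is.rooted(tree))
  edge <- tree$edge
  len <- tree$edge.length
  ntip <- length(tree$tip.label)
  parent_of <- integer(max(edge))
  parent_of[edge[, 2]] <- edge[, 1]
  root <- setdiff(edge[, 1], edge[, 2])[1]
  path_nodes <- lapply(seq_len(ntip), function(tip) {
    nodes <- tip
    while (nodes[length(nodes)] != root) {
      nodes <- c(nodes, parent_of[nodes[length(nodes)]])
    }
    nodes
  })
  tips_below <- lapply(seq_len(nrow(edge)), function(e) {
    child <- edge[e, 2]
    which(vapply(path_nodes, function(p) child %in% p, logical(1)))
  })
  a <- a[tree$tip.label]
  b <- b[tree$tip.label]
  if (weighted) {
    pa <- a / sum(a)
    pb <- b / sum(b)
    num <- 0
    den <- 0
    for (e in seq_len(nrow(edge))) {
      wa <- sum(pa[tips_below[[e]]])
      wb <- sum(pb[tips_below[[e]]])
      num <- num + len[e] * abs(wa - wb)
      den <- den + len[e] * (wa + wb)
    }
    if (!normalized) return(num)
    return(if (den == 0) 0 else num / den)
  }
  uniq <- 0
  either <- 0
  for (e in seq_len(nrow(edge))) {
    ina <- any(a[tips_below[[e]]] > 0)
    inb <- any(b[tips_below[[e]]] > 0)
    if (ina || inb) either <- either + len[e]
    if (xor(ina, inb)) uniq <- uniq + len[e]
  }
  if (either == 0) return(0)
  uniq / either
}

# random rooted tree with branch lengths and labelled tips
random_tree <- function(n_tips) {
  tree <- ape::rtree(n_tips, tip.label = paste0("t", seq_len(n_tips)))
  tree$edge.length <- stats::runif(length(tree$edge.length), 0.05, 2)
  tree
}

random_counts <- function(tree, max_count = 20, p_zero = 0.3) {
  n <- length(tree$tip.label)
  x <- stats::rpois(n, lambda = stats::runif(n, 0.5, max_count))
  x[stats::runif(n) < p_zero] <- 0
  stats::setNames(x, tree$tip.label)
}

# small feature table shared by io/diversity tests
tiny_feature_table <- function() {
  m <- matrix(c(5, 1, 0,
                0, 2, 7), nrow = 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("fA", "fB", "fC")))
  feature_table(m, lineage = c(
    "Bacteria;P1;C1;Bacteroidales;F1;Bacteroides",
    "Bacteria;P1;C1;Bacteroidales;F1;Prevotella",
    "Bacteria;P2;C2;Clostridiales;F2;Blautia"))
}

# small null-trajectory series over the full schedule for scoring tests
flat_series <- function(n_ctrl = 3, n_trt = 3, sd = 0.1, seed = 1) {
  set.seed(seed)
  times <- mbra_schedule()
  chambers <- tibble::tibble(
    chamber_id = sprintf("C%02d", seq_len(n_ctrl + n_trt)),
    treatment = rep(c("control", "trtA"), c(n_ctrl, n_trt)))
  tidyr::expand_grid(chambers, time_h = times) |>
    dplyr::mutate(value = exp(stats::rnorm(dplyr::n(), 0, sd)))
}
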