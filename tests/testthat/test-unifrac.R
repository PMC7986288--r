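test_that("unifrac closed-form examples hold on a two-leaf tree", {
  tree <- ape::read.tree(text = "(A:1,B:1):0;")
  a <- c(A = 4, B = 0)
  b <- c(A = 0, B = 9)
  expect_equal(unweighted_unifrac(a, a, tree), 0)
  expect_equal(unweighted_unifrac(a, b, tree), 1)
  expect_equal(weighted_unifrac(a, b, tree, normalized = FALSE), 2)
  expect_equal(weighted_unifrac(a, b, tree, normalized = TRUE), 1)
  expect_equal(weighted_unifrac(a, a * 10, tree), 0)  # composition identical
})

test_that("unifrac implementations match the brute-force oracle", {
  set.seed(20)
  for (i in 1:60) {
    tree <- random_tree(sample(3:8, 1))
    a <- random_counts(tree)
    b <- random_counts(tree)
    if (sum(a) == 0 || sum(b) == 0) next
    expect_equal(unweighted_unifrac(a, b, tree),
                 brute_unifrac(a, b, tree, weighted = FALSE),
                 tolerance = 1e-10)
    expect_equal(weighted_unifrac(a, b, tree, normalized = TRUE),
                 brute_unifrac(a, b, tree, weighted = TRUE,
                               normalized = TRUE),
                 tolerance = 1e-10)
    expect_equal(weighted_unifrac(a, b, tree, normalized = FALSE),
                 brute_unifrac(a, b, tree, weighted = TRUE,
                               normalized = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("unweighted unifrac agrees with picante", {
  skip_if_not_installed("picante")
  set.seed(5)
  for (i in 1:5) {
    tree <- random_tree(7)
    m <- rbind(a = random_counts(tree, p_zero = 0.4),
               b = random_counts(tree, p_zero = 0.4))
    if (any(rowSums(m) == 0)) next
    ours <- unweighted_unifrac(m["a", ], m["b", ], tree)
    theirs <- as.numeric(picante::unifrac(m, tree))
    expect_equal(ours, theirs, tolerance = 1e-10)
  }
})

test_that("metric axioms hold: symmetry, identity, triangle inequality", {
  set.seed(8)
  tree <- random_tree(8)
  xs <- replicate(3, random_counts(tree), simplify = FALSE)
  for (f in list(jaccard_distance,
                 function(a, b) unweighted_unifrac(a, b, tree))) {
    d12 <- f(xs[[1]], xs[[2]])
    d21 <- f(xs[[2]], xs[[1]])
    d13 <- f(xs[[1]], xs[[3]])
    d23 <- f(xs[[2]], xs[[3]])
    expect_equal(d12, d21)
    expect_equal(f(xs[[1]], xs[[1]]), 0)
    expect_lte(d13, d12 + d23 + 1e-12)
  }
})

test_that("weighted unifrac is invariant to total-count scaling", {
  set.seed(13)
  tree <- random_tree(6)
  a <- random_counts(tree) + 1
  b <- random_counts(tree) + 1
  expect_equal(weighted_unifrac(a, b, tree),
               weighted_unifrac(a * 7, b * 3, tree), tolerance = 1e-12)
})

test_that("features absent from the tree are reported by name", {
  tree <- ape::read.tree(text = "(A:1,B:1):0;")
  expect_error(unweighted_unifrac(c(A = 1, Z = 1), c(A = 1, Z = 0), tree),
               "Z")
  # absent but zero-count features are tolerated
  expect_equal(unweighted_unifrac(c(A = 1, Z = 0), c(A = 2, Z = 0), tree), 0)
})

test_that("unrooted trees are midpoint-rooted before unifrac", {
  skip_if_not_installed("phangorn")
  set.seed(3)
  tree <- ape::unroot(random_tree(6))
  expect_false(ape::is.rooted(tree))
  a <- random_counts(tree) + 1
  b <- random_counts(tree) + 1
  rooted <- phangorn::midpoint(tree)
  expect_equal(weighted_unifrac(a, b, tree),
               brute_unifrac(a, b, rooted, weighted = TRUE))
})

test_that("distance_matrix matches single-pair calls and is label-driven", {
  set.seed(31)
  tree <- random_tree(6)
  m <- do.call(rbind, lapply(1:4, function(i) random_counts(tree) + 1))
  rownames(m) <- paste0("s", 1:4)
  ft <- feature_table(m)
  for (metric in c("jaccard", "bray_curtis", "unweighted_unifrac",
                   "weighted_unifrac")) {
    d <- distance_matrix(ft, metric, tree = tree)
    expect_true(isSymmetric(unclass(d)))
    expect_equal(unname(diag(d)), rep(0, 4))
    fun <- switch(metric,
                  jaccard = jaccard_distance,
                  bray_curtis = bray_curtis_distance,
                  unweighted_unifrac = function(a, b)
                    unweighted_unifrac(a, b, tree),
                  weighted_unifrac = function(a, b)
                    weighted_unifrac(a, b, tree))
    expect_equal(d["s1", "s3"], fun(m["s1", ], m["s3", ]),
                 tolerance = 1e-12)
    # permuting sample order permutes entries consistently
    perm <- feature_table(m[c(3, 1, 4, 2), ])
    dp <- distance_matrix(perm, metric, tree = tree)
    expect_equal(dp[rownames(d), colnames(d)], unclass(d),
                 ignore_attr = TRUE)
  }
  # identical samples give a zero matrix
  trio <- m[c(1, 1, 1), ]
  rownames(trio) <- c("a", "b", "c")
  expect_true(all(distance_matrix(feature_table(trio), "jaccard") == 0))
})

test_that("pcoa recovers classical scaling solutions", {
  # zero distances: all coordinates zero
  z <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  p0 <- pcoa(z, n_axes = 2)
  expect_true(all(p0$coordinates[, -1] == 0))
  # collinear points: a single positive eigenvalue explaining everything
  d <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  expect_warning(p1 <- pcoa(d, n_axes = 2), "truncated")
  expect_equal(p1$prop_explained[1], 1)
  # euclidean-embeddable input is reproduced by recovered coordinates
  set.seed(4)
  x <- matrix(rnorm(10 * 3), 10, 3)
  de <- as.matrix(dist(x))
  pe <- pcoa(de, n_axes = 3)
  co <- as.matrix(pe$coordinates[, -1])
  expect_equal(as.matrix(dist(co)), de, ignore_attr = TRUE,
               tolerance = 1e-8)
})
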