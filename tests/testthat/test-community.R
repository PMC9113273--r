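# independent textbook CH computation via pairwise-distance identities:
# within-cluster dispersion of a set equals the mean of squared pairwise
# distances over cluster size; no centroid is ever formed explicitly.
ch_pairwise <- function(X, labels) {
  n <- nrow(X)
  labels <- canon(labels)
  k <- max(labels)
  d2 <- as.matrix(stats::dist(X))^2
  wss <- function(idx) if (length(idx) < 2) 0 else
    sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
  tot <- wss(seq_len(n))
  w <- sum(vapply(seq_len(k), function(g) wss(which(labels == g)),
                  numeric(1)))
  b <- tot - w
  (b / (k - 1)) / (w / (n - k))
}

test_that("Ward merges match a brute-force minimum-variance oracle", {
  for (seed in 1:10) {
    n <- 5 + (seed %% 6)
    d <- random_dynamic_distance(n, seed)
    expect_equal(tree_partitions(ward_tree(d, "rows")),
                 naive_ward_features(d))
    expect_equal(tree_partitions(ward_tree(d, "lw")),
                 naive_ward_lw(d))
  }
})

test_that("tree cuts hit the trivial extremes and planted bipartitions", {
  d <- random_dynamic_distance(8, seed = 21)
  tree <- ward_tree(d)
  expect_equal(cut_communities(tree, 8), 1:8)
  expect_equal(cut_communities(tree, 1), rep(1, 8))
  expect_error(cut_communities(tree, 0), "between")
  expect_error(cut_communities(tree, 9), "between")

  cc <- make_block_correlation(c(5, 5), 0.9, -0.2)
  labs <- cut_communities(ward_tree(dynamic_distance(cc)), 2)
  expect_equal(labs, attr(cc, "block_labels"))
})

test_that("a two-residue input yields a single merge", {
  d <- matrix(c(0, 1, 1, 0), 2)
  tree <- ward_tree(d)
  expect_equal(nrow(tree$merge), 1)
  expect_equal(cut_communities(tree, 2), 1:2)
})

test_that("the CH score matches an independent pairwise-identity computation", {
  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(rnorm(10 * 4), 10)
    labels <- sample(1:3, 10, replace = TRUE)
    while (length(unique(labels)) < 3) labels <- sample(1:3, 10, TRUE)
    expect_equal(ch_score(X, labels), ch_pairwise(X, labels),
                 tolerance = 1e-10)
  }
})

test_that("degenerate CH cases follow the sentinel conventions", {
  # two point-masses, perfectly separated: largest finite score
  X <- rbind(matrix(0, 3, 2), matrix(1, 3, 2))
  expect_equal(ch_score(X, c(1, 1, 1, 2, 2, 2)), .Machine$double.xmax)
  # all points identical: zero by convention
  expect_equal(ch_score(matrix(1, 6, 2), c(1, 1, 2, 2, 3, 3)), 0)
  expect_error(ch_score(X, rep(1, 6)), "undefined")
  expect_error(ch_score(X, 1:6), "undefined")
})

test_that("CH score is invariant under label permutation", {
  set.seed(33)
  X <- matrix(rnorm(30), 10)
  labels <- c(1, 2, 3, 1, 2, 3, 1, 2, 3, 1)
  perm <- c(3, 1, 2)
  expect_equal(ch_score(X, labels), ch_score(X, perm[labels]))
})

test_that("the sweep selects the planted two-block structure", {
  cc <- make_block_correlation(c(5, 5), 0.9, -0.2)
  res <- select_communities(dynamic_distance(cc), k_min = 2, k_max = 8)
  expect_equal(res$optimal_k, 2)
  expect_equal(res$membership, attr(cc, "block_labels"))
  expect_equal(res$ranked_all$k[1], res$optimal_k)
})

test_that("the optimal k is the CH argmax with ties to fewer communities", {
  d <- random_dynamic_distance(15, seed = 5)
  res <- select_communities(d, 2, 10)
  ch <- res$ch_by_k
  expect_true(all(ch[[as.character(res$optimal_k)]] >= unlist(ch)))
  expect_equal(res$optimal_k,
               as.integer(names(ch)[which.max(unlist(ch))]))
  expect_error(select_communities(d, 2, 15), "N - 1")
  expect_error(select_communities(d, 5, 3), "k_min")
})

test_that("ranked peaks are the strict local maxima of the CH curve", {
  d <- random_dynamic_distance(20, seed = 8)
  res <- select_communities(d, 2, 12)
  ch <- unlist(res$ch_by_k)
  ks <- as.integer(names(ch))
  for (r in seq_len(nrow(res$ranked_peaks))) {
    i <- match(res$ranked_peaks$k[r], ks)
    if (i > 1) expect_gt(ch[i], ch[i - 1])
    if (i < length(ks)) expect_gt(ch[i], ch[i + 1])
  }
  expect_true(res$optimal_k %in% res$ranked_peaks$k)
  expect_false(is.unsorted(rev(res$ranked_peaks$ch)))
})

test_that("cuts of one tree are nested: the k-cut refines the (k-1)-cut", {
  d <- random_dynamic_distance(18, seed = 13)
  tree <- ward_tree(d)
  for (k in 3:10) {
    fine <- cut_communities(tree, k)
    coarse <- cut_communities(tree, k - 1)
    # each fine cluster maps into exactly one coarse cluster
    expect_true(all(tapply(coarse, fine,
                           function(v) length(unique(v))) == 1))
  }
})
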