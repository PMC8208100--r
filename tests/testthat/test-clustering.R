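test_that("Ward tree matches the brute-force SSE-greedy oracle on 1-D points", {
  x <- matrix(c(0, 1, 10), ncol = 1)
  tree <- ward_linkage(x)
  oracle <- brute_force_ward(x)
  expect_equal(tree$height, oracle$height, tolerance = 1e-10)
  # first merge is {0, 1} at height 1 (their Euclidean distance)
  expect_equal(sort(tree$merge[1, ]), c(-2, -1))
  expect_equal(tree$height[1], 1)
  expect_equal(unname(canon_partition(cut_tree(tree, 2))),
               canon_partition(c(1, 1, 2)))
})

test_that("Ward tree equals the brute-force oracle on random instances", {
  set.seed(101)
  for (rep in 1:25) {
    n <- sample(4:8, 1)
    x <- matrix(rnorm(n * 3), n, 3)
    tree <- ward_linkage(x)
    oracle <- brute_force_ward(x)
    expect_equal(tree$height, oracle$height, tolerance = 1e-8)
    for (k in 2:(n - 1)) {
      expect_identical(canon_partition(cut_tree(tree, k)),
                       canon_partition(merge_partition(oracle$merge, n, k)))
    }
  }
  # duplicate rows merge at height zero
  tree0 <- ward_linkage(rbind(c(1, 1), c(1, 1), c(5, 5)))
  expect_equal(tree0$height[1], 0)
})

test_that("cut_tree covers the trivial cuts and rejects bad k", {
  x <- matrix(rnorm(12), 6, 2)
  tree <- ward_linkage(x)
  expect_equal(unname(cut_tree(tree, 1)), rep(1L, 6))
  expect_equal(sort(unname(cut_tree(tree, 6))), 1:6)
  expect_error(cut_tree(tree, 0), "out of range")
  expect_error(cut_tree(tree, 7), "out of range")
})

test_that("min-max normalisation maps columns to [0,1], is idempotent, flags constants", {
  m <- cbind(a = c(2, 4, 6), b = c(0.25, 0.5, 1))
  nm <- minmax_normalize(m)
  expect_equal(unname(nm[, "a"]), c(0, 0.5, 1))
  expect_equal(range(nm), c(0, 1))
  expect_equal(minmax_normalize(nm), nm)   # idempotent
  expect_warning(cm <- minmax_normalize(cbind(c(3, 3, 3))), "constant")
  expect_equal(unname(cm[, 1]), rep(0.5, 3))
})

test_that("silhouette k-selection recovers planted structure and falls back sanely", {
  syn <- synthesize_feature_table(k = 2, n_per_cluster = 8, separation = 10,
                                  n_features = 5, seed = 7)
  tree <- ward_linkage(syn$table$values)
  res <- silhouette_select_k(syn$table$values, tree)
  expect_equal(res$chosen_k, 2L)
  expect_true(all(unlist(res$silhouettes) >= -1 &
                    unlist(res$silhouettes) <= 1))

  syn4 <- synthesize_feature_table(k = 4, n_per_cluster = 8, separation = 10,
                                   n_features = 8, seed = 11)
  tree4 <- ward_linkage(syn4$table$values)
  res4 <- silhouette_select_k(syn4$table$values, tree4)
  expect_equal(res4$chosen_k, 4L)
  expect_equal(mclust::adjustedRandIndex(cut_tree(tree4, 4),
                                         syn4$ground_truth$labels), 1)

  # single blob: no multi-cluster support reported
  one <- synthesize_feature_table(k = 1, n_per_cluster = 20, n_features = 4,
                                  seed = 3)
  tree1 <- ward_linkage(one$table$values)
  res1 <- silhouette_select_k(one$table$values, tree1)
  expect_true(res1$chosen_k == 1L ||
                (!is.null(res1$flag) && res1$flag == "no negative found"))
  expect_false(is.null(res1$flag))
})

test_that("chosen k is invariant to row permutation", {
  syn <- synthesize_feature_table(k = 3, n_per_cluster = 7, separation = 8,
                                  n_features = 6, seed = 5)
  x <- syn$table$values
  res <- silhouette_select_k(x, ward_linkage(x))
  set.seed(9)
  perm <- sample(nrow(x))
  xp <- x[perm, ]
  resp <- silhouette_select_k(xp, ward_linkage(xp))
  expect_equal(resp$chosen_k, res$chosen_k)
})

test_that("Newick export uses midpoint branch lengths and survives a parser", {
  two <- ward_linkage(matrix(c(0, 1), ncol = 1))
  nk <- export_dendrogram_newick(two, labels = c("A", "B"))
  expect_equal(nk, "(A:0.5,B:0.5);")
  x <- matrix(c(0, 1, 10), ncol = 1)
  tree <- ward_linkage(x)
  nk3 <- export_dendrogram_newick(tree, labels = c("a", "b", "c"))
  ph <- ape::read.tree(text = nk3)
  expect_equal(sort(ph$tip.label), c("a", "b", "c"))
  # leaf depths all equal root height / 2 (ultrametric midpoint convention)
  depths <- ape::node.depth.edgelength(ph)[1:3]
  expect_equal(depths, rep(max(tree$height) / 2, 3), tolerance = 1e-8)
  # metacharacters get quoted
  nkq <- export_dendrogram_newick(two, labels = c("A:1", "B"))
  expect_match(nkq, "'A:1'", fixed = TRUE)
})

test_that("cluster purity is the majority identity fraction", {
  pur <- cluster_purity(c(rep(1, 40), rep(2, 30)),
                        c(rep("SPBN", 40), rep("SPBN", 17), rep("UN", 13)))
  expect_equal(pur$purity_pct[pur$cluster == "1"], 100)
  expect_equal(round(pur$purity_pct[pur$cluster == "2"], 1), 56.7)
  expect_error(cluster_purity(1:3, c("a", "b")), "aligned")
})

test_that("feature-table assembly imputes medians and errors on absent features", {
  recs <- list(c1 = c(f1 = 1, f2 = 10), c2 = c(f1 = 3, f2 = NA),
               c3 = c(f1 = 5, f2 = 30))
  tab <- assemble_feature_table(recs, features = c("f1", "f2"))
  expect_equal(unname(tab$values["c2", "f2"]), 20)   # median of 10, 30
  expect_true(tab$mask["c2", "f2"])
  expect_false(any(is.na(tab$values)))
  full <- assemble_feature_table(recs["c1"], features = c("f1", "f2"))
  expect_false(any(full$mask))
  expect_error(assemble_feature_table(recs, features = c("f1", "nope")),
               "absent")
})
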