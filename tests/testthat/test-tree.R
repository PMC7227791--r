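test_that("entropy matches closed forms in bits", {
  expect_identical(entropy(c(2, 2)), 1)
  expect_identical(entropy(c(4, 0)), 0)
  # -(3/4)log2(3/4) - (1/4)log2(1/4)
  expect_equal(entropy(c(3, 1)), 0.811278124459133, tolerance = 1e-12)
  expect_equal(entropy(c(1, 1, 1, 1)), 2)
  expect_error(entropy(c(0, 0)), "zero")
  expect_error(entropy(c(-1, 2)), "negative")
})

test_that("information gain matches direct entropy arithmetic", {
  p <- c("A", "A", "B", "B")
  expect_equal(information_gain(p, c("A", "A"), c("B", "B")), 1)
  expect_equal(information_gain(p, c("A", "B"), c("A", "B")), 0)
  # 1 - (3/4) * H(2,1)
  expect_equal(information_gain(p, c("A", "A", "B"), "B"),
               0.311278124459133, tolerance = 1e-12)
  expect_error(information_gain(p, p, character(0)), "empty")
  expect_error(information_gain(p, c("A", "A"), c("A", "B")), "partition")
})

test_that("a separable single feature yields one exact midpoint split", {
  x <- named_matrix(c(1, 2, 8, 9), nrow = 1)
  tree <- grow_tree(x, factor(c("A", "A", "B", "B")))
  expect_false(tree$root$leaf)
  expect_identical(tree$root$feature, "f1")
  expect_identical(tree$root$threshold, 5)
  expect_equal(tree$root$info_gain, 1)
  expect_true(tree$root$left$leaf && tree$root$right$leaf)
  expect_identical(tree$root$left$class, "A")
  expect_identical(tree$root$right$class, "B")
})

test_that("degenerate training data gives a depth-0 majority leaf", {
  # all-identical feature values: no split has positive gain
  x <- named_matrix(rep(3, 4), nrow = 1)
  t1 <- grow_tree(x, factor(c("A", "A", "A", "B")))
  expect_true(t1$root$leaf)
  expect_identical(t1$root$class, "A")
  # majority tie resolves to the first class level
  t2 <- grow_tree(x, factor(c("A", "A", "B", "B")))
  expect_true(t2$root$leaf)
  expect_identical(t2$root$class, "A")
  # already-pure labels
  t3 <- grow_tree(named_matrix(1:4, nrow = 1), factor(rep("B", 4)))
  expect_true(t3$root$leaf)
  expect_identical(t3$root$class, "B")
})

test_that("gain ties break by earlier feature, then smaller threshold", {
  # two identical separable features: the first row must win the root
  x <- matrix(c(1, 2, 8, 9, 1, 2, 8, 9), nrow = 2, byrow = TRUE,
              dimnames = list(c("early", "late"), paste0("s", 1:4)))
  tree <- grow_tree(x[c("early", "late"), ], factor(c("A", "A", "B", "B")))
  expect_identical(tree$root$feature, "early")
  tree2 <- grow_tree(x[c("late", "early"), ], factor(c("A", "A", "B", "B")))
  expect_identical(tree2$root$feature, "late")
})

test_that("root gain equals the brute-force maximum over all midpoints", {
  for (rep in 1:8) {
    set.seed(rep)
    x <- named_matrix(stats::rnorm(4 * 10), nrow = 4)
    y <- factor(sample(c("A", "B"), 10, replace = TRUE,
                       prob = c(0.6, 0.4)))
    if (nlevels(droplevels(y)) < 2) next
    tree <- grow_tree(x, y)
    oracle <- brute_force_root_ig(x, as.character(y))
    if (tree$root$leaf) {
      expect_lte(oracle, 1e-12)
    } else {
      expect_equal(tree$root$info_gain, oracle, tolerance = 1e-12)
    }
  }
})

test_that("an unpruned tree is perfect on separable training data", {
  set.seed(7)
  x <- named_matrix(stats::rnorm(3 * 12), nrow = 3)
  y <- factor(sample(c("A", "B"), 12, replace = TRUE))
  tree <- grow_tree(x, y, min_leaf = 1)
  expect_identical(predict(tree, x), as.character(y))
})

test_that("balanced accuracy is the mean of per-class recalls", {
  train <- named_matrix(c(1, 2, 8, 9), nrow = 1)
  tree <- grow_tree(train, factor(c("A", "A", "B", "B")))
  # class A: 3/4 correct; class B: 1/2 correct -> 0.625
  test_x <- named_matrix(c(1, 2, 3, 8, 1, 9), nrow = 1,
                         sample_ids = paste0("t", 1:6))
  test_y <- c("A", "A", "A", "A", "B", "B")
  expect_equal(weighted_accuracy(tree, test_x, test_y), 0.625)
  # all correct
  expect_equal(weighted_accuracy(tree, named_matrix(c(1, 9), nrow = 1),
                                 c("A", "B")), 1)
  # constant-prediction tree on a two-class test set scores 0.5
  leaf <- grow_tree(named_matrix(rep(1, 4), nrow = 1),
                    factor(c("A", "A", "A", "B")))
  expect_equal(weighted_accuracy(leaf, named_matrix(1:4, nrow = 1),
                                 c("A", "A", "B", "B")), 0.5)
  # a class absent from the test set is an error
  expect_error(weighted_accuracy(tree, named_matrix(c(1, 2), nrow = 1),
                                 c("A", "A")), "absent")
})

test_that("per-tree feature contributions follow the coverage weighting", {
  # hand-checkable two-level tree; see the arithmetic inline
  x <- matrix(c(1, 2, 3, 4, 11, 12, 13, 14,
                1, 9, 2, 8, 3, 4, 5, 7), nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), paste0("s", 1:8)))
  y <- factor(c("A", "A", "A", "A", "B", "B", "B", "A"))
  tree <- grow_tree(x, y)
  h_parent <- -(5 / 8) * log2(5 / 8) - (3 / 8) * log2(3 / 8)
  h31 <- -(3 / 4) * log2(3 / 4) - (1 / 4) * log2(1 / 4)
  ig_root <- h_parent - 0.5 * h31      # left child pure
  expect_identical(tree$root$feature, "g1")
  expect_equal(tree$root$info_gain, ig_root, tolerance = 1e-12)
  # right child (s5..s8, BBBA): g1 and g2 tie at full purification; g1 wins
  expect_identical(tree$root$right$feature, "g1")
  expect_equal(tree$root$right$info_gain, h31, tolerance = 1e-12)
  contrib <- mcfsel:::tree_feature_contributions(tree, v = 1)
  expect_equal(contrib[["g1"]], ig_root * 1 + h31 * (4 / 8),
               tolerance = 1e-12)
  expect_false("g2" %in% names(contrib))
  # v = 0 collapses the coverage weight: plain summed gain
  contrib0 <- mcfsel:::tree_feature_contributions(tree, v = 0)
  expect_equal(contrib0[["g1"]], ig_root + h31, tolerance = 1e-12)
})
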