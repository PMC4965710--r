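make_xy <- function(seed = 1, n = 100, p = 12, signal = 4) {
  set.seed(seed)
  X <- matrix(rpois(n * p, 0.6), n, p)
  y <- as.integer(runif(n) < 0.35)
  X[, signal] <- X[, signal] + 3L * y   # strong separator on column `signal`
  storage.mode(X) <- "double"
  list(X = X, y = y)
}

test_that("gini impurity matches the two-class formula", {
  expect_equal(gini_impurity(c(5, 5)), 0.5)
  expect_equal(gini_impurity(c(10, 0)), 0)
  expect_equal(gini_impurity(c(3, 1)), 0.375)
  expect_error(gini_impurity(c(0, 0)), class = "trf_argument_error")
})

test_that("candidate sampling respects the probability support", {
  for (s in 1:200)
    expect_identical(sample_candidates(c(0, 1, 0), 1, seed = s), 2L)
  expect_identical(sample_candidates(rep(0.2, 5), 5, seed = 3), 1:5)
  # zero-probability column never drawn, others always both drawn
  draws <- lapply(1:500, function(s)
    sample_candidates(c(0.5, 0.5, 0), 2, seed = s))
  expect_true(all(vapply(draws, identical, TRUE, y = 1:2)))
  # more candidates requested than nonzero columns: all nonzero returned
  expect_identical(sample_candidates(c(0, 0.4, 0, 0.6), 3, seed = 1),
                   c(2L, 4L))
  expect_error(sample_candidates(c(0, 0), 1),
               class = "trf_degenerate_weights_error")
})

test_that("candidate sampling frequencies follow successive-draw weights", {
  # P(first draw = 3) = 0.6; P(3 in a 2-draw without replacement) can be
  # enumerated: 1 - P(both draws avoid 3) = 1 - 0.  With weights
  # (0.1, 0.3, 0.6) and mtry 1, long-run frequencies approach the weights.
  hits <- table(factor(vapply(1:4000, function(s)
    sample_candidates(c(0.1, 0.3, 0.6), 1, seed = s), 1L), levels = 1:3))
  freq <- as.numeric(hits) / 4000
  expect_equal(freq, c(0.1, 0.3, 0.6), tolerance = 0.12)
})

test_that("single trees stop on purity and find perfect separators", {
  d <- make_xy()
  # constant labels -> single leaf voting that class everywhere
  t0 <- build_tree(d$X, rep(1L, 100), params = forest_params(seed = 1))
  expect_equal(length(t0$trees[[1]]$feature), 1)
  expect_equal(predict(t0, d$X), rep(1L, 100))
  expect_error(fit_forest(d$X, rep(1L, 100)), class = "trf_class_error")

  # a perfectly separating feature with all sampling mass on it gives a
  # depth-1 tree with two pure leaves
  X <- matrix(c(1, 2, 3, 10, 11, 12, rnorm(6)), 6, 2)
  y <- c(0, 0, 0, 1, 1, 1)
  tr <- build_tree(X, y, probs = c(1, 0), params = forest_params(seed = 2))
  nodes <- tr$trees[[1]]
  expect_equal(length(nodes$feature), 3)       # root + 2 leaves
  expect_equal(nodes$feature[1], 0L)           # 0-based column index
  expect_equal(nodes$threshold[1], 6.5)        # midpoint of 3 and 10
  expect_equal(predict(tr, X), y)
})

test_that("split ties break towards the lowest column then lowest threshold", {
  # two identical columns: identical impurity decreases at every threshold
  x <- c(0, 0, 1, 1, 2, 2)
  X <- cbind(x, x)
  y <- c(0, 0, 0, 1, 1, 1)
  # mtry = 2 so both (identical) columns compete; thresholds 0.5 and 1.5
  # tie on the impurity decrease within each column as well
  tr <- build_tree(X, y, probs = c(0.5, 0.5),
                   params = forest_params(mtry = 2, seed = 1))
  expect_equal(tr$trees[[1]]$feature[1], 0L)
  expect_equal(tr$trees[[1]]$threshold[1], 0.5)
})

test_that("forests are deterministic and conserve votes", {
  d <- make_xy(2)
  p1 <- forest_params(n_trees = 60, seed = 9)
  f1 <- fit_forest(d$X, d$y, params = p1)
  f2 <- fit_forest(d$X, d$y, params = p1)
  expect_identical(f1$trees, f2$trees)
  expect_identical(gini_importance(f1), gini_importance(f2))

  votes <- predict(f1, d$X, type = "votes")
  expect_true(all(votes %in% 0:1))
  expect_equal(ncol(votes), 60)  # positive + negative votes = n_trees
  score <- predict(f1, d$X, type = "prob")
  expect_equal(score, rowMeans(votes))
  expect_equal(predict(f1, d$X), as.integer(score > 0.5))
})

test_that("prediction ties vote negative", {
  # hand-built 2-tree forest disagreeing on every sample: score 0.5 -> 0
  stump <- function(flip) list(
    feature = c(0L, -1L, -1L), threshold = c(0.5, 0, 0),
    left = c(1L, -1L, -1L), right = c(2L, -1L, -1L),
    count0 = if (flip) c(1L, 0L, 1L) else c(1L, 1L, 0L),
    count1 = if (flip) c(1L, 1L, 0L) else c(1L, 0L, 1L))
  forest <- structure(list(trees = list(stump(FALSE), stump(TRUE)),
                           importance_raw = c(1, 0), params = forest_params(),
                           mtry = 1L, manifest = c("a", "b"), n_features = 2L,
                           probs = NULL), class = "temporal_rf")
  X <- cbind(a = c(0, 1), b = c(5, 5))
  expect_equal(predict(forest, X, type = "prob"), c(0.5, 0.5))
  expect_equal(predict(forest, X), c(0L, 0L))
})

test_that("gini importance concentrates on the separating feature", {
  X <- matrix(c(1, 2, 3, 10, 11, 12), 6, 1)
  X <- cbind(X, 0)
  y <- c(0, 0, 0, 1, 1, 1)
  f <- fit_forest(X, y, params = forest_params(n_trees = 50, seed = 4))
  imp <- gini_importance(f)
  expect_gte(unname(imp[1]), 0.99)
  expect_equal(unname(imp[2]), 0, tolerance = 0.01)
  expect_equal(sum(imp), 1)
})

test_that("tree importance equals the hand-computed impurity decreases", {
  # 6 samples, no bootstrap, all sampling mass on feature 1 (values
  # 0,0,1,1,2,2 against labels 0,0,0,1,1,1); feature 2 is constant.
  # Root splits 0.5 and 1.5 tie on the decrease, so the tree takes 0.5
  # (lowest threshold) and then splits the right child at 1.5.
  X <- cbind(c(0, 0, 1, 1, 2, 2), c(7, 7, 7, 7, 7, 7))
  y <- c(0, 0, 0, 1, 1, 1)
  tr <- build_tree(X, y, probs = c(1, 0), params = forest_params(seed = 1))
  nodes <- tr$trees[[1]]
  g <- function(cnt) 1 - sum((cnt / sum(cnt))^2)
  delta_05 <- (6 / 6) * (g(c(3, 3)) - (2 / 6) * g(c(2, 0)) - (4 / 6) * g(c(1, 3)))
  delta_15 <- (6 / 6) * (g(c(3, 3)) - (4 / 6) * g(c(3, 1)) - (2 / 6) * g(c(0, 2)))
  expect_equal(delta_05, delta_15)  # fixture sanity: the root splits tie
  expect_equal(nodes$threshold[1], 0.5)
  # right child (values 1,1,2,2; labels 0,1,1,1) then splits at 1.5; its
  # (1,1) grandchild has no distinct values left and stays an impure leaf
  delta_child <- (4 / 6) * (g(c(1, 3)) - (2 / 4) * g(c(1, 1)) - (2 / 4) * g(c(0, 2)))
  expect_equal(tr$importance_raw[1], delta_05 + delta_child, tolerance = 1e-12)
  expect_equal(tr$importance_raw[2], 0)
})

test_that("zero-probability features are excluded from every tree", {
  d <- make_xy(5, n = 80, p = 20, signal = 3)
  probs <- rep(1, 20)
  probs[c(1, 7, 13, 20)] <- 0
  f <- fit_forest(d$X, d$y, probs = probs / sum(probs),
                  params = forest_params(n_trees = 200, seed = 6))
  used <- tempoRF:::forest_features_used(f)
  expect_length(intersect(used, c(1, 7, 13, 20)), 0)
})

test_that("error decomposition matches an enumerable 3-tree fixture", {
  # indicator features; tree i votes negative exactly on sample i
  mk_tree <- function(i) list(
    feature = c(as.integer(i - 1), -1L, -1L), threshold = c(0.5, 0, 0),
    left = c(1L, -1L, -1L), right = c(2L, -1L, -1L),
    count0 = c(1L, 0L, 1L), count1 = c(2L, 2L, 0L))
  forest <- structure(list(trees = lapply(1:3, mk_tree),
                           importance_raw = rep(1 / 3, 3),
                           params = forest_params(), mtry = 1L,
                           manifest = c("a", "b", "c"), n_features = 3L,
                           probs = NULL), class = "temporal_rf")
  X <- diag(3)
  colnames(X) <- c("a", "b", "c")
  y <- c(1, 1, 1)
  dec <- error_decomposition(forest, X, y)
  expect_equal(dec$avg_tree_error, 1 / 3)
  expect_equal(dec$ensemble_error, 0)
  expect_equal(dec$diversity, 1 / 3)

  # all trees identical -> diversity 0; perfect forest -> all zero
  d <- make_xy(3)
  f <- fit_forest(d$X, d$y, params = forest_params(n_trees = 40, seed = 2))
  dec2 <- error_decomposition(f, d$X, d$y)
  expect_equal(dec2$diversity, dec2$avg_tree_error - dec2$ensemble_error)
  expect_error(error_decomposition(f, d$X[0, , drop = FALSE], integer(0)),
               class = "trf_argument_error")
})

test_that("forests round-trip through the text serialization", {
  d <- make_xy(7, n = 60, p = 8)
  f <- fit_forest(d$X, d$y, params = forest_params(n_trees = 15, seed = 3))
  path <- withr::local_tempfile(fileext = ".txt")
  write_forest(f, path)
  back <- read_forest(path)
  expect_identical(back$trees, f$trees)
  expect_equal(predict(back, d$X, "prob"), predict(f, d$X, "prob"))
})

test_that("column-manifest mismatches are rejected at prediction", {
  d <- make_xy(8)
  f <- fit_forest(d$X, d$y, params = forest_params(n_trees = 5, seed = 1))
  expect_error(predict(f, d$X[, 1:5]), class = "trf_manifest_error")
})
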