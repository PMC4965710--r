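#' Forest hyper-parameters
#'
#' @param n_trees number of trees (default 500).
#' @param mtry candidate features sampled per node; default
#'   `floor(sqrt(p))`, at least 1, resolved at fit time.
#' @param min_node_size nodes at or below this size are not split
#'   (default 1: trees are fully grown).
#' @param bootstrap draw a size-n bootstrap replicate per tree (default on).
#' @param seed integer seed; each tree derives an independent RNG substream
#'   from `(seed, tree index)`, so fits are reproducible regardless of
#'   execution order.
#' @return A list of class `forest_params`.
#' @export
forest_params <- function(n_trees = 500L, mtry = NULL, min_node_size = 1L,
                          bootstrap = TRUE, seed = 1L) {
  if (n_trees < 1) trf_stop("argument", "n_trees must be >= 1")
  if (!is.null(mtry) && mtry < 1) trf_stop("argument", "mtry must be >= 1")
  structure(list(n_trees = as.integer(n_trees),
                 mtry = if (is.null(mtry)) NULL else as.integer(mtry),
                 min_node_size = as.integer(min_node_size),
                 bootstrap = isTRUE(bootstrap),
                 seed = as.integer(seed)),
            class = "forest_params")
}

#' Gini impurity of a two-class node
#'
#' `1 - sum_k (n_k / n)^2` for class counts `n_k`; 0 for a pure node and
#' 0.5 for a perfectly mixed one.
#'
#' @param class_counts non-negative pair of class counts, not both zero.
#' @return Impurity in `[0, 0.5]`.
#' @export
gini_impurity <- function(class_counts) {
  if (length(class_counts) != 2 || any(class_counts < 0) ||
      sum(class_counts) == 0)
    trf_stop("argument",
             "class_counts must be two non-negative counts, not both zero")
  n <- sum(class_counts)
  1 - sum((class_counts / n)^2)
}

#' Sample candidate features by weighted draws without replacement
#'
#' Draws `min(mtry, #nonzero)` distinct column indices by successive draws
#' without replacement, each draw proportional to the remaining
#' probabilities; zero-probability columns are never returned. This is the
#' per-node candidate sampler of the weighted (enriched) forest.
#'
#' @param probs non-negative weights over the columns (need not sum to 1).
#' @param mtry number of candidates requested.
#' @param seed integer seed making the draw deterministic.
#' @return Sorted integer vector of distinct 1-based column indices.
#' @export
sample_candidates <- function(probs, mtry, seed = 1L) {
  if (mtry < 1) trf_stop("argument", "mtry must be >= 1")
  if (any(probs < 0)) trf_stop("argument", "probabilities must be >= 0")
  if (all(probs == 0)) trf_stop("degenerate_weights",
                                "all candidate probabilities are zero")
  rf_sample_candidates_cpp(as.numeric(probs), as.integer(mtry),
                           as.double(seed))
}

resolve_features <- function(X) {
  if (inherits(X, "binned_matrix") || inherits(X, "aggregated_matrix")) {
    list(mat = as.matrix(X$X),
         manifest = colnames(X$X) %||% character(0))
  } else {
    mat <- as.matrix(X)
    list(mat = mat, manifest = colnames(mat) %||%
           paste0("V", seq_len(ncol(mat))))
  }
}

#' Fit a weighted-sampling random forest
#'
#' Grows `n_trees` Gini-split CART trees, each (by default) on an
#' independent bootstrap replicate. At every node a candidate feature set is
#' drawn by [sample_candidates()] with the supplied probabilities — uniform
#' probabilities recover the standard random forest — and the
#' (feature, threshold) pair maximizing the Gini impurity decrease is taken,
#' thresholds being midpoints between consecutive distinct values. Ties are
#' broken towards the lowest column, then the lowest threshold. Nodes stop
#' at purity, at `min_node_size`, or when no candidate yields a positive
#' decrease.
#'
#' @param X feature matrix (numeric matrix, `Matrix` sparse matrix,
#'   `binned_matrix` or `aggregated_matrix`); rows are patients.
#' @param y binary labels (0 = negative, 1 = ADE-positive).
#' @param probs per-column sampling weights; `NULL` (default) for uniform.
#' @param params a [forest_params()].
#' @return An object of class `temporal_rf`.
#' @export
fit_forest <- function(X, y, probs = NULL, params = forest_params()) {
  feat <- resolve_features(X)
  y <- as.integer(y)
  if (length(y) != nrow(feat$mat))
    trf_stop("argument", "length(y) must equal nrow(X)")
  if (length(unique(y)) < 2)
    trf_stop("class", "both classes must be present in y")
  p <- ncol(feat$mat)
  if (is.null(probs)) probs <- rep(1 / p, p)
  if (length(probs) != p)
    trf_stop("argument", "probs must have one entry per feature column")
  if (any(probs < 0)) trf_stop("argument", "probabilities must be >= 0")
  if (all(probs == 0))
    trf_stop("degenerate_weights", "all candidate probabilities are zero")
  mtry <- params$mtry %||% max(1L, floor(sqrt(p)))
  fit <- rf_fit_cpp(feat$mat, y, as.numeric(probs), params$n_trees,
                    as.integer(mtry), params$min_node_size,
                    params$bootstrap, as.double(params$seed))
  structure(list(trees = fit$trees,
                 importance_raw = as.numeric(fit$importance),
                 params = params, mtry = mtry,
                 manifest = feat$manifest, n_features = p,
                 probs = as.numeric(probs)),
            class = "temporal_rf")
}

#' Build a single decision tree
#'
#' A single Gini-split tree on the full sample (no bootstrap), using the
#' same node-level candidate sampling as [fit_forest()].
#'
#' @inheritParams fit_forest
#' @param seed RNG seed for the candidate draws.
#' @return A `temporal_rf` with one tree.
#' @export
build_tree <- function(X, y, probs = NULL, params = forest_params(),
                       seed = params$seed) {
  params$n_trees <- 1L
  params$bootstrap <- FALSE
  params$seed <- as.integer(seed)
  y <- as.integer(y)
  if (length(unique(y)) < 2) {
    # pure sample: the tree is a single leaf holding the class counts
    feat <- resolve_features(X)
    leaf <- list(feature = -1L, threshold = 0, left = -1L, right = -1L,
                 count0 = sum(y == 0L), count1 = sum(y == 1L))
    return(structure(list(trees = list(leaf),
                          importance_raw = rep(0, ncol(feat$mat)),
                          params = params,
                          mtry = params$mtry %||%
                            max(1L, floor(sqrt(ncol(feat$mat)))),
                          manifest = feat$manifest,
                          n_features = ncol(feat$mat), probs = probs),
                     class = "temporal_rf"))
  }
  fit_forest(X, y, probs, params)
}

check_manifest <- function(forest, feat) {
  if (ncol(feat$mat) != forest$n_features ||
      !identical(as.character(feat$manifest),
                 as.character(forest$manifest)))
    trf_stop("manifest", "feature columns do not match the fitted manifest")
}

forest_votes <- function(forest, X) {
  feat <- resolve_features(X)
  check_manifest(forest, feat)
  rf_predict_votes_cpp(forest$trees, feat$mat)
}

#' Predict from a fitted forest
#'
#' Each tree routes a sample to a leaf and votes for the leaf's majority
#' class (leaf tie votes negative). The score is the fraction of positive
#' votes; the label is positive iff the score exceeds 0.5 (an exact 0.5
#' tie is negative).
#'
#' @param object a `temporal_rf`.
#' @param newdata feature matrix matching the fitted column manifest.
#' @param type `"class"` for 0/1 labels, `"prob"` for positive-vote
#'   fractions, `"votes"` for the full samples x trees 0/1 vote matrix.
#' @param ... unused.
#' @return Vector of labels or scores, or a vote matrix.
#' @export
predict.temporal_rf <- function(object, newdata,
                                type = c("class", "prob", "votes"), ...) {
  type <- match.arg(type)
  votes <- forest_votes(object, newdata)
  if (type == "votes") return(votes)
  score <- rowMeans(votes)
  if (type == "prob") score else as.integer(score > 0.5)
}

#' Gini variable importance of a fitted forest
#'
#' For every internal node splitting on feature `f`, the impurity decrease
#' `(n_node/n) * (G_node - (n_L/n_node) G_L - (n_R/n_node) G_R)` is
#' accredited to `f`; per-feature totals are averaged over trees and, by
#' default, normalized to sum to 1. A zero importance means the feature is
#' useless as a splitter or was never selected.
#'
#' @param forest a fitted `temporal_rf`.
#' @param normalize divide by the total so importances sum to 1 (the
#'   all-zero vector is left untouched).
#' @return Named numeric vector over the column manifest.
#' @export
gini_importance <- function(forest, normalize = TRUE) {
  imp <- forest$importance_raw
  if (normalize && sum(imp) > 0) imp <- imp / sum(imp)
  names(imp) <- forest$manifest
  imp
}

#' Tree-versus-ensemble error decomposition
#'
#' Measures ensemble diversity as the gap between the mean 0-1 error of the
#' individual trees and the 0-1 error of the majority-voted ensemble on a
#' labelled set; the voted error can be no larger than the average tree
#' error only in expectation, but the gap (`diversity`) is the quantity of
#' interest.
#'
#' @param forest a fitted `temporal_rf`.
#' @param X labelled evaluation features.
#' @param y binary labels.
#' @return List with `avg_tree_error`, `ensemble_error`, `diversity`
#'   (= avg_tree_error - ensemble_error).
#' @export
error_decomposition <- function(forest, X, y) {
  y <- as.integer(y)
  if (length(y) == 0) trf_stop("argument", "empty evaluation set")
  votes <- forest_votes(forest, X)
  if (nrow(votes) != length(y))
    trf_stop("argument", "length(y) must equal nrow(X)")
  avg_tree <- mean(colMeans(votes != y))
  ens <- mean(as.integer(rowMeans(votes) > 0.5) != y)
  list(avg_tree_error = avg_tree, ensemble_error = ens,
       diversity = avg_tree - ens)
}

#' Write a fitted forest to a self-describing text file
#'
#' Plain-text serialization: a parameter header, the column manifest, then a
#' pre-order node table per tree. Thresholds are written with 17 significant
#' digits so [read_forest()] round-trips exactly.
#'
#' @param forest a `temporal_rf`.
#' @param path output path.
#' @export
write_forest <- function(forest, path) {
  con <- file(path, "w")
  on.exit(close(con))
  p <- forest$params
  writeLines(c("tempoRF-forest v1",
               sprintf("n_trees=%d mtry=%d min_node_size=%d bootstrap=%d seed=%d n_features=%d",
                       p$n_trees, forest$mtry, p$min_node_size,
                       as.integer(p$bootstrap), p$seed, forest$n_features),
               paste0("manifest=", paste(forest$manifest, collapse = ","))),
             con)
  for (t in seq_along(forest$trees)) {
    tr <- forest$trees[[t]]
    writeLines(sprintf("tree %d nodes %d", t, length(tr$feature)), con)
    writeLines(sprintf("%d %.17g %d %d %d %d", tr$feature, tr$threshold,
                       tr$left, tr$right, tr$count0, tr$count1), con)
  }
  invisible(path)
}

#' Read a forest written by [write_forest()]
#' @param path input path.
#' @return A `temporal_rf` (with empty importance: importances are a fit
#'   product, not part of the serialized model).
#' @export
read_forest <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "tempoRF-forest v1")
    trf_stop("format", "not a tempoRF forest file")
  hdr <- as.integer(regmatches(lines[2],
                               gregexpr("-?[0-9]+", lines[2]))[[1]])
  manifest <- strsplit(sub("^manifest=", "", lines[3]), ",", fixed = TRUE)[[1]]
  params <- forest_params(n_trees = hdr[1], mtry = hdr[2],
                          min_node_size = hdr[3], bootstrap = hdr[4] == 1L,
                          seed = hdr[5])
  trees <- vector("list", hdr[1])
  ln <- 4L
  for (t in seq_len(hdr[1])) {
    n_nodes <- as.integer(sub(".*nodes ", "", lines[ln]))
    ln <- ln + 1L
    rows <- do.call(rbind, strsplit(lines[ln:(ln + n_nodes - 1L)], " ",
                                    fixed = TRUE))
    trees[[t]] <- list(feature = as.integer(rows[, 1]),
                       threshold = as.numeric(rows[, 2]),
                       left = as.integer(rows[, 3]),
                       right = as.integer(rows[, 4]),
                       count0 = as.integer(rows[, 5]),
                       count1 = as.integer(rows[, 6]))
    ln <- ln + n_nodes
  }
  structure(list(trees = trees,
                 importance_raw = rep(0, hdr[6]),
                 params = params, mtry = hdr[2], manifest = manifest,
                 n_features = hdr[6], probs = NULL),
            class = "temporal_rf")
}

#' @export
print.temporal_rf <- function(x, ...) {
  cat(sprintf("Weighted-sampling random forest: %d trees, %d features, mtry %d\n",
              length(x$trees), x$n_features, x$mtry))
  invisible(x)
}

# internal: features used in any internal node of any tree (1-based)
forest_features_used <- function(forest) {
  sort(unique(unlist(lapply(forest$trees, function(tr)
    tr$feature[tr$feature >= 0])))) + 1L
}
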