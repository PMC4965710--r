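STRATEGIES <- c("PWA", "LWA", "PWS", "LWS")

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Stratified k-fold cross-validation plan
#'
#' Per iteration, patients are shuffled within class by a seeded RNG and
#' dealt round-robin into the folds (the dealing pointer continues across
#' classes, so fold sizes are as equal as possible and per-fold class counts
#' deviate from perfect stratification by at most one).
#'
#' @param labels binary label vector.
#' @param k number of folds (default 5).
#' @param iterations number of independent repetitions (default 2).
#' @param seed integer seed; the plan is deterministic given the seed.
#' @return A list of class `fold_plan` with `k`, `iterations`, `seed` and
#'   `assignments`: one integer fold-id vector (aligned with `labels`) per
#'   iteration.
#' @export
stratified_cv <- function(labels, k = 5L, iterations = 2L, seed = 1L) {
  labels <- as.integer(labels)
  k <- as.integer(k)
  if (any(table(labels) < k))
    trf_stop("stratification",
             "each class must have at least k = %d members", k)
  assignments <- with_seed(seed, {
    lapply(seq_len(iterations), function(it) {
      fold <- integer(length(labels))
      ptr <- 0L
      for (cls in c(1L, 0L)) {
        ids <- which(labels == cls)
        ids <- ids[sample.int(length(ids))]
        fold[ids] <- (ptr + seq_along(ids) - 1L) %% k + 1L
        ptr <- (ptr + length(ids)) %% k
      }
      fold
    })
  })
  structure(list(k = k, iterations = as.integer(iterations),
                 seed = as.integer(seed), assignments = assignments),
            class = "fold_plan")
}

#' Classification metrics: accuracy, AUC and AUPRC
#'
#' Accuracy (as a percentage) uses the voting threshold rule: positive iff
#' the score exceeds 0.5, an exact tie counting as negative. AUC is the
#' probability that a random positive is ranked above a random negative
#' (ties between a positive and a negative score count 1/2). AUPRC is the
#' average-precision formulation: the mean of the precision at the rank of
#' each positive in descending-score order, ties broken by stable input
#' order.
#'
#' @param scores numeric scores in `[0, 1]` (positive-vote fractions).
#' @param labels binary labels; both classes must be present.
#' @return List with `accuracy` (percent), `auc`, `auprc`.
#' @export
compute_metrics <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels))
    trf_stop("argument", "scores and labels must have equal length")
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0 || n_neg == 0)
    trf_stop("metric", "both classes must be present")
  pred <- as.integer(scores > 0.5)
  accuracy <- 100 * mean(pred == labels)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  ord <- order(-scores)  # stable: input order preserved within ties
  hits <- cumsum(labels[ord] == 1L)
  prec_at_pos <- (hits / seq_along(hits))[labels[ord] == 1L]
  list(accuracy = accuracy, auc = auc, auprc = mean(prec_at_pos))
}

#' Run one temporal-weighting strategy through cross-validation
#'
#' The four pipelines compared by the package:
#' \describe{
#'   \item{PWA}{pre-assigned weighted aggregation — reciprocal exact-day
#'     weights summed per code, uniform-sampling forest;}
#'   \item{LWA}{learned weighted aggregation — per-fold weight learning on
#'     the training binned matrix, granularity aggregation, max-scaling,
#'     weighted sums per code, uniform-sampling forest;}
#'   \item{PWS}{pre-assigned weighted sampling — binned features, per-window
#'     reciprocal weights as candidate-sampling probabilities;}
#'   \item{LWS}{learned weighted sampling — per-fold learned weights as
#'     candidate-sampling probabilities over the binned features.}
#' }
#' Weights for the learned strategies are always learned inside the
#' training fold, never on held-out patients. Each held-out fold is scored
#' with [compute_metrics()] and [error_decomposition()].
#'
#' @param strategy one of `"PWA"`, `"LWA"`, `"PWS"`, `"LWS"`.
#' @param events an [event_table()].
#' @param cohort a [cohort_table()].
#' @param grid a [window_grid()].
#' @param params a [forest_params()].
#' @param plan a [stratified_cv()] plan over `cohort$label`.
#' @param granularity weight granularity for LWA/LWS (`"all"`, `"type"`,
#'   `"time"`); ignored for the pre-assigned strategies.
#' @param floor smoothing floor for sampling probabilities (default 0).
#' @return A data.frame with one row per (iteration, fold): strategy,
#'   granularity, iteration, fold, accuracy, auc, auprc, avg_tree_error,
#'   ensemble_error, diversity.
#' @export
run_strategy <- function(strategy, events, cohort, grid = window_grid(),
                         params = forest_params(), plan, granularity = "all",
                         floor = 0) {
  if (!strategy %in% STRATEGIES)
    trf_stop("argument", "unknown strategy '%s' (expected %s)", strategy,
             paste(STRATEGIES, collapse = "/"))
  if (!granularity %in% WEIGHT_LEVELS)
    trf_stop("argument", "unknown granularity '%s'", granularity)
  y <- cohort$label

  binned <- NULL
  Xbin <- NULL
  if (strategy %in% c("LWA", "PWS", "LWS")) {
    binned <- bin_events(events, cohort, grid)
    Xbin <- as.matrix(binned$X)
  }
  Xagg_pre <- if (strategy == "PWA") aggregate_preassigned(events, cohort)$X
  probs_pws <- if (strategy == "PWS")
    to_sampling_probs(preassigned_window_weights(grid), binned$manifest)

  rows <- list()
  for (it in seq_len(plan$iterations)) {
    fold_id <- plan$assignments[[it]]
    for (f in seq_len(plan$k)) {
      test <- which(fold_id == f)
      train <- which(fold_id != f)
      if (length(unique(y[test])) < 2 || length(unique(y[train])) < 2)
        trf_stop("stratification",
                 "fold %d of iteration %d is single-class", f, it)
      fit_seed <- params$seed + 1000L * it + f
      fp <- params
      fp$seed <- fit_seed

      if (strategy %in% c("LWA", "LWS")) {
        wl_params <- params
        wl_params$seed <- fit_seed + 500000L
        sub <- binned
        sub$X <- binned$X[train, , drop = FALSE]
        sub$patients <- binned$patients[train]
        learned <- learn_event_weights(sub, y[train], wl_params)
        learned <- aggregate_weights(learned, granularity, binned$manifest)
      }

      if (strategy == "PWA") {
        forest <- fit_forest(Xagg_pre[train, , drop = FALSE], y[train],
                             params = fp)
        Xte <- Xagg_pre[test, , drop = FALSE]
      } else if (strategy == "LWA") {
        agg <- aggregate_learned(binned, scale_for_aggregation(learned))
        forest <- fit_forest(agg$X[train, , drop = FALSE], y[train],
                             params = fp)
        Xte <- agg$X[test, , drop = FALSE]
      } else if (strategy == "PWS") {
        forest <- fit_forest(Xbin[train, , drop = FALSE], y[train],
                             probs = probs_pws, params = fp)
        Xte <- Xbin[test, , drop = FALSE]
      } else {
        probs <- to_sampling_probs(learned, binned$manifest, floor = floor)
        forest <- fit_forest(Xbin[train, , drop = FALSE], y[train],
                             probs = probs, params = fp)
        Xte <- Xbin[test, , drop = FALSE]
      }

      score <- predict(forest, Xte, type = "prob")
      met <- compute_metrics(score, y[test])
      dec <- error_decomposition(forest, Xte, y[test])
      rows[[length(rows) + 1L]] <- data.frame(
        strategy = strategy,
        granularity = if (strategy %in% c("LWA", "LWS")) granularity else "n/a",
        iteration = it, fold = f,
        accuracy = met$accuracy, auc = met$auc, auprc = met$auprc,
        avg_tree_error = dec$avg_tree_error,
        ensemble_error = dec$ensemble_error,
        diversity = dec$diversity,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Exact / approximate two-sided Wilcoxon signed-rank test
#'
#' Zero differences are dropped; tied absolute differences are mid-ranked.
#' For up to 25 remaining pairs the p-value is computed from the exact null
#' distribution of the positive rank sum over all sign assignments
#' (conditioned on the observed tie pattern); beyond that a normal
#' approximation with tie correction and no continuity correction is used.
#' If all differences are zero, p = 1 by convention.
#'
#' @param a,b paired numeric vectors of equal length.
#' @return List with `statistic` (positive rank sum `W+`), `n_used`
#'   (non-zero pairs) and `p_value`.
#' @export
wilcoxon_signed_rank <- function(a, b) {
  if (length(a) != length(b) || length(a) < 1)
    trf_stop("argument", "a and b must be paired vectors of equal length >= 1")
  d <- a - b
  d <- d[d != 0]
  if (length(d) == 0)
    return(list(statistic = 0, n_used = 0L, p_value = 1))
  n <- length(d)
  r <- rank(abs(d), ties.method = "average")
  w_pos <- sum(r[d > 0])
  if (n <= 25) {
    # exact distribution by convolution over doubled ranks (integers even
    # with .5 mid-ranks)
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    dist <- c(1, rep(0, total))  # dist[w+1] = #assignments with 2*W+ = w
    for (ri in r2) {
      shifted <- c(rep(0, ri), dist[seq_len(total + 1 - ri)])
      dist <- dist + shifted
    }
    w2 <- as.integer(round(2 * w_pos))
    p_le <- sum(dist[seq_len(w2 + 1)]) / 2^n
    p_ge <- sum(dist[(w2 + 1):(total + 1)]) / 2^n
    p <- min(1, 2 * min(p_le, p_ge))
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w_pos - mu) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
  }
  list(statistic = w_pos, n_used = n, p_value = p)
}

# within-row ranks, higher value = better = rank 1
rank_matrix <- function(results) {
  t(apply(results, 1, function(row) rank(-row, ties.method = "average")))
}

#' Friedman test over datasets x methods
#'
#' Within each row (dataset), methods are ranked so the highest metric gets
#' rank 1 (ties mid-ranked). The statistic is
#' `chi2_F = 12 N / (m (m + 1)) * sum_j (Rbar_j - (m + 1) / 2)^2`,
#' referred to the chi-square distribution with `m - 1` degrees of freedom.
#'
#' @param results numeric matrix, N datasets (rows) x m methods (columns),
#'   N >= 2 and m >= 2.
#' @return List with `statistic`, `p_value`, `avg_ranks`.
#' @export
friedman_test <- function(results) {
  results <- as.matrix(results)
  n <- nrow(results)
  m <- ncol(results)
  if (n < 2 || m < 2)
    trf_stop("argument", "need at least 2 datasets and 2 methods")
  rbar <- colMeans(rank_matrix(results))
  stat <- 12 * n / (m * (m + 1)) * sum((rbar - (m + 1) / 2)^2)
  p <- if (stat == 0) 1 else pchisq(stat, df = m - 1, lower.tail = FALSE)
  list(statistic = stat, p_value = p, avg_ranks = rbar)
}

# Bergmann-Hommel adjustment for the 3 pairwise hypotheses among 3 methods.
# Exhaustive sets of simultaneously-true hypotheses: each singleton and the
# full set of 3 (if any two pairwise nulls hold, so does the third), so
# APV_i = max(p_i, 3 * min(p)) with monotonicity in the raw p enforced.
bh_adjust_3 <- function(p_raw) {
  adj <- pmax(p_raw, 3 * min(p_raw))
  ord <- order(p_raw)
  adj[ord] <- cummax(adj[ord])
  pmin(adj, 1)
}

#' Bergmann-Hommel post-hoc pairwise comparisons after a Friedman test
#'
#' For exactly three methods, computes the pairwise z statistics from the
#' average-rank differences,
#' `z = (Rbar_i - Rbar_j) / sqrt(m (m + 1) / (6 N))`, two-sided normal raw
#' p-values, and adjusts them by the Bergmann-Hommel exhaustive-set
#' procedure (which for three hypotheses multiplies the smallest raw p by
#' 3). Adjusted p-values dominate the raw ones and are monotone in them.
#'
#' @param results numeric matrix, N datasets x 3 methods.
#' @return data.frame with columns `method_i`, `method_j`, `z`, `p_raw`,
#'   `p_adj`, plus attribute `avg_ranks`.
#' @export
bergmann_hommel_posthoc <- function(results) {
  results <- as.matrix(results)
  if (ncol(results) != 3)
    trf_stop("argument",
             "the exhaustive-set procedure is implemented for exactly 3 methods")
  n <- nrow(results)
  if (n < 2) trf_stop("argument", "need at least 2 datasets")
  m <- 3
  rbar <- colMeans(rank_matrix(results))
  nm <- colnames(results) %||% paste0("m", 1:3)
  pairs <- cbind(c(1, 1, 2), c(2, 3, 3))
  se <- sqrt(m * (m + 1) / (6 * n))
  z <- (rbar[pairs[, 1]] - rbar[pairs[, 2]]) / se
  p_raw <- 2 * pnorm(-abs(z))
  out <- data.frame(method_i = nm[pairs[, 1]], method_j = nm[pairs[, 2]],
                    z = z, p_raw = p_raw, p_adj = bh_adjust_3(p_raw),
                    stringsAsFactors = FALSE)
  attr(out, "avg_ranks") <- setNames(rbar, nm)
  out
}

#' Benchmark strategies (or granularities) across synthetic datasets
#'
#' Runs each requested strategy on every dataset through stratified
#' cross-validation, summarizes the per-fold metrics per dataset, and
#' attaches the statistical comparison: a two-sided Wilcoxon signed-rank
#' p-value per metric when exactly two strategies are compared, or a
#' Friedman test plus Bergmann-Hommel post-hoc when one learned strategy is
#' run at the three granularity levels. Also reports the
#' average-tree-versus-ensemble error decomposition per strategy.
#'
#' @param datasets list of `list(events =, cohort =)` pairs (>= 2 for any
#'   statistical test).
#' @param strategies character vector of strategy ids.
#' @param granularities granularity levels; if more than one, `strategies`
#'   must be a single learned strategy and the comparison runs across
#'   levels.
#' @param grid a [window_grid()].
#' @param params a [forest_params()].
#' @param k,iterations cross-validation setup per dataset.
#' @param seed base seed for the fold plans.
#' @param out_dir optional directory for the CSV report files.
#' @return A list of class `trf_benchmark` with `fold_results`, `summary`,
#'   `diversity`, `stats`.
#' @export
run_benchmark <- function(datasets, strategies = c("PWS", "LWS"),
                          granularities = "all", grid = window_grid(),
                          params = forest_params(), k = 5L, iterations = 2L,
                          seed = 1L, out_dir = NULL) {
  if (length(granularities) > 1 && length(strategies) != 1)
    trf_stop("argument",
             "granularity comparison requires a single learned strategy")
  arms <- if (length(granularities) > 1)
    data.frame(strategy = strategies, granularity = granularities,
               stringsAsFactors = FALSE)
  else
    data.frame(strategy = strategies,
               granularity = granularities[1], stringsAsFactors = FALSE)
  arms$id <- if (length(granularities) > 1)
    paste0(arms$strategy, ":", arms$granularity) else arms$strategy
  if (length(datasets) < 2)
    trf_stop("reporting",
             "statistical comparison requires at least 2 datasets")

  fold_rows <- list()
  for (d in seq_along(datasets)) {
    ds <- datasets[[d]]
    plan <- stratified_cv(ds$cohort$label, k = k, iterations = iterations,
                          seed = seed + d)
    for (a in seq_len(nrow(arms))) {
      res <- run_strategy(arms$strategy[a], ds$events, ds$cohort, grid,
                          params, plan, granularity = arms$granularity[a])
      res$arm <- arms$id[a]
      res$dataset <- d
      fold_rows[[length(fold_rows) + 1L]] <- res
    }
  }
  fold_results <- do.call(rbind, fold_rows)

  metrics <- c("accuracy", "auc", "auprc")
  summary_df <- do.call(rbind, lapply(split(
    fold_results, fold_results[c("dataset", "arm")]), function(g) {
      cbind(data.frame(dataset = g$dataset[1], arm = g$arm[1],
                       stringsAsFactors = FALSE),
            as.data.frame(as.list(colMeans(
              g[c(metrics, "avg_tree_error", "ensemble_error",
                  "diversity")]))))
    }))
  rownames(summary_df) <- NULL
  summary_df <- summary_df[order(summary_df$dataset,
                                 match(summary_df$arm, arms$id)), ]

  diversity <- do.call(rbind, lapply(split(summary_df, summary_df$arm),
    function(g) data.frame(arm = g$arm[1],
                           avg_tree_error = mean(g$avg_tree_error),
                           ensemble_error = mean(g$ensemble_error),
                           diversity = mean(g$diversity),
                           stringsAsFactors = FALSE)))
  rownames(diversity) <- NULL

  stats <- NULL
  wide <- function(metric) {
    m <- sapply(arms$id, function(a)
      summary_df[summary_df$arm == a, metric])
    matrix(m, ncol = nrow(arms), dimnames = list(NULL, arms$id))
  }
  if (nrow(arms) == 2) {
    stats <- do.call(rbind, lapply(metrics, function(metric) {
      w <- wide(metric)
      t <- wilcoxon_signed_rank(w[, 1], w[, 2])
      data.frame(metric = metric, test = "wilcoxon",
                 comparison = paste(arms$id, collapse = " vs "),
                 statistic = t$statistic, p_value = t$p_value,
                 stringsAsFactors = FALSE)
    }))
  } else if (nrow(arms) == 3) {
    stats <- do.call(rbind, lapply(metrics, function(metric) {
      w <- wide(metric)
      fr <- friedman_test(w)
      ph <- bergmann_hommel_posthoc(w)
      rbind(
        data.frame(metric = metric, test = "friedman", comparison = "all",
                   statistic = fr$statistic, p_value = fr$p_value,
                   stringsAsFactors = FALSE),
        data.frame(metric = metric, test = "bergmann-hommel",
                   comparison = paste(ph$method_i, "vs", ph$method_j),
                   statistic = ph$z, p_value = ph$p_adj,
                   stringsAsFactors = FALSE))
    }))
  }

  out <- structure(list(fold_results = fold_results, summary = summary_df,
                        diversity = diversity, stats = stats, arms = arms),
                   class = "trf_benchmark")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(fold_results, file.path(out_dir, "fold_results.csv"),
              row.names = FALSE)
    write.csv(summary_df, file.path(out_dir, "dataset_summary.csv"),
              row.names = FALSE)
    write.csv(diversity, file.path(out_dir, "diversity.csv"),
              row.names = FALSE)
    if (!is.null(stats))
      write.csv(stats, file.path(out_dir, "statistics.csv"),
                row.names = FALSE)
  }
  out
}

#' @export
print.trf_benchmark <- function(x, ...) {
  cat("Temporal-weighting benchmark over", max(x$summary$dataset),
      "datasets\n\nPer-arm means:\n")
  agg <- do.call(rbind, lapply(split(x$summary, x$summary$arm), function(g)
    data.frame(arm = g$arm[1], accuracy = mean(g$accuracy),
               auc = mean(g$auc), auprc = mean(g$auprc))))
  rownames(agg) <- NULL
  print(agg, digits = 4)
  cat("\nTree vs ensemble error:\n")
  print(x$diversity, digits = 4)
  if (!is.null(x$stats)) {
    cat("\nStatistical comparison:\n")
    print(x$stats, digits = 4)
  }
  invisible(x)
}
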