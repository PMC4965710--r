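test_that("stratified folds deal classes round-robin", {
  labels <- c(rep(1, 3), rep(0, 7))
  plan <- stratified_cv(labels, k = 3, iterations = 2, seed = 1)
  for (fold in plan$assignments) {
    sizes <- table(factor(fold, levels = 1:3))
    expect_true(max(sizes) - min(sizes) <= 1)   # folds as equal as possible
    pos_per_fold <- table(factor(fold[labels == 1], levels = 1:3))
    expect_true(all(pos_per_fold == 1))         # perfect stratification
  }
  labels2 <- c(rep(1, 5), rep(0, 5))
  plan2 <- stratified_cv(labels2, k = 5, iterations = 1, seed = 2)
  sizes <- table(factor(plan2$assignments[[1]], levels = 1:5))
  expect_true(all(sizes == 2))  # 10 samples dealt into 5 folds of 2
  expect_identical(stratified_cv(labels, 3, 2, seed = 7),
                   stratified_cv(labels, 3, 2, seed = 7))
  expect_error(stratified_cv(c(rep(1, 4), rep(0, 20)), k = 5),
               class = "trf_stratification_error")
})

test_that("metrics match their definitions on frozen examples", {
  # two pos (0.9, 0.4), one neg (0.5): one concordant pair, one discordant
  m <- compute_metrics(c(0.9, 0.4, 0.5), c(1, 1, 0))
  expect_equal(m$auc, 0.5)
  # ranked (pos, neg, pos): precision 1 at rank 1, 2/3 at rank 3
  m2 <- compute_metrics(c(0.9, 0.8, 0.7), c(1, 0, 1))
  expect_equal(m2$auprc, (1 + 2 / 3) / 2)
  # perfect separation
  m3 <- compute_metrics(c(0.9, 0.8, 0.1), c(1, 1, 0))
  expect_equal(m3$accuracy, 100)
  expect_equal(m3$auc, 1)
  expect_equal(m3$auprc, 1)
  # exact 0.5 scores count as negative predictions
  m4 <- compute_metrics(c(0.5, 0.6), c(0, 1))
  expect_equal(m4$accuracy, 100)
  expect_error(compute_metrics(c(0.1, 0.2), c(1, 1)),
               class = "trf_metric_error")
})

test_that("AUC equals the brute-force pairwise oracle", {
  set.seed(42)
  for (i in 1:60) {
    n <- sample(4:20, 1)
    labels <- c(1, 0, rbinom(n - 2, 1, 0.5))
    scores <- round(runif(n), sample(c(1, 2), 1))  # coarse: forces ties
    expect_equal(compute_metrics(scores, labels)$auc,
                 oracle_auc(scores, labels), tolerance = 1e-12)
  }
})

test_that("Wilcoxon exact path agrees with full sign enumeration", {
  w <- wilcoxon_signed_rank(c(1, 2, 3), c(0, 0, 0))
  expect_equal(w$p_value, 0.25)  # W+ = 6 is one of 8 equally likely; doubled
  expect_equal(wilcoxon_signed_rank(1:4, 1:4)$p_value, 1)
  set.seed(7)
  for (i in 1:40) {
    n <- sample(3:10, 1)
    a <- round(rnorm(n), 1)
    b <- round(rnorm(n), 1)
    got <- wilcoxon_signed_rank(a, b)
    expect_equal(got$p_value, oracle_wilcoxon(a, b), tolerance = 1e-12)
    # symmetry of the two-sided p
    expect_equal(got$p_value, wilcoxon_signed_rank(b, a)$p_value)
  }
  # tie-free large-n normal path tracks stats::wilcox.test
  set.seed(8)
  a <- rnorm(40)
  b <- rnorm(40)
  ref <- stats::wilcox.test(a, b, paired = TRUE, exact = FALSE,
                            correct = FALSE)
  expect_equal(wilcoxon_signed_rank(a, b)$p_value, ref$p.value,
               tolerance = 1e-10)
})

test_that("Friedman statistic matches the closed form", {
  m <- matrix(rep(c(3, 2, 1), 4), nrow = 4, byrow = TRUE)
  fr <- friedman_test(m)
  expect_equal(fr$statistic, 8)
  expect_equal(fr$p_value, pchisq(8, 2, lower.tail = FALSE))
  expect_equal(unname(fr$avg_ranks), c(1, 2, 3))

  flat <- matrix(1, 4, 3)
  fr0 <- friedman_test(flat)
  expect_equal(fr0$statistic, 0)
  expect_equal(fr0$p_value, 1)

  # column permutation permutes the average ranks identically
  m2 <- matrix(rnorm(15), 5, 3)
  perm <- c(3, 1, 2)
  expect_equal(unname(friedman_test(m2[, perm])$avg_ranks),
               unname(friedman_test(m2)$avg_ranks[perm]))
  # tie-free case agrees with stats::friedman.test
  ref <- stats::friedman.test(m2)
  expect_equal(friedman_test(m2)$statistic, unname(ref$statistic))
})

test_that("Bergmann-Hommel adjustment follows the 3-hypothesis exhaustive sets", {
  # raw (0.001, 0.5, 0.6): smallest is scaled by the full set of size 3
  expect_equal(tempoRF:::bh_adjust_3(c(0.001, 0.5, 0.6)),
               c(0.003, 0.5, 0.6))
  expect_equal(tempoRF:::bh_adjust_3(c(0.2, 0.3, 0.25)),
               c(0.6, 0.6, 0.6))  # 3*min dominates, monotone capped

  # equal average ranks -> all adjusted p = 1
  flat <- matrix(c(1, 2, 3, 3, 1, 2, 2, 3, 1), 3, 3, byrow = TRUE)
  ph <- bergmann_hommel_posthoc(flat)
  expect_equal(ph$p_adj, rep(1, 3))

  set.seed(5)
  for (i in 1:20) {
    m <- matrix(rnorm(24), 8, 3)
    ph <- bergmann_hommel_posthoc(m)
    expect_true(all(ph$p_adj >= ph$p_raw - 1e-12))
    expect_true(all(ph$p_adj <= 1))
    # monotone in raw p
    ord <- order(ph$p_raw)
    expect_true(all(diff(ph$p_adj[ord]) >= -1e-12))
  }
  expect_error(bergmann_hommel_posthoc(matrix(rnorm(8), 2, 4)),
               class = "trf_argument_error")
})

test_that("run_strategy emits one row per fold and rejects bad inputs", {
  sim <- generate_cohort(small_config(seed = 51))
  plan <- stratified_cv(sim$cohort$label, k = 5, iterations = 2, seed = 2)
  params <- forest_params(n_trees = 30, seed = 3)
  res <- run_strategy("LWS", sim$events, sim$cohort, params = params,
                      plan = plan)
  expect_equal(nrow(res), 10)  # 5 folds x 2 iterations
  expect_true(all(res$accuracy >= 0 & res$accuracy <= 100))
  expect_true(all(res$auc >= 0 & res$auc <= 1))
  expect_equal(res$diversity, res$avg_tree_error - res$ensemble_error)
  expect_error(run_strategy("XWS", sim$events, sim$cohort,
                            params = params, plan = plan),
               class = "trf_argument_error")
})

test_that("with all events on day 0, aggregation and sampling see the same signal", {
  # one code whose day-0 count separates the classes: PWA's aggregated value
  # equals the raw count (weight 1 per occurrence) and PWS's only varying
  # features live in window 1, so both strategies classify perfectly
  set.seed(6)
  n <- 60
  label <- rep(c(1, 0), each = n / 2)
  counts <- ifelse(label == 1, 3 + rpois(n, 1), rpois(n, 0.3))
  pat <- sprintf("p%02d", 1:n)
  keep <- counts > 0
  events <- event_table(rep(pat[keep], counts[keep]), "MARK", "drug",
                        rep(0, sum(counts[keep])))
  cohort <- cohort_table(pat, label)
  plan <- stratified_cv(label, k = 3, iterations = 1, seed = 4)
  params <- forest_params(n_trees = 50, seed = 5)
  r_pwa <- run_strategy("PWA", events, cohort, params = params, plan = plan)
  r_pws <- run_strategy("PWS", events, cohort, params = params, plan = plan)
  expect_equal(mean(r_pwa$auc), mean(r_pws$auc), tolerance = 0.05)
  expect_gt(mean(r_pwa$auc), 0.95)
  expect_gt(mean(r_pws$auc), 0.95)
})

test_that("benchmark reports have the promised shape", {
  datasets <- lapply(61:63, function(s) {
    sim <- generate_cohort(small_config(seed = s))
    list(events = sim$events, cohort = sim$cohort)
  })
  params <- forest_params(n_trees = 25, seed = 1)
  out_dir <- withr::local_tempdir()
  bench <- run_benchmark(datasets, strategies = c("PWS", "LWS"),
                         params = params, k = 3, iterations = 1, seed = 9,
                         out_dir = out_dir)
  expect_equal(nrow(bench$fold_results), 3 * 2 * 3)  # datasets x arms x folds
  expect_equal(nrow(bench$summary), 6)
  expect_equal(nrow(bench$stats), 3)  # one Wilcoxon row per metric
  expect_true(all(bench$stats$test == "wilcoxon"))
  expect_true(file.exists(file.path(out_dir, "statistics.csv")))

  gran <- run_benchmark(datasets[1:2], strategies = "LWS",
                        granularities = c("all", "type", "time"),
                        params = params, k = 3, iterations = 1, seed = 9)
  expect_equal(sort(unique(gran$stats$test)),
               c("bergmann-hommel", "friedman"))
  # one Friedman + 3 pairwise rows per metric
  expect_equal(nrow(gran$stats), 3 * 4)

  expect_error(run_benchmark(datasets[1], strategies = c("PWS", "LWS"),
                             params = params),
               class = "trf_reporting_error")
})
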