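# Independent oracles used to freeze expected values: deliberately naive
# implementations, kept separate from the package's own code paths.

# AUC by exhaustive pairwise comparison of every (positive, negative) pair
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (sp in pos) for (sn in neg)
    total <- total + if (sp > sn) 1 else if (sp == sn) 0.5 else 0
  total / (length(pos) * length(neg))
}

# exact two-sided Wilcoxon signed-rank p by full 2^n sign enumeration
oracle_wilcoxon <- function(a, b) {
  d <- (a - b)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  ws <- vapply(seq_len(2^n) - 1L, function(mask) {
    signs <- bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0
    sum(r[signs])
  }, numeric(1))
  p_le <- mean(ws <= w_obs)
  p_ge <- mean(ws >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# per-patient-per-code-per-window recount straight from the event rows
oracle_bin_count <- function(events, patient, code, window, grid) {
  sum(events$patient == patient & events$code == code &
        assign_window(events$day_offset, grid) == window)
}

# small event/cohort fixture: 4 patients, hand-placed events
tiny_tables <- function() {
  events <- event_table(
    patient = c("p1", "p1", "p1", "p2", "p2", "p3"),
    code = c("DIA1", "DIA1", "DRG1", "DIA1", "MEA1", "DRG1"),
    type = c("diagnosis", "diagnosis", "drug", "diagnosis", "measurement",
             "drug"),
    day_offset = c(1, 1, 5, 8, 0, 90))
  cohort <- cohort_table(c("p1", "p2", "p3", "p4"), c(1, 1, 0, 0))
  list(events = events, cohort = cohort)
}

# small synthetic config for fast unit tests (not the study-scale default)
small_config <- function(seed, n_patients = 120, n_informative = 5,
                         effect_multiplier = 6,
                         n_codes = c(diagnosis = 30, drug = 20,
                                     measurement = 10), ...) {
  simulation_config(n_patients = n_patients, n_codes_per_type = n_codes,
                    n_informative = n_informative,
                    effect_multiplier = effect_multiplier, seed = seed, ...)
}

random_weight_table <- function(seed, level = "all",
                                normalization = "raw_importance") {
  set.seed(seed)
  key <- switch(level,
                all = sprintf("C%03d", 1:8),
                type = rep(c("diagnosis", "drug"), 4),
                time = rep("*", 8))
  window <- switch(level, all = sample(1:12, 8, TRUE),
                   type = rep(1:4, each = 2), time = sample(1:12, 8))
  w <- round(runif(8), 6)
  if (normalization == "probability") w <- w / sum(w)
  if (level == "type") {
    keep <- !duplicated(paste(key, window))
    key <- key[keep]; window <- window[keep]; w <- w[keep]
  }
  weight_table(key, window, w, level = level, normalization = normalization)
}
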