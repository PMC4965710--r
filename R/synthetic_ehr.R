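#' Configuration for the synthetic longitudinal cohort generator
#'
#' The generator emulates the qualitative structure of the ADE detection
#' cohorts the method targets: thousands of sparse count features over
#' diagnosis / drug / measurement codes, a 90-day history horizon, class
#' imbalance, and a small fraction of informative (code, window) pairs whose
#' occurrence rate is elevated among ADE-positive patients.
#'
#' Per patient and code, occurrence counts are drawn independently per time
#' window from a Poisson process whose expected count is
#' `baseline_rate * window_width / (horizon + 1)`, multiplied by
#' `effect_multiplier` when the patient is positive and the (code, window)
#' pair is informative; occurrence days are placed uniformly within the
#' window. Defaults plant the signal in the multi-day windows (8-12), where
#' baseline occurrence counts are large enough to carry signal at this
#' cohort size.
#'
#' @param n_patients cohort size (default 600).
#' @param n_codes_per_type named integer vector over
#'   `diagnosis`/`drug`/`measurement` (default 600/500/400).
#' @param horizon history horizon in days (default 90).
#' @param positive_fraction fraction of ADE-positive patients (default 0.3).
#' @param n_informative number of informative (code, window) pairs
#'   (default 20).
#' @param effect_multiplier rate ratio of informative pairs in positives
#'   versus negatives (> 1 plants signal; default 3).
#' @param baseline_rate expected occurrences of a code per patient over the
#'   whole horizon (default 0.5, giving the >95 % zero-cell sparsity typical
#'   of EHR count features).
#' @param informative_window_profile window indices eligible to carry
#'   signal (default 8:12).
#' @param grid a [window_grid()]; its horizon must equal `horizon`.
#' @param seed integer seed; generation is fully reproducible.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_patients = 600L,
                              n_codes_per_type = c(diagnosis = 600L,
                                                   drug = 500L,
                                                   measurement = 400L),
                              horizon = 90L,
                              positive_fraction = 0.3,
                              n_informative = 20L,
                              effect_multiplier = 3,
                              baseline_rate = 0.5,
                              informative_window_profile = 8:12,
                              grid = window_grid(),
                              seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              n_codes_per_type = n_codes_per_type,
              horizon = as.integer(horizon),
              positive_fraction = positive_fraction,
              n_informative = as.integer(n_informative),
              effect_multiplier = effect_multiplier,
              baseline_rate = baseline_rate,
              informative_window_profile = as.integer(informative_window_profile),
              grid = grid, seed = as.integer(seed))
  if (is.null(names(cfg$n_codes_per_type)) ||
      !all(names(cfg$n_codes_per_type) %in% EVENT_TYPES))
    trf_stop("config", "n_codes_per_type must be named by event type")
  if (grid$horizon != cfg$horizon)
    trf_stop("config", "grid horizon (%d) != horizon (%d)",
             grid$horizon, cfg$horizon)
  if (cfg$positive_fraction <= 0 || cfg$positive_fraction >= 1)
    trf_stop("config", "positive_fraction must lie in (0, 1)")
  n_pos <- round(cfg$n_patients * cfg$positive_fraction)
  if (n_pos < 2 || cfg$n_patients - n_pos < 2)
    trf_stop("config", "positive_fraction must leave >= 2 patients per class")
  if (cfg$effect_multiplier < 1)
    trf_stop("config", "effect_multiplier must be >= 1")
  if (cfg$baseline_rate < 0)
    trf_stop("config", "baseline_rate must be >= 0")
  if (any(cfg$informative_window_profile < 1 |
            cfg$informative_window_profile > grid$n_windows))
    trf_stop("config", "informative_window_profile outside the grid windows")
  total_codes <- sum(cfg$n_codes_per_type)
  if (cfg$n_informative >
        total_codes * length(cfg$informative_window_profile))
    trf_stop("config",
             "n_informative exceeds codes x informative windows (%d)",
             total_codes * length(cfg$informative_window_profile))
  structure(cfg, class = "simulation_config")
}

window_days <- function(grid) {
  lo <- c(0L, grid$boundaries[-grid$n_windows] + 1L)
  hi <- grid$boundaries
  data.frame(window = seq_len(grid$n_windows), lo = lo, hi = hi,
             width = hi - lo + 1L)
}

code_universe <- function(cfg) {
  prefix <- c(diagnosis = "DIA", drug = "DRG", measurement = "MEA")
  out <- lapply(EVENT_TYPES, function(tp) {
    k <- cfg$n_codes_per_type[[tp]] %||% 0L
    if (k == 0) return(NULL)
    data.frame(code = sprintf("%s%04d", prefix[[tp]], seq_len(k)),
               type = tp, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Generate a synthetic cohort with planted temporal signal
#'
#' @param config a [simulation_config()].
#' @return A list with elements `events` (an [event_table()]), `cohort`
#'   (a [cohort_table()]) and `truth` (class `planted_truth`: data.frame of
#'   informative `code`/`window` pairs plus the effect multiplier).
#' @export
generate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  grid <- config$grid
  wd <- window_days(grid)
  codes <- code_universe(config)
  n <- config$n_patients
  patients <- sprintf("P%05d", seq_len(n))
  n_pos <- round(n * config$positive_fraction)
  label <- c(rep(1L, n_pos), rep(0L, n - n_pos))

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  # planted informative (code, window) pairs
  pool <- expand.grid(code_i = seq_len(nrow(codes)),
                      window = config$informative_window_profile)
  pick <- sample.int(nrow(pool), config$n_informative)
  truth <- data.frame(code = codes$code[pool$code_i[pick]],
                      window = as.integer(pool$window[pick]),
                      stringsAsFactors = FALSE)
  truth <- truth[order(truth$code, truth$window), , drop = FALSE]
  rownames(truth) <- NULL

  # Poisson counts per (patient, code, window), generated window by window
  recs <- vector("list", grid$n_windows)
  share <- wd$width / (config$horizon + 1)
  for (w in seq_len(grid$n_windows)) {
    lam <- rep(config$baseline_rate * share[w], nrow(codes))
    boosted <- match(truth$code[truth$window == w], codes$code)
    lam_mat <- matrix(lam, nrow = n, ncol = nrow(codes), byrow = TRUE)
    if (length(boosted) > 0 && config$effect_multiplier > 1)
      lam_mat[label == 1L, boosted] <-
        lam_mat[label == 1L, boosted] * config$effect_multiplier
    cnt <- matrix(rpois(length(lam_mat), lam_mat), nrow = n)
    nz <- which(cnt > 0, arr.ind = TRUE)
    if (nrow(nz) == 0) next
    reps <- cnt[nz]
    pat_i <- rep(nz[, 1], reps)
    code_i <- rep(nz[, 2], reps)
    days <- sample(wd$lo[w]:wd$hi[w], length(pat_i), replace = TRUE)
    recs[[w]] <- data.frame(patient = patients[pat_i],
                            code = codes$code[code_i],
                            type = codes$type[code_i],
                            day_offset = days, stringsAsFactors = FALSE)
  }
  ev <- do.call(rbind, recs[!vapply(recs, is.null, TRUE)])
  if (is.null(ev))
    ev <- data.frame(patient = character(0), code = character(0),
                     type = character(0), day_offset = integer(0),
                     stringsAsFactors = FALSE)
  ev <- ev[order(ev$patient, ev$code, ev$day_offset), , drop = FALSE]

  list(events = validate_event_table(ev, config$horizon),
       cohort = cohort_table(patients, label),
       truth = structure(list(informative_pairs = truth,
                              effect_multiplier = config$effect_multiplier),
                         class = "planted_truth"))
}

#' Fraction of planted pairs recovered among the top-k learned weights
#'
#' Ranks the learned level-`all` weights in decreasing order, breaking ties
#' at the k-th weight by lexicographic (code, window) order, and returns
#' `|top-k  intersect  planted| / |planted|`.
#'
#' @param learned a [weight_table()] at level `all`.
#' @param truth the `planted_truth` from [generate_cohort()].
#' @param k number of top-weighted pairs considered (default: the number of
#'   planted pairs).
#' @return Recovery score in `[0, 1]`.
#' @export
recovery_score <- function(learned, truth,
                           k = nrow(truth$informative_pairs)) {
  stopifnot(inherits(learned, "weight_table"),
            inherits(truth, "planted_truth"))
  if (weight_level(learned) != "all")
    trf_stop("argument", "learned weights must be at level 'all'")
  if (k < 1) trf_stop("argument", "k must be >= 1")
  ord <- order(-learned$weight, learned$key, learned$window)
  top <- learned[ord[seq_len(min(k, nrow(learned)))], ]
  planted <- column_key(truth$informative_pairs$code,
                        truth$informative_pairs$window)
  hits <- sum(column_key(top$key, top$window) %in% planted)
  hits / length(planted)
}
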