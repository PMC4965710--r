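#' Learn per-(event, window) temporal weights from Gini importance
#'
#' Fits a standard (uniform candidate-probability) forest on the binned
#' count matrix, where the same clinical event from different time windows
#' is a different feature, and returns each column's normalized Gini
#' importance as its learned weight. The weights thereby reflect both the
#' temporality and the informativeness of the events.
#'
#' @param binned a [bin_events()] result.
#' @param labels binary labels aligned with `binned$patients`.
#' @param params a [forest_params()].
#' @return A [weight_table()] at level `all` with normalization
#'   `raw_importance`; weights sum to 1 (unless no split was ever made).
#' @export
learn_event_weights <- function(binned, labels, params = forest_params()) {
  stopifnot(inherits(binned, "binned_matrix"))
  forest <- fit_forest(binned, labels, probs = NULL, params = params)
  imp <- gini_importance(forest, normalize = TRUE)
  weight_table(key = binned$manifest$code, window = binned$manifest$window,
               weight = as.numeric(imp), level = "all",
               normalization = "raw_importance")
}

#' Aggregate a per-event weight table to a coarser granularity
#'
#' From level `all` (one weight per event code per window):
#' \describe{
#'   \item{`all`}{identity;}
#'   \item{`type`}{the arithmetic mean of member weights per event type per
#'     window;}
#'   \item{`time`}{the arithmetic mean over all columns of each window.}
#' }
#' The arithmetic mean keeps all levels on a common scale, so expanding a
#' coarser table back onto the columns preserves the mean column weight.
#'
#' @param table a [weight_table()] at level `all`.
#' @param target_level `"all"`, `"type"` or `"time"`.
#' @param manifest the binned-matrix column manifest (data.frame with
#'   `code`, `type`, `window`), needed to resolve event types.
#' @return A [weight_table()] at the target level.
#' @export
aggregate_weights <- function(table, target_level, manifest) {
  stopifnot(inherits(table, "weight_table"))
  if (!target_level %in% WEIGHT_LEVELS)
    trf_stop("argument", "unknown granularity level '%s'", target_level)
  if (weight_level(table) != "all")
    trf_stop("argument", "input table must be at level 'all'")
  if (target_level == "all") return(table)
  idx <- match(column_key(table$key, table$window),
               column_key(manifest$code, manifest$window))
  if (anyNA(idx))
    trf_stop("coverage", "weight table keys missing from the manifest")
  group <- if (target_level == "type")
    paste(manifest$type[idx], table$window) else as.character(table$window)
  agg <- tapply(table$weight, group, mean)
  if (target_level == "type") {
    parts <- strsplit(names(agg), " ", fixed = TRUE)
    weight_table(key = vapply(parts, `[[`, "", 1),
                 window = as.integer(vapply(parts, `[[`, "", 2)),
                 weight = as.numeric(agg), level = "type",
                 normalization = weight_normalization(table))
  } else {
    weight_table(key = "*", window = as.integer(names(agg)),
                 weight = as.numeric(agg), level = "time",
                 normalization = weight_normalization(table))
  }
}

#' Expand a weight table onto the binned-matrix columns
#'
#' Assigns each (code, window) column its group's weight according to the
#' table's granularity level.
#'
#' @param table a [weight_table()] at any level.
#' @param manifest the binned-matrix column manifest.
#' @return Numeric weight vector, one entry per manifest row.
#' @export
expand_weights <- function(table, manifest) {
  level <- weight_level(table)
  idx <- switch(level,
    all = match(column_key(manifest$code, manifest$window),
                column_key(table$key, table$window)),
    type = match(column_key(manifest$type, manifest$window),
                 column_key(table$key, table$window)),
    time = match(manifest$window, table$window))
  if (anyNA(idx)) {
    miss <- unique(manifest$key[is.na(idx)])
    trf_stop("coverage", "missing weight for column(s): %s",
             paste(head(miss, 5), collapse = ", "))
  }
  table$weight[idx]
}

#' Convert weights into candidate-sampling probabilities
#'
#' `prob_c = (w_c + floor) / sum(w + floor)` over the manifest columns. With
#' the default `floor = 0`, zero-weight columns get probability zero and are
#' never sampled as split candidates, honouring the reading of a zero Gini
#' importance as "useless or never selected".
#'
#' @param table a [weight_table()].
#' @param manifest the binned-matrix column manifest.
#' @param floor non-negative smoothing constant added to every weight.
#' @return Probability vector over the manifest columns (sums to 1).
#' @export
to_sampling_probs <- function(table, manifest, floor = 0) {
  if (floor < 0) trf_stop("argument", "floor must be >= 0")
  w <- expand_weights(table, manifest) + floor
  s <- sum(w)
  if (s <= 0)
    trf_stop("degenerate_weights",
             "all weights are zero and floor is zero")
  w / s
}

#' Rescale learned weights for weighted aggregation
#'
#' Divides every weight by the maximum weight, mapping the table onto
#' `[0, 1]` to mirror the range of the pre-assigned weights.
#'
#' @param table a [weight_table()] with non-negative weights, max > 0.
#' @return The same table with normalization `unit_interval`.
#' @export
scale_for_aggregation <- function(table) {
  stopifnot(inherits(table, "weight_table"))
  m <- max(table$weight)
  if (m <= 0)
    trf_stop("degenerate_weights", "cannot scale an all-zero weight table")
  weight_table(table$key, table$window, table$weight / m,
               level = weight_level(table), normalization = "unit_interval")
}

#' Pre-assigned per-window weights for the sampling strategy
#'
#' One weight per window, the reciprocal weight evaluated at the window's
#' representative day, taken as its upper boundary. Weights are strictly
#' decreasing across windows.
#'
#' @param grid a [window_grid()].
#' @return A [weight_table()] at level `time`.
#' @export
preassigned_window_weights <- function(grid = window_grid()) {
  weight_table(key = "*", window = seq_len(grid$n_windows),
               weight = preassigned_weight(grid$boundaries, grid$horizon),
               level = "time", normalization = "raw_importance")
}
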