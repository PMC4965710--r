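#' Temporal window grid over the patient history
#'
#' The history horizon is partitioned into consecutive windows by a strictly
#' increasing vector of day boundaries. Window `i` covers the half-open day
#' interval `(boundaries[i-1], boundaries[i]]`, with day 0 (the index day)
#' folded into window 1, so every event falls in exactly one window and
#' events from the previous window are excluded from the next. The default
#' grid is the 12-window split at 1, 2, 3, 4, 5, 6, 7, 14, 21, 30, 60 and 90
#' days before the index event.
#'
#' @param boundaries strictly increasing positive integer day boundaries;
#'   the last boundary is the horizon.
#' @return A list of class `window_grid` with elements `boundaries`,
#'   `horizon` and `n_windows`.
#' @export
window_grid <- function(boundaries = c(1, 2, 3, 4, 5, 6, 7, 14, 21, 30, 60, 90)) {
  boundaries <- as.integer(boundaries)
  if (length(boundaries) < 1 || boundaries[1] < 1L ||
      any(diff(boundaries) <= 0))
    trf_stop("argument",
             "boundaries must be strictly increasing integers with first >= 1")
  structure(list(boundaries = boundaries,
                 horizon = boundaries[length(boundaries)],
                 n_windows = length(boundaries)),
            class = "window_grid")
}

#' Map day offsets to window indices
#'
#' Returns, for each day offset, the smallest window index `i` such that
#' `day_offset <= boundaries[i]`; day 0 maps to window 1.
#'
#' @param day_offset integer vector of day offsets in `[0, horizon]`.
#' @param grid a [window_grid()].
#' @return Integer vector of window indices in `1..n_windows`.
#' @export
assign_window <- function(day_offset, grid = window_grid()) {
  if (any(day_offset < 0 | day_offset > grid$horizon))
    trf_stop("range", "day_offset outside [0, %d]", grid$horizon)
  findInterval(day_offset, grid$boundaries + 1L) + 1L
}

#' Pre-assigned reciprocal temporal weight
#'
#' The pre-assigned weighting of an event observed `n` days before the index
#' event is the reciprocal `w = 1/n`, the best-performing of the previously
#' proposed monotone decay curves; events on the index day itself (`n = 0`)
#' receive the maximal weight 1. Weights therefore lie in `(0, 1]` and are
#' non-increasing in `n`.
#'
#' @param day_offset integer vector of day offsets in `[0, horizon]`.
#' @param horizon history horizon in days.
#' @return Numeric vector of weights in `(0, 1]`.
#' @export
preassigned_weight <- function(day_offset, horizon = 90L) {
  if (any(day_offset < 0 | day_offset > horizon))
    trf_stop("range", "day_offset outside [0, %d]", horizon)
  1 / pmax(day_offset, 1)
}

column_key <- function(code, window) {
  if (length(code) == 0) return(character(0))
  paste0(code, "|w", window)
}

# Shared column manifest: all observed codes crossed with all grid windows,
# sorted by code then window, so feature order is deterministic and the
# pre-assigned window weights address every column.
build_manifest <- function(events, grid) {
  codes <- unique(events[, c("code", "type")])
  codes <- codes[order(codes$code), , drop = FALSE]
  manifest <- data.frame(
    code = rep(codes$code, each = grid$n_windows),
    type = rep(codes$type, each = grid$n_windows),
    window = rep(seq_len(grid$n_windows), times = nrow(codes)),
    stringsAsFactors = FALSE)
  manifest$key <- if (nrow(manifest) > 0)
    column_key(manifest$code, manifest$window) else character(0)
  rownames(manifest) <- NULL
  manifest
}

check_patients <- function(events, cohort) {
  unknown <- setdiff(unique(events$patient), cohort$patient)
  if (length(unknown) > 0)
    trf_stop("validation", "event(s) for unknown patient(s): %s",
             paste(head(unknown, 5), collapse = ", "))
}

#' Bin events into the Bag-of-Binned-Events count matrix
#'
#' Builds the sparse patients x (event code, window) occurrence-count matrix
#' in which the same clinical event observed in different time windows is a
#' different feature. Rows follow the cohort order; columns are every
#' observed code crossed with every grid window, sorted by code then window.
#' Patients without events get all-zero rows; the grand total of the matrix
#' equals the number of event records.
#'
#' @param events an [event_table()].
#' @param cohort a [cohort_table()]; every event patient must appear in it.
#' @param grid a [window_grid()].
#' @return A list of class `binned_matrix` with elements `X` (a
#'   `Matrix::dgCMatrix`), `manifest` (data.frame `code`, `type`, `window`,
#'   `key`) and `patients`.
#' @export
bin_events <- function(events, cohort, grid = window_grid()) {
  check_patients(events, cohort)
  if (attr(events, "horizon") > grid$horizon)
    trf_stop("argument", "event horizon exceeds grid horizon")
  manifest <- build_manifest(events, grid)
  i <- match(events$patient, cohort$patient)
  j <- match(column_key(events$code, assign_window(events$day_offset, grid)),
             manifest$key)
  X <- Matrix::sparseMatrix(
    i = i, j = j, x = rep(1, nrow(events)),
    dims = c(nrow(cohort), max(nrow(manifest), 1L)),
    dimnames = list(cohort$patient,
                    if (nrow(manifest) > 0) manifest$key else NULL))
  structure(list(X = X, manifest = manifest, patients = cohort$patient),
            class = "binned_matrix")
}

#' Aggregate events with pre-assigned exact-day weights
#'
#' The Bag-of-Weighted-Events representation: one column per event code,
#' whose value for a patient is the sum over that code's occurrences of the
#' reciprocal weight [preassigned_weight()] evaluated at the occurrence's
#' exact day offset.
#'
#' @param events an [event_table()].
#' @param cohort a [cohort_table()].
#' @return A list of class `aggregated_matrix` with elements `X` (dense
#'   numeric matrix), `manifest` (data.frame `code`, `type`) and `patients`.
#' @export
aggregate_preassigned <- function(events, cohort) {
  check_patients(events, cohort)
  codes <- unique(events[, c("code", "type")])
  codes <- codes[order(codes$code), , drop = FALSE]
  rownames(codes) <- NULL
  X <- Matrix::sparseMatrix(
    i = match(events$patient, cohort$patient),
    j = match(events$code, codes$code),
    x = preassigned_weight(events$day_offset, attr(events, "horizon")),
    dims = c(nrow(cohort), max(nrow(codes), 1L)),
    dimnames = list(cohort$patient,
                    if (nrow(codes) > 0) codes$code else NULL))
  structure(list(X = as.matrix(X), manifest = codes,
                 patients = cohort$patient),
            class = "aggregated_matrix")
}

#' Aggregate binned counts with learned per-window weights
#'
#' Collapses the binned matrix back to one column per event code by the
#' weighted sum over windows: `cell[p, c] = sum_i w(c, i) * count[p, (c, i)]`.
#' Weights must be on the unit-interval scale (see
#' [scale_for_aggregation()]) and, after granularity expansion, must cover
#' every binned column.
#'
#' @param binned a [bin_events()] result.
#' @param weights a [weight_table()] with normalization `unit_interval`.
#' @return An `aggregated_matrix` (see [aggregate_preassigned()]).
#' @export
aggregate_learned <- function(binned, weights) {
  stopifnot(inherits(binned, "binned_matrix"))
  if (weight_normalization(weights) != "unit_interval")
    trf_stop("argument",
             "aggregation weights must carry normalization 'unit_interval'")
  w <- expand_weights(weights, binned$manifest)
  codes <- unique(binned$manifest[, c("code", "type")])
  rownames(codes) <- NULL
  # sparse p x n_codes selector carrying the per-column weights
  S <- Matrix::sparseMatrix(
    i = seq_len(nrow(binned$manifest)),
    j = match(binned$manifest$code, codes$code),
    x = w, dims = c(nrow(binned$manifest), nrow(codes)),
    dimnames = list(binned$manifest$key, codes$code))
  X <- as.matrix(binned$X %*% S)
  structure(list(X = X, manifest = codes, patients = binned$patients),
            class = "aggregated_matrix")
}

#' Export a binned matrix as sparse triplets plus a column manifest
#'
#' Writes two CSVs: `<prefix>_triplets.csv` with columns
#' `patient`, `key`, `value` (non-zero cells only) and
#' `<prefix>_manifest.csv` fixing the column order.
#'
#' @param binned a [bin_events()] result.
#' @param prefix output path prefix.
#' @export
write_binned_matrix <- function(binned, prefix) {
  trip <- Matrix::summary(binned$X)
  df <- data.frame(patient = binned$patients[trip$i],
                   key = binned$manifest$key[trip$j],
                   value = trip$x, stringsAsFactors = FALSE)
  df <- df[order(match(df$patient, binned$patients), match(df$key, binned$manifest$key)), ]
  write.csv(df, paste0(prefix, "_triplets.csv"), row.names = FALSE,
            quote = FALSE)
  write.csv(binned$manifest, paste0(prefix, "_manifest.csv"),
            row.names = FALSE, quote = FALSE)
  invisible(prefix)
}
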