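#' @useDynLib tempoRF, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom methods as is
#' @importFrom stats pchisq pnorm rbinom rpois predict setNames
#' @importFrom utils read.csv write.csv head
NULL

EVENT_TYPES <- c("diagnosis", "drug", "measurement")
WEIGHT_LEVELS <- c("all", "type", "time")
NORMALIZATION_TAGS <- c("raw_importance", "unit_interval", "probability")

#' Construct a validated table of time-stamped clinical events
#'
#' An event table is the package's abstraction of a longitudinal health
#' record: one row per occurrence of a clinical event (a diagnosis, drug or
#' clinical measurement code) for a patient, time-stamped as an integer
#' day offset counted backwards from the patient's index (target adverse
#' drug event) date. Day 0 is the index day itself; repeated
#' (patient, code, day) rows are meaningful repeated occurrences and are
#' never deduplicated.
#'
#' @param patient character vector of patient identifiers.
#' @param code character vector of event codes (e.g. ICD-10 / ATC /
#'   measurement identifiers); no code-syntax validation is attempted.
#' @param type event type, one of `"diagnosis"`, `"drug"`, `"measurement"`.
#' @param day_offset integer days before the index event, in `[0, horizon]`.
#' @param horizon history horizon in days (default 90).
#' @return A `data.frame` of class `event_table` with columns
#'   `patient`, `code`, `type`, `day_offset` and attribute `horizon`.
#' @export
event_table <- function(patient, code, type, day_offset, horizon = 90L) {
  df <- data.frame(patient = as.character(patient),
                   code = as.character(code),
                   type = as.character(type),
                   day_offset = day_offset,
                   stringsAsFactors = FALSE)
  validate_event_table(df, horizon)
}

validate_event_table <- function(df, horizon) {
  horizon <- as.integer(horizon)
  if (!is.numeric(df$day_offset) ||
      any(is.na(df$day_offset)) && nrow(df) > 0 ||
      (nrow(df) > 0 && any(df$day_offset != floor(df$day_offset))))
    trf_stop("validation", "day_offset must be integer days%s",
             bad_row_suffix(!is.finite(df$day_offset) |
                              df$day_offset != floor(df$day_offset)))
  df$day_offset <- as.integer(df$day_offset)
  bad <- df$day_offset < 0L | df$day_offset > horizon
  if (any(bad))
    trf_stop("validation",
             "day_offset outside [0, %d]%s", horizon, bad_row_suffix(bad))
  bad <- !(df$type %in% EVENT_TYPES)
  if (any(bad))
    trf_stop("validation", "unknown event_type %s%s",
             paste(unique(df$type[bad]), collapse = ", "),
             bad_row_suffix(bad))
  if (nrow(df) > 0 && any(!nzchar(df$code)))
    trf_stop("validation", "empty event code%s",
             bad_row_suffix(!nzchar(df$code)))
  rownames(df) <- NULL
  structure(df, horizon = horizon,
            class = c("event_table", "data.frame"))
}

bad_row_suffix <- function(bad) {
  bad <- which(bad)
  if (length(bad) == 0) return("")
  sprintf(" (row%s %s)", if (length(bad) > 1) "s" else "",
          paste(head(bad, 5), collapse = ", "))
}

#' Read an event table from CSV
#'
#' Expects a UTF-8 comma-separated file with a header naming the columns
#' `patient`, `code`, `type`, `day_offset` (extra columns are ignored).
#' Row order is preserved; repeated rows are kept.
#'
#' @param path path to the CSV file.
#' @param horizon history horizon in days; every `day_offset` must lie in
#'   `[0, horizon]`.
#' @return An [event_table()].
#' @export
read_events <- function(path, horizon = 90L) {
  if (!file.exists(path)) trf_stop("format", "file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("patient", "code", "type", "day_offset")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    trf_stop("format", "missing column(s): %s", paste(miss, collapse = ", "))
  day <- suppressWarnings(as.numeric(df$day_offset))
  if (nrow(df) > 0 && any(is.na(day)))
    trf_stop("validation", "non-numeric day_offset%s",
             bad_row_suffix(is.na(day)))
  df$day_offset <- day
  validate_event_table(df[need], horizon)
}

#' Write an event table to CSV
#' @param events an [event_table()].
#' @param path output path.
#' @export
write_events <- function(events, path) {
  write.csv(as.data.frame(events)[c("patient", "code", "type", "day_offset")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a validated cohort label table
#'
#' One row per patient with a binary class label; `1` marks the
#' ADE-positive class (the rare class of interest), `0` the control class.
#'
#' @param patient character vector of unique patient identifiers.
#' @param label binary labels encodable as `{0, 1}`.
#' @return A `data.frame` of class `cohort_table` with columns
#'   `patient`, `label`.
#' @export
cohort_table <- function(patient, label) {
  patient <- as.character(patient)
  if (anyDuplicated(patient))
    trf_stop("validation", "duplicated patient id(s): %s",
             paste(unique(patient[duplicated(patient)]), collapse = ", "))
  lab <- suppressWarnings(as.numeric(label))
  if (length(lab) != length(patient) ||
      (length(lab) > 0 && (any(is.na(lab)) || !all(lab %in% c(0, 1)))))
    trf_stop("validation", "labels must be encodable as {0, 1}")
  structure(data.frame(patient = patient, label = as.integer(lab),
                       stringsAsFactors = FALSE),
            class = c("cohort_table", "data.frame"))
}

#' Read a cohort table from CSV
#'
#' Expects columns `patient`, `label` with unique patients and labels in
#' `{0, 1}` (1 = ADE-positive).
#'
#' @param path path to the CSV file.
#' @return A [cohort_table()].
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) trf_stop("format", "file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  miss <- setdiff(c("patient", "label"), names(df))
  if (length(miss) > 0)
    trf_stop("format", "missing column(s): %s", paste(miss, collapse = ", "))
  cohort_table(df$patient, df$label)
}

#' Write a cohort table to CSV
#' @param cohort a [cohort_table()].
#' @param path output path.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(as.data.frame(cohort)[c("patient", "label")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a temporal weight table
#'
#' A weight table maps keys at one of three granularity levels to a
#' non-negative weight per time window:
#' \describe{
#'   \item{`all`}{one weight per individual event code per window
#'     (`key` = event code);}
#'   \item{`type`}{one weight per event type per window
#'     (`key` in `diagnosis`/`drug`/`measurement`);}
#'   \item{`time`}{one weight per window (`key` = `"*"`).}
#' }
#' The `normalization` tag records the scale of the weights:
#' `raw_importance` (normalized Gini importances), `unit_interval`
#' (max-scaled into `[0, 1]`, for weighted aggregation) or `probability`
#' (simplex over feature columns, for weighted sampling).
#'
#' @param key character keys as described above.
#' @param window integer window indices (1-based).
#' @param weight non-negative weights.
#' @param level granularity level, one of `"all"`, `"type"`, `"time"`.
#' @param normalization one of `"raw_importance"`, `"unit_interval"`,
#'   `"probability"`.
#' @return A `data.frame` of class `weight_table` with columns
#'   `key`, `window`, `weight` and attributes `level`, `normalization`.
#' @export
weight_table <- function(key, window, weight, level,
                         normalization = "raw_importance") {
  level <- match.arg(level, WEIGHT_LEVELS)
  normalization <- match.arg(normalization, NORMALIZATION_TAGS)
  df <- data.frame(key = as.character(key), window = as.integer(window),
                   weight = as.numeric(weight), stringsAsFactors = FALSE)
  if (nrow(df) > 0 && any(!is.finite(df$weight) | df$weight < 0))
    trf_stop("validation", "weights must be finite and >= 0")
  if (level == "time" && !all(df$key == "*"))
    trf_stop("validation", "level 'time' entries must use the wildcard key '*'")
  if (level == "type" && !all(df$key %in% EVENT_TYPES))
    trf_stop("validation", "level 'type' keys must be event types")
  if (anyDuplicated(df[c("key", "window")]))
    trf_stop("validation", "duplicated (key, window) entries")
  if (normalization == "unit_interval" && nrow(df) > 0 &&
      any(df$weight > 1 + 1e-12))
    trf_stop("validation", "unit_interval weights must lie in [0, 1]")
  if (normalization == "probability" && nrow(df) > 0 &&
      abs(sum(df$weight) - 1) > 1e-9)
    trf_stop("validation",
             "probability-tagged weights must sum to 1 (got %.12g)",
             sum(df$weight))
  rownames(df) <- NULL
  structure(df, level = level, normalization = normalization,
            class = c("weight_table", "data.frame"))
}

weight_level <- function(table) attr(table, "level")
weight_normalization <- function(table) attr(table, "normalization")

#' Write a weight table to CSV
#'
#' The file carries a one-line metadata header
#' `# level=<level> normalization=<tag>` followed by a regular CSV with
#' columns `level`, `key`, `window`, `weight`. Weights are written with 17
#' significant digits so that [read_weight_table()] round-trips exactly.
#'
#' @param table a [weight_table()].
#' @param path output path.
#' @export
write_weight_table <- function(table, path) {
  stopifnot(inherits(table, "weight_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# level=%s normalization=%s",
                     weight_level(table), weight_normalization(table)), con)
  writeLines("level,key,window,weight", con)
  if (nrow(table) > 0)
    writeLines(sprintf("%s,%s,%d,%.17g", weight_level(table), table$key,
                       table$window, table$weight), con)
  invisible(path)
}

#' Read a weight table from CSV
#' @param path path written by [write_weight_table()].
#' @return A [weight_table()].
#' @export
read_weight_table <- function(path) {
  if (!file.exists(path)) trf_stop("format", "file not found: %s", path)
  lines <- readLines(path)
  if (length(lines) < 2 || !grepl("^# level=", lines[1]))
    trf_stop("format", "missing '# level=... normalization=...' header")
  meta <- regmatches(lines[1],
                     regexec("^# level=(\\S+) normalization=(\\S+)", lines[1]))[[1]]
  if (length(meta) != 3) trf_stop("format", "unparseable metadata header")
  df <- read.csv(text = paste(lines[-1], collapse = "\n"),
                 stringsAsFactors = FALSE)
  if (nrow(df) > 0 && any(df$weight < 0))
    trf_stop("validation", "negative weight on read")
  weight_table(df$key, df$window, df$weight,
               level = meta[2], normalization = meta[3])
}
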