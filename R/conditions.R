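# Classed error conditions so callers (and tests) can distinguish the
# failure kinds the interfaces promise: validation, format, argument, range,
# configuration, coverage, degenerate-weights, stratification, class, metric,
# manifest and reporting errors.

trf_stop <- function(class, msg, ...) {
  msg <- sprintf(msg, ...)
  stop(structure(
    class = c(paste0("trf_", class, "_error"), "trf_error", "error",
              "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
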