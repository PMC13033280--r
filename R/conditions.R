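# Classed conditions so callers (and the CLI) can distinguish bad input
# values from out-of-range lookups and file parse failures.

abort_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("rudose_validation_error", "rudose_error")))
}

abort_range <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("rudose_range_error", "rudose_error")))
}

abort_parse <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("rudose_parse_error", "rudose_error")))
}

check_that <- function(cond, msg, ...) {
  if (!isTRUE(cond)) abort_validation(msg, ...)
  invisible(TRUE)
}
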