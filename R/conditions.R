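# Classed conditions so callers can distinguish "the quantity does not
# exist for this input" (pg_undefined) from programming errors, and so the
# CLI can map error classes to exit codes.

pg_stop <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "pg_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

#' @rdname pg_conditions
#' @name pg_conditions
#' @title Condition classes used by pgcc
#' @description
#' `pg_undefined` signals that a requested quantity is undefined for the
#' given input (for example R50 on a profile that never falls below half
#' maximum, or the precision of an empty selection). `pg_schema_error` and
#' `pg_integrity_error` signal malformed or tampered files.
#' `pg_degenerate_training` signals a single-class training set.
#' All inherit from `pg_error` and `error`.
NULL

pg_undefined <- function(message) pg_stop(message, "pg_undefined")
pg_schema_error <- function(message) pg_stop(message, "pg_schema_error")
pg_integrity_error <- function(message) pg_stop(message, "pg_integrity_error")
pg_degenerate_training <- function(message) pg_stop(message, "pg_degenerate_training")
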