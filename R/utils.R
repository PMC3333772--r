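# Internal helpers: error conditions, seeded RNG scoping, logging.

condspec_error <- function(class, message, call = sys.call(-1)) {
  structure(
    class = c(class, "condspec_error", "error", "condition"),
    list(message = message, call = call)
  )
}

#' @noRd
stop_validation <- function(fmt, ...) {
  stop(condspec_error("condspec_validation_error", sprintf(fmt, ...)))
}

#' @noRd
stop_degenerate <- function(fmt, ...) {
  stop(condspec_error("condspec_degenerate_error", sprintf(fmt, ...)))
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a per-unit seed from a master seed; stays within 32-bit range.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(i) * 104729) %% 2147483647L)
}

# Minimal in-memory log collector; messages are also emitted via message()
# when verbose. Retrieved by the pipeline to write run.log.
log_env <- new.env(parent = emptyenv())
log_env$lines <- character()
log_env$verbose <- FALSE

condspec_log <- function(fmt, ...) {
  line <- sprintf(fmt, ...)
  log_env$lines <- c(log_env$lines, line)
  if (isTRUE(log_env$verbose)) message(line)
  invisible(line)
}

log_reset <- function(verbose = FALSE) {
  log_env$lines <- character()
  log_env$verbose <- verbose
  invisible(NULL)
}

log_lines <- function() log_env$lines
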