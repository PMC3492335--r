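`%||%` <- function(x, y) if (is.null(x)) y else x

#' Raise a classed validation error
#'
#' All readers and constructors signal errors of class
#' `triomics_validation_error` with a specific subclass, so callers can
#' distinguish, e.g., an overlap violation from a range violation.
#'
#' @param subclass character scalar, specific condition class.
#' @param message error message; include file/line/field context where known.
#' @param ... additional fields stored on the condition.
#' @keywords internal
abort_validation <- function(subclass, message, ...) {
  cond <- structure(
    class = c(subclass, "triomics_validation_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == as.integer(x)
}

#' Autosome identifiers admitted throughout the package
#' @keywords internal
autosomes <- function(n = 22L) as.character(seq_len(n))

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. Sub-seeds derived per platform keep the streams
# independent: adding probes on one platform cannot perturb another.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}
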