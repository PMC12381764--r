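#' @importFrom rlang abort warn inform %||%
#' @importFrom stats rnorm runif qbinom setNames predict
#' @importFrom utils head tail
NULL

# Internal: stop with a classed condition so tests can target error types.
stop_subloc <- function(msg, class, ...) {
  rlang::abort(msg, class = c(class, "subloc_error"), ...)
}

assert_that <- function(ok, msg, class = "subloc_argument_error") {
  if (!isTRUE(ok)) stop_subloc(msg, class)
  invisible(TRUE)
}

# Binary 0/1 matrix check used by the label-dependent operations.
assert_binary_matrix <- function(m, name = "matrix") {
  assert_that(is.matrix(m) && is.numeric(m), sprintf("`%s` must be a numeric matrix", name))
  assert_that(all(m %in% c(0, 1)), sprintf("`%s` must contain only 0/1 entries", name))
  invisible(TRUE)
}

#' Order-insensitive checksum of a parameter list
#'
#' Collapses every numeric array in a (possibly nested) parameter list into a
#' short deterministic fingerprint. Used to verify the frozen-encoder
#' contract: the checksum must be identical before and after decoder
#' training.
#'
#' @param params A (nested) list of numeric arrays.
#' @return A character scalar fingerprint.
#' @export
param_checksum <- function(params) {
  x <- unlist(params, use.names = FALSE)
  x <- as.numeric(x)
  stats <- c(length(x), sum(x), sum(x^2), sum(x * seq_along(x)), sum(abs(x)))
  paste(formatC(stats, format = "e", digits = 15), collapse = "|")
}

# Evaluate `code` with a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Derive a stream-specific child seed below 2^31 from a master seed.
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + stream * 1009) %% 2147483647
}
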