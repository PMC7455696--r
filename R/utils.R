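# Helpers shared across modules.

#' Derive a child seed from a root seed
#'
#' Deterministic derivation of per-operation seeds from one root seed, so
#' that every stage of a workflow draws from its own reproducible stream.
#' The result stays below 2^31 - 1 (a valid R integer seed).
#'
#' @param seed root seed (numeric scalar).
#' @param k stream index.
#' @return integer seed.
#' @export
child_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(k))
  as.integer((abs(as.numeric(seed)) * 7919 + as.numeric(k) * 104729) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)

# log a filter-style message (input -> output counts); suppressible via
# options(ailqtl.verbose = FALSE)
log_info <- function(...) {
  if (isTRUE(getOption("ailqtl.verbose", TRUE))) message("[ailqtl] ", ...)
}
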