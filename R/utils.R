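#' Evaluate an expression under a local RNG seed
#'
#' Runs `expr` with the global random-number state set from `seed`, then
#' restores whatever state existed before the call, so package functions are
#' reproducible without clobbering the caller's stream.
#'
#' @param seed Integer seed, or `NULL` to use the current stream as-is.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1)  # force initialisation so there is a state to restore
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a formatted message
#' @noRd
abort <- function(...) stop(sprintf(...), call. = FALSE)

#' Sample that never interprets a length-1 x as 1:x
#' @noRd
sample_vals <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}
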