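#' Evaluate an expression with a locally seeded RNG
#'
#' Runs `expr` with the RNG seeded to `seed`, restoring the caller's RNG
#' state afterwards so generators never leak global state. `seed = NULL`
#' uses the current stream untouched.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  }
  invisible(x)
}

#' Derive a stream-specific child seed
#'
#' Deterministically maps a base seed and a stream label to a 31-bit seed so
#' independent generators driven from one user seed do not share streams.
#'
#' @keywords internal
child_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  (as.integer(seed) %% 1000003L) * 2017L + as.integer(h %% 104729L) %% .Machine$integer.max
}
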