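#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so seeded simulation helpers do not
#' disturb the caller's random stream. `seed = NULL` leaves the stream alone.
#'
#' @param seed integer seed or `NULL`
#' @param expr expression to evaluate
#' @return the value of `expr`
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

#' Derive a child seed from a base seed
#'
#' Deterministic, keeps results below 2^31 so they remain valid R integers.
#' @param base integer base seed
#' @param k stream index
#' @keywords internal
child_seed <- function(base, k) {
  as.integer((as.numeric(base) * 1103L + 7919 * k) %% 2147483647)
}
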