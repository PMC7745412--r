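# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
abort <- function(class, msg, ...) {
  stop(structure(class = c(class, "kmerbind_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

# Evaluate `expr` under a fixed RNG state, restoring the caller's state after.
# All stochastic entry points funnel through this so runs are reproducible from
# their `seed` argument alone and do not disturb the session RNG.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
sigmoid <- function(x) 1 / (1 + exp(-x))
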