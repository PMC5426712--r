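# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# error class for analytic-approximation breakdowns (negative variances etc.);
# the CLI maps this class to exit status 2
numerical_error <- function(fmt, ...) {
  stop(structure(
    class = c("sascov_numerical", "error", "condition"),
    list(message = sprintf(fmt, ...), call = NULL)
  ))
}

# run `expr` under a fixed RNG seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_q_grid <- function(q) {
  if (!is.numeric(q) || length(q) < 1L || anyNA(q))
    stopf("q grid must be numeric without NAs")
  if (q[1] < 0) stopf("q grid must start at q >= 0")
  if (length(q) > 1L && any(diff(q) <= 0))
    stopf("q grid must be strictly increasing")
  as.numeric(q)
}
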