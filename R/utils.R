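# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ..., class = NULL) {
  msg <- sprintf(fmt, ...)
  cond <- structure(
    class = c(class, "riskeqtl_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state on exit.
# All generators route their randomness through this so identical seeds give
# bit-identical output regardless of what the session did before.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stopf("seed must be a single integer", class = "invalid_argument")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == floor(x)
}

check_fraction <- function(x, name, lo = 0, hi = 1, open_lo = FALSE, open_hi = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (open_lo) x > lo else x >= lo) && (if (open_hi) x < hi else x <= hi)
  if (!ok) stopf("%s must lie in %s%g, %g%s", name,
                 if (open_lo) "(" else "[", lo, hi, if (open_hi) ")" else "]",
                 class = "invalid_argument")
  invisible(x)
}
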