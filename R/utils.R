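# Internal helpers shared across modules.

# Evaluate `expr` under a private RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. `seed = NULL` uses (and advances) the
# current stream.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

# scalar checks ---------------------------------------------------------------

.checkCount <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}

.checkNumber <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (strict && x <= min) || (!strict && x < min))
    stop(sprintf("'%s' must be a single number %s %s", name,
                 if (strict) ">" else ">=", format(min)), call. = FALSE)
  as.numeric(x)
}

# uniform integer draw on [lo, hi], vectorised, using runif so the stream is
# independent of R's sample() internals
.runifInt <- function(n, lo, hi) {
  lo + as.integer(floor(stats::runif(n) * (hi - lo + 1L)))
}
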