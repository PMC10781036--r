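#' @useDynLib ppgbioid, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. All stochastic code in the package funnels through
# this so that every operation is a pure function of its seed arguments.
withSeed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  force(expr)
}

# Derive a child seed < 2^31 from a parent seed and a stream label.
# The multiplier keeps every product below 2^53 so the modular arithmetic
# stays exact in double precision.
childSeed <- function(seed, ...) {
  parts <- c(seed, unlist(list(...)))
  acc <- 0
  for (p in parts) {
    vs <- if (is.character(p)) utf8ToInt(p) else as.numeric(p)
    for (v in vs)
      acc <- (acc * 69069 + (v %% 2147483647) + 12345) %% 2147483647
  }
  as.integer(acc)
}

assertScalar <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x)))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be positive", name), call. = FALSE)
  invisible(x)
}
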