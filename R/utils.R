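# Internal helpers.

nextPow2 <- function(n) {
  stopifnot(n >= 1)
  2L^as.integer(ceiling(log2(n)))
}

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
# seed = NULL leaves the current RNG stream untouched.
withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) return(force(expr))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

vmsg <- function(verbose, ...) if (isTRUE(verbose)) message(sprintf(...))
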