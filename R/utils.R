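#' @import methods
#' @importFrom stats cor fft median pchisq ptukey quantile rbinom rnorm runif sd var
#' @importFrom utils head read.csv write.csv
NULL

## Run an expression under a local RNG seed, restoring the caller's RNG
## state afterwards so seeded helpers never perturb the global stream.
withSeed <- function(seed, expr) {
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

## Derive a stream-specific child seed from a master seed; kept < 2^31.
deriveSeed <- function(seed, offset) {
  (as.double(seed) * 7919 + as.double(offset) * 104729) %% 2147483629
}

assertScalarNumber <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stop(sprintf("'%s' must be a finite number in [%s, %s]", name,
                 format(lower), format(upper)), call. = FALSE)
  invisible(x)
}
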