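#' @keywords internal
"_PACKAGE"

# Run expr with a locally seeded RNG, restoring the caller's RNG state on exit.
# All stochastic package functions take an explicit `seed` and route through
# this, so identical (inputs, seed) give byte-identical results without
# clobbering the user's random stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# sample() without the length-1 surprise
sample_int <- function(n, size, replace = FALSE) {
  if (n < 1L) integer(0) else sample.int(n, size, replace = replace)
}
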