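#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All stochastic operations in the package go
# through this so that user code and package code never perturb each other.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic child seeds: each pipeline stage draws from its own stream so
# adding a stage never perturbs another stage's random numbers. Kept < 2^31-1.
child_seed <- function(master, stream, index = 0L) {
  as.integer((as.double(master) * 48271 + as.double(stream) * 1299721 +
                as.double(index) * 7919) %% 2147483563) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_erphab <- function(...) stop(..., call. = FALSE)

assert_finite <- function(x, what) {
  if (!all(is.finite(x))) stop_erphab("non-finite values in ", what)
  invisible(x)
}
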