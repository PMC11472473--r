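#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed` and restores the caller's
#' RNG state afterwards, so seeded generators do not perturb user simulations.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# Deterministic sub-seed for (seed, index) pairs; stays inside 32-bit range
# and decorrelates consecutive indices.
sub_seed <- function(seed, index) {
  s <- (as.double(seed) * 48271 + as.double(index) * 30269 + 11) %% 2147483629
  as.integer(s) + 1L
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_param <- function(...) stop(..., call. = FALSE)

clip_adu <- function(x, bit_depth) {
  pmin(pmax(x, 0), 2^bit_depth - 1)
}
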