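#' Derive reproducible sub-seeds from a root seed
#'
#' All stochastic functions in the package take an explicit `rng_seed`.
#' Multi-stage drivers fan a single root seed out into per-stage seeds with
#' this helper so that stages stay independently reproducible.
#'
#' @param seed Integer root seed.
#' @param n Number of sub-seeds to derive.
#' @return Integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seeds(1, 3)
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(n), n >= 1)
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

# Run `expr` under `seed` when given, leaving the caller's RNG state intact.
# seed = NULL uses (and advances) the current RNG stream.
with_opt_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stopifnot with a formatted message
assert_that <- function(cond, ...) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)
  invisible(TRUE)
}
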