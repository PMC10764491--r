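#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the global `.Random.seed`, seeds the Mersenne-Twister generator with
#' `seed`, evaluates `expr`, and restores the previous RNG state so that
#' simulation helpers never perturb the caller's random stream.
#'
#' @param seed Integer scalar seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a parent seed
#'
#' All randomness in the package flows from one integer seed through this
#' splitting scheme: child `k` of seed `s` is
#' `(s * 48271 + k * 2246822519) mod (2^31 - 1)`, a multiplicative-congruential
#' mix that keeps children well separated for consecutive `k` and always below
#' `2^31` (valid `set.seed()` input).
#'
#' @param seed Parent integer seed.
#' @param k Child index (integer, may be a vector).
#' @return Integer vector of child seeds.
#' @export
split_seed <- function(seed, k) {
  m <- 2147483647
  s <- as.numeric(seed) %% m
  as.integer((s * 48271 + as.numeric(k) * 2246822519) %% m)
}
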