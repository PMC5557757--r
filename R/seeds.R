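#' Derive a reproducible substream seed
#'
#' All randomness in the package flows from one master integer seed. Each
#' participant x task (x replicate) combination gets its own substream seed so
#' that any stage can be regenerated in isolation without replaying the whole
#' simulation. The derivation is a small multiplicative integer mix, kept
#' strictly below 2^31 so the result is always a valid R seed.
#'
#' @param seed master integer seed.
#' @param ... further non-negative integer indices identifying the substream
#'   (e.g. participant index, task code, trial block). Character values are
#'   hashed by their UTF-8 bytes.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @examples
#' substream_seed(42, 3, "tct")
#' @export
substream_seed <- function(seed, ...) {
  stopifnot(length(seed) == 1, is.finite(seed))
  m <- 2147483647 # 2^31 - 1, prime
  s <- as.double(seed) %% m
  keys <- list(...)
  for (k in keys) {
    if (is.character(k)) {
      k <- sum(as.double(utf8ToInt(k)) * seq_along(utf8ToInt(k)))
    }
    for (ki in k) {
      stopifnot(is.finite(ki))
      # 69069 and 1103515245 are classic LCG multipliers; doubles hold the
      # intermediate products exactly (< 2^53).
      s <- (s * 69069 + (as.double(ki) %% m) * 1103515 + 12345) %% m
    }
  }
  as.integer(s)
}

#' Evaluate an expression under a temporary RNG state
#'
#' Saves and restores `.Random.seed` so simulation helpers do not perturb the
#' caller's random stream.
#'
#' @param seed integer seed for the expression.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
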