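#' Simulated psychophysical observer
#'
#' An observer for two-interval forced-choice (2IFC) tasks, with a logistic
#' psychometric function. The probability of a correct response at stimulus
#' level `x` is
#'
#' \deqn{P(correct | x) = \gamma + (1 - \gamma - \lambda)\,F((x - \theta)/\sigma)}
#'
#' where \eqn{F} is the standard logistic CDF, \eqn{\theta} the threshold
#' (location), \eqn{\sigma} the spread, \eqn{\gamma} the guess rate (0.5 for
#' 2IFC) and \eqn{\lambda} the lapse rate.
#'
#' @param threshold location \eqn{\theta} in stimulus units (mm or grams).
#' @param spread positive spread \eqn{\sigma} in stimulus units.
#' @param guess_rate lower asymptote; 0.5 for a two-interval task.
#' @param lapse_rate lapse probability in `[0, 0.1]`.
#' @return An object of class `"observer_spec"`.
#' @examples
#' obs <- observer_spec(threshold = 10, spread = 3)
#' p_correct(obs, c(5, 10, 20))
#' @export
observer_spec <- function(threshold, spread, guess_rate = 0.5, lapse_rate = 0) {
  if (!is.finite(spread) || spread <= 0) {
    stop("`spread` must be a positive number, got ", spread)
  }
  if (guess_rate < 0 || guess_rate >= 1) {
    stop("`guess_rate` must lie in [0, 1), got ", guess_rate)
  }
  if (lapse_rate < 0 || lapse_rate > 0.1) {
    stop("`lapse_rate` must lie in [0, 0.1], got ", lapse_rate)
  }
  structure(
    list(
      threshold = as.double(threshold), spread = as.double(spread),
      guess_rate = as.double(guess_rate), lapse_rate = as.double(lapse_rate)
    ),
    class = "observer_spec"
  )
}

#' @export
print.observer_spec <- function(x, ...) {
  cat(sprintf(
    "Simulated 2IFC observer: threshold %.4g, spread %.4g, guess %.3g, lapse %.3g\n",
    x$threshold, x$spread, x$guess_rate, x$lapse_rate
  ))
  invisible(x)
}

#' Probability of a correct response at given stimulus levels
#'
#' @param observer an [observer_spec()].
#' @param level numeric vector of stimulus levels.
#' @return Numeric vector of probabilities, nondecreasing in `level`.
#' @export
p_correct <- function(observer, level) {
  stopifnot(inherits(observer, "observer_spec"))
  g <- observer$guess_rate
  l <- observer$lapse_rate
  g + (1 - g - l) * stats::plogis((level - observer$threshold) / observer$spread)
}

#' Simulate 2IFC responses
#'
#' Bernoulli draws at the observer's `p_correct(level)`. Uses the current RNG
#' stream; seed control is the caller's responsibility (see
#' [substream_seed()]).
#'
#' @inheritParams p_correct
#' @return Logical vector, `TRUE` for a correct response.
#' @export
simulate_2ifc_response <- function(observer, level) {
  stats::runif(length(level)) < p_correct(observer, level)
}

#' Simulate 0-10 subjective ratings for one stimulation trial
#'
#' Ratings of perceived intensity, painfulness and unpleasantness on the
#' 11-point scale (0 = not at all, 10 = extremely). Each rating is an
#' ordered-normal discretisation: a Gaussian draw around the configured mean
#' for the stimulus intensity, rounded to the nearest integer and clipped to
#' 0..10.
#'
#' @param means named numeric vector or list with elements `intensity`,
#'   `pain`, `unpleasant`: latent means for this stimulus intensity.
#' @param sd latent standard deviation (shared across the three scales).
#' @return Named integer vector (`intensity`, `pain`, `unpleasant`) in 0..10.
#' @export
simulate_ratings <- function(means, sd = 1.5) {
  stopifnot(all(c("intensity", "pain", "unpleasant") %in% names(means)), sd >= 0)
  m <- unlist(means)[c("intensity", "pain", "unpleasant")]
  r <- round(stats::rnorm(3, mean = m, sd = sd))
  r <- pmin(pmax(r, 0), 10)
  stats::setNames(as.integer(r), c("intensity", "pain", "unpleasant"))
}
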