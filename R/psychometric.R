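#' Constant-stimuli design for the touch comparison task
#'
#' The standard monofilament (1.4 g) is compared against each comparison
#' force in a two-interval forced-choice "which was stronger" paradigm: 4
#' blocks x 8 trials per comparison = 32 trials per comparison force and 192
#' trials in total.
#'
#' @param standard_g standard force, grams.
#' @param comparisons_g comparison forces, grams (must exclude the standard).
#' @param trials_per_comparison total trials per comparison force across all
#'   blocks.
#' @param blocks number of blocks; `trials_per_comparison` must be divisible
#'   by `blocks`.
#' @return An object of class `"cs_design"`.
#' @export
constant_stimuli_design <- function(standard_g = 1.4,
                                    comparisons_g = c(0.4, 0.6, 1.0, 2.0, 4.0, 6.0),
                                    trials_per_comparison = 32,
                                    blocks = 4) {
  if (standard_g %in% comparisons_g) {
    stop("the standard force must not appear among the comparison forces")
  }
  if (trials_per_comparison %% blocks != 0) {
    stop("trials_per_comparison must be divisible by the number of blocks")
  }
  structure(
    list(
      standard_g = standard_g, comparisons_g = sort(comparisons_g),
      trials_per_comparison = trials_per_comparison, blocks = blocks,
      n_trials = trials_per_comparison * length(comparisons_g)
    ),
    class = "cs_design"
  )
}

#' @export
print.cs_design <- function(x, ...) {
  cat(sprintf(
    "Constant-stimuli design: standard %g g, %d comparisons, %d blocks, %d trials\n",
    x$standard_g, length(x$comparisons_g), x$blocks, x$n_trials
  ))
  invisible(x)
}

#' Generate the trial table for a constant-stimuli session
#'
#' Each block presents every comparison force `trials_per_comparison /
#' blocks` times in shuffled order; the standard/comparison presentation
#' order within a trial is drawn uniformly (stochastic counterbalancing).
#'
#' @param design a [constant_stimuli_design()].
#' @return Data frame: `block`, `trial_index` (within session),
#'   `comparison_g`, `order` (`"standard_first"`/`"comparison_first"`).
#' @export
generate_tct_trials <- function(design) {
  stopifnot(inherits(design, "cs_design"))
  per_block <- design$trials_per_comparison / design$blocks
  rows <- lapply(seq_len(design$blocks), function(b) {
    forces <- sample(rep(design$comparisons_g, per_block))
    data.frame(
      block = b, comparison_g = forces,
      order = sample(c("standard_first", "comparison_first"),
                     length(forces), replace = TRUE)
    )
  })
  out <- do.call(rbind, rows)
  out$trial_index <- seq_len(nrow(out))
  out[, c("block", "trial_index", "comparison_g", "order")]
}

#' Simulate "stronger" judgements for a comparison observer
#'
#' The observer reports the comparison stronger than the standard with
#' probability `plogis(b * (x - pse))`, a cumulative-logistic psychometric
#' function with point of subjective equality `pse` and scale `b`.
#'
#' @param trials trial table from [generate_tct_trials()].
#' @param pse point of subjective equality, grams.
#' @param slope_b logistic scale parameter, per gram (> 0).
#' @param lapse_rate probability of a random response (halved to each side).
#' @return `trials` with a logical `response_stronger` column added.
#' @export
simulate_tct_responses <- function(trials, pse, slope_b, lapse_rate = 0) {
  stopifnot(slope_b > 0, lapse_rate >= 0, lapse_rate <= 0.1)
  p <- lapse_rate / 2 +
    (1 - lapse_rate) * stats::plogis(slope_b * (trials$comparison_g - pse))
  trials$response_stronger <- stats::runif(nrow(trials)) < p
  trials
}

#' Tabulate "stronger" responses per comparison force
#'
#' @param trials data frame with `comparison_g` and logical
#'   `response_stronger`.
#' @param design optional [constant_stimuli_design()]; when given, any trial
#'   whose force is not in the design is an error.
#' @return Data frame sorted by force: `comparison_g`, `n_trials`,
#'   `n_stronger`, `fraction_stronger`.
#' @export
tabulate_responses <- function(trials, design = NULL) {
  if (is.null(trials) || nrow(trials) == 0) stop("no trials to tabulate")
  stopifnot(all(c("comparison_g", "response_stronger") %in% names(trials)))
  if (!is.null(design)) {
    bad <- which(!trials$comparison_g %in% design$comparisons_g)
    if (length(bad)) {
      stop("trial ", bad[1], " uses force ", trials$comparison_g[bad[1]],
           " g, which is not in the design")
    }
  }
  agg <- stats::aggregate(
    cbind(n_trials = 1, n_stronger = trials$response_stronger),
    by = list(comparison_g = trials$comparison_g), FUN = sum
  )
  agg <- agg[order(agg$comparison_g), ]
  agg$fraction_stronger <- agg$n_stronger / agg$n_trials
  rownames(agg) <- NULL
  agg
}

#' Fit a two-parameter cumulative-logistic psychometric function
#'
#' Maximises the Bernoulli log-likelihood of
#' \deqn{P(stronger | x) = \gamma + (1-\gamma-\lambda)\,/\,(1 + e^{-(a + b x)})}
#' in the location/scale parameters `(a, b)` (guess \eqn{\gamma} and lapse
#' \eqn{\lambda} are optional fixed constants, 0 by default), with a weak
#' ridge penalty on `b` to stabilise near-separable response tables. On fully
#' separable data the fit is flagged `converged = FALSE` with clamped
#' parameters and a warning.
#'
#' @param table response table from [tabulate_responses()].
#' @param guess_rate,lapse_rate fixed asymptote parameters.
#' @param ridge ridge penalty weight on `b^2` (log-likelihood units).
#' @param b_max clamp for the scale parameter; reaching it marks
#'   non-convergence.
#' @return Object of class `"psychometric_fit"`: `a`, `b`, `pse` (= `-a/b`),
#'   `slope_at_pse` (= `b/4`), `log_likelihood`, `converged`, `n_trials`.
#' @examples
#' des <- constant_stimuli_design()
#' set.seed(1)
#' tr <- simulate_tct_responses(generate_tct_trials(des), pse = 1.4, slope_b = 2)
#' fit_logistic(tabulate_responses(tr, des))
#' @export
fit_logistic <- function(table, guess_rate = 0, lapse_rate = 0,
                         ridge = 0.01, b_max = 60) {
  stopifnot(all(c("comparison_g", "n_trials", "n_stronger") %in% names(table)))
  x <- table$comparison_g
  n <- table$n_trials
  k <- table$n_stronger
  if (length(unique(x)) < 2) {
    stop("need responses at >= 2 distinct forces to fit a psychometric function")
  }
  g <- guess_rate
  l <- lapse_rate
  nll <- function(par) {
    p <- g + (1 - g - l) * stats::plogis(par[1] + par[2] * x)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -(sum(k * log(p) + (n - k) * log(1 - p))) + ridge * par[2]^2
  }
  # start from the empirical logit line
  frac <- pmin(pmax((k + 0.5) / (n + 1), 1e-3), 1 - 1e-3)
  lg <- stats::qlogis(frac)
  start_b <- max(stats::coef(stats::lm(lg ~ x))[2], 0.1)
  start_a <- mean(lg) - start_b * mean(x)
  opt <- stats::optim(c(start_a, start_b), nll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  a <- opt$par[1]
  b <- opt$par[2]
  # a table whose fractions are all 0 or 1 is perfectly separable: the
  # unpenalised MLE diverges, so the (finite) penalised optimum is reported
  # but flagged
  separable <- all(k == 0 | k == n)
  converged <- opt$convergence == 0 && abs(b) < b_max && is.finite(a) &&
    !separable
  if (!converged) {
    warning("psychometric fit did not converge (near-separable data); ",
            "parameters clamped")
    b <- sign(b) * min(abs(b), b_max)
  }
  ll <- -(nll(c(a, b)) - ridge * b^2)
  structure(
    list(
      a = a, b = b, pse = -a / b, slope_at_pse = b / 4,
      guess_rate = g, lapse_rate = l,
      log_likelihood = ll, converged = converged, n_trials = sum(n)
    ),
    class = "psychometric_fit"
  )
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(
    "Cumulative-logistic fit: a = %.3f, b = %.3f /g | PSE = %.3f g, slope at PSE = %.3f /g%s\n",
    x$a, x$b, x$pse, x$slope_at_pse,
    if (x$converged) "" else " [NOT CONVERGED]"
  ))
  invisible(x)
}

#' Slope of the psychometric function at the point of subjective equality
#'
#' The derivative of the fitted cumulative logistic where it crosses 50%
#' "stronger" responses; for a logistic with scale `b` this is exactly `b/4`
#' (fraction per gram). A steeper slope indicates greater sensitivity to the
#' force difference.
#'
#' @param fit a converged [fit_logistic()] result.
#' @return Slope at the PSE, fraction per gram.
#' @export
slope_at_pse <- function(fit) {
  stopifnot(inherits(fit, "psychometric_fit"))
  if (!fit$converged) stop("slope_at_pse requires a converged fit")
  fit$b / 4
}

#' Evaluate a fitted psychometric function
#'
#' @param fit a `"psychometric_fit"`.
#' @param x forces, grams.
#' @return Predicted fraction of "stronger" responses.
#' @export
predict_psychometric <- function(fit, x) {
  fit$guess_rate + (1 - fit$guess_rate - fit$lapse_rate) *
    stats::plogis(fit$a + fit$b * x)
}
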