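#' Stimulus ladders for the adaptive tasks
#'
#' `ladder_2pdt()` is the two-point discrimination ladder: separations from 2
#' to 90 mm (1 mm steps from 2-20, 2 mm steps from 20-40, 5 mm steps from
#' 40-90). The single-needle (0 mm) probe is the catch presentation, not a
#' ladder level. `ladder_tdt()` is the touch-detection ladder: the standard
#' von Frey monofilament forces 0.008-6.0 grams.
#'
#' @param levels strictly increasing numeric vector of stimulus magnitudes.
#' @param units units label (`"mm"` or `"g"`).
#' @return An object of class `"stimulus_ladder"`.
#' @export
stimulus_ladder <- function(levels, units) {
  if (any(diff(levels) <= 0)) stop("ladder levels must be strictly increasing")
  structure(list(levels = as.double(levels), units = units),
            class = "stimulus_ladder")
}

#' @rdname stimulus_ladder
#' @export
ladder_2pdt <- function() {
  stimulus_ladder(c(2:20, seq(22, 40, by = 2), seq(45, 90, by = 5)), "mm")
}

#' @rdname stimulus_ladder
#' @export
ladder_tdt <- function() {
  stimulus_ladder(
    c(0.008, 0.02, 0.04, 0.07, 0.16, 0.4, 0.6, 1.0, 1.4, 2.0, 4.0, 6.0), "g"
  )
}

#' @export
print.stimulus_ladder <- function(x, ...) {
  cat(sprintf("Stimulus ladder: %d levels, %g-%g %s\n",
              length(x$levels), min(x$levels), max(x$levels), x$units))
  invisible(x)
}

#' Initialise a transformed up-down (2-down/1-up) staircase
#'
#' The staircase moves one ladder level down (harder) after two consecutive
#' correct responses and one level up (easier) after a single incorrect
#' response, clamping at the ladder ends. A reversal is recorded whenever the
#' direction of an actual level change differs from the previous change's
#' direction; the reversal value is the level at which the change of
#' direction occurred. The run terminates after ten reversals (threshold =
#' mean of the last five reversal values) or after ten consecutive correct
#' trials at the smallest level (`passed_minimum`).
#'
#' @param ladder a [stimulus_ladder()].
#' @param start_level starting stimulus level; default the maximum (clearly
#'   suprathreshold). Must be a ladder member.
#' @param n_reversals_stop reversal count that ends the run (10).
#' @param n_correct_min_stop consecutive-correct count at the minimum level
#'   that ends the run (10).
#' @param reset_on_change if `TRUE` (default) the consecutive-correct counter
#'   is cleared whenever the level changes. Under the 2-down/1-up rule every
#'   level change already follows a counter reset (a completed pair or an
#'   error), so both settings yield identical trajectories; the flag is kept
#'   so the bookkeeping assumption is explicit and testable.
#' @return A `"staircase_state"` list.
#' @export
staircase_new <- function(ladder, start_level = max(ladder$levels),
                          n_reversals_stop = 10, n_correct_min_stop = 10,
                          reset_on_change = TRUE) {
  stopifnot(inherits(ladder, "stimulus_ladder"))
  idx <- match(start_level, ladder$levels)
  if (is.na(idx)) stop("start_level ", start_level, " is not a ladder level")
  structure(
    list(
      ladder = ladder, idx = idx, n_correct = 0L,
      last_direction = "none",
      history_level = numeric(0), history_correct = logical(0),
      reversal_values = numeric(0), correct_at_min = 0L,
      n_reversals_stop = n_reversals_stop,
      n_correct_min_stop = n_correct_min_stop,
      reset_on_change = reset_on_change,
      terminated = FALSE, termination_reason = NA_character_
    ),
    class = "staircase_state"
  )
}

#' Current stimulus level of a staircase
#' @param state a `"staircase_state"`.
#' @return Stimulus level (ladder units).
#' @export
staircase_level <- function(state) state$ladder$levels[state$idx]

#' Advance a staircase by one response
#'
#' Applies the 2-down/1-up rule to one trial outcome and returns the updated
#' state (including the next level to present, termination flags, and the
#' growing reversal record).
#'
#' @param state a `"staircase_state"` from [staircase_new()].
#' @param correct logical, whether the response was correct.
#' @return Updated `"staircase_state"`.
#' @export
staircase_step <- function(state, correct) {
  stopifnot(inherits(state, "staircase_state"), !state$terminated)
  lv <- state$ladder$levels
  at_min <- state$idx == 1L
  state$history_level <- c(state$history_level, lv[state$idx])
  state$history_correct <- c(state$history_correct, correct)

  move <- function(state, dir) {
    new_idx <- if (dir == "down") max(state$idx - 1L, 1L) else
      min(state$idx + 1L, length(lv))
    if (new_idx != state$idx) {
      if (state$last_direction != "none" && state$last_direction != dir) {
        state$reversal_values <- c(state$reversal_values, lv[state$idx])
      }
      state$last_direction <- dir
      state$idx <- new_idx
      if (state$reset_on_change) state$n_correct <- 0L
    }
    state
  }

  if (correct) {
    state$n_correct <- state$n_correct + 1L
    state$correct_at_min <- if (at_min) state$correct_at_min + 1L else 0L
    if (at_min && state$correct_at_min >= state$n_correct_min_stop) {
      state$terminated <- TRUE
      state$termination_reason <- "ten_correct_at_minimum"
      return(state)
    }
    if (state$n_correct >= 2L) {
      state$n_correct <- 0L
      state <- move(state, "down")
    }
  } else {
    state$n_correct <- 0L
    state$correct_at_min <- 0L
    state <- move(state, "up")
  }

  if (length(state$reversal_values) >= state$n_reversals_stop) {
    state$terminated <- TRUE
    state$termination_reason <- "ten_reversals"
  }
  state
}

#' Threshold from the last five reversal values
#'
#' @param reversal_values numeric vector of reversal levels in occurrence
#'   order (at least five).
#' @return Arithmetic mean of the final five entries.
#' @export
threshold_from_reversals <- function(reversal_values) {
  n <- length(reversal_values)
  if (n < 5) stop("need at least 5 reversals, got ", n)
  mean(reversal_values[(n - 4):n])
}

#' Run a full adaptive staircase on a simulated observer
#'
#' Iterates 2IFC trials (interval order drawn uniformly per trial, emulating
#' counterbalancing) under the 2-down/1-up rule until ten reversals or ten
#' consecutive correct trials at the minimum level. Termination is guaranteed
#' for any observer with response probabilities bounded away from 0 and 1; a
#' hard cap guards pathological observers.
#'
#' @param observer an [observer_spec()] (or any object accepted by
#'   [p_correct()]).
#' @param ladder a [stimulus_ladder()].
#' @param start_level starting level; default the ladder maximum.
#' @param seed optional integer seed for this run's substream.
#' @param max_trials hard trial cap; exceeding it is an error.
#' @inheritParams staircase_new
#' @return An object of class `"staircase_result"`: list with `history`
#'   (data frame `trial_index`, `level`, `interval_order`, `correct`),
#'   `reversal_values`, `termination_reason`, `passed_minimum`, `threshold`
#'   (`NA` when the minimum was passed), and `n_trials`.
#' @examples
#' obs <- observer_spec(threshold = 10, spread = 3)
#' res <- run_staircase(obs, ladder_2pdt(), seed = 1)
#' res$threshold
#' @export
run_staircase <- function(observer, ladder, start_level = max(ladder$levels),
                          seed = NULL, max_trials = 10000,
                          reset_on_change = TRUE) {
  runner <- function() {
    state <- staircase_new(ladder, start_level, reset_on_change = reset_on_change)
    orders <- character(0)
    n <- 0L
    while (!state$terminated) {
      n <- n + 1L
      if (n > max_trials) {
        stop("staircase failed to terminate within ", max_trials, " trials")
      }
      orders <- c(orders, sample(c("AB", "BA"), 1))
      correct <- simulate_2ifc_response(observer, staircase_level(state))
      state <- staircase_step(state, correct)
    }
    passed <- state$termination_reason == "ten_correct_at_minimum"
    structure(
      list(
        history = data.frame(
          trial_index = seq_len(n),
          level = state$history_level,
          interval_order = orders,
          correct = state$history_correct
        ),
        reversal_values = state$reversal_values,
        termination_reason = state$termination_reason,
        passed_minimum = passed,
        threshold = if (passed) NA_real_ else
          threshold_from_reversals(state$reversal_values),
        n_trials = n
      ),
      class = "staircase_result"
    )
  }
  if (is.null(seed)) runner() else with_seed(seed, runner())
}

#' @export
print.staircase_result <- function(x, ...) {
  cat(sprintf(
    "Staircase run: %d trials, %d reversals, %s (threshold %s)\n",
    x$n_trials, length(x$reversal_values), x$termination_reason,
    if (x$passed_minimum) "passed_minimum" else format(x$threshold)
  ))
  invisible(x)
}

#' Stimulus level at which a 2IFC observer is 70.7% correct
#'
#' The analytic convergence point of the 2-down/1-up rule: the level where
#' P(correct) equals `sqrt(0.5)`.
#'
#' @param observer an [observer_spec()].
#' @return Stimulus level (same units as the observer's threshold).
#' @export
level_p707 <- function(observer) {
  target <- sqrt(0.5)
  g <- observer$guess_rate
  l <- observer$lapse_rate
  f <- (target - g) / (1 - g - l)
  if (f <= 0 || f >= 1) stop("observer cannot attain 70.7% correct")
  observer$threshold + observer$spread * stats::qlogis(f)
}

#' Monte-Carlo convergence study of the staircase estimator
#'
#' Runs many seeded staircases on one observer and summarises the threshold
#' estimates against the analytic 70.7%-correct convergence point.
#'
#' @inheritParams run_staircase
#' @param n_runs number of independent runs (>= 1).
#' @param seed master seed; each run uses its own substream.
#' @return List with `thresholds` (vector, `NA` when a run passed the
#'   minimum), `mean`, `sd`, `se`, `target` (the 70.7% level),
#'   `prop_passed_minimum`, `n_runs`.
#' @export
convergence_study <- function(observer, ladder, n_runs,
                              start_level = max(ladder$levels), seed = 1) {
  stopifnot(n_runs >= 1)
  thr <- vapply(seq_len(n_runs), function(i) {
    run_staircase(observer, ladder, start_level,
                  seed = substream_seed(seed, "staircase", i))$threshold
  }, numeric(1))
  ok <- !is.na(thr)
  list(
    thresholds = thr,
    mean = mean(thr[ok]), sd = stats::sd(thr[ok]),
    se = stats::sd(thr[ok]) / sqrt(sum(ok)),
    target = level_p707(observer),
    prop_passed_minimum = mean(!ok),
    n_runs = n_runs
  )
}
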