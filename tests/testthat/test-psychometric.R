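test_that("the constant-stimuli design yields 6 x 8 x 4 = 192 trials", {
  des <- constant_stimuli_design()
  expect_equal(des$n_trials, 192)
  set.seed(1)
  tr <- generate_tct_trials(des)
  expect_equal(nrow(tr), 192)
  expect_equal(as.vector(table(tr$comparison_g)), rep(32, 6))
  per_block <- table(tr$block, tr$comparison_g)
  expect_true(all(per_block == 8))
  expect_error(constant_stimuli_design(standard_g = 1.4,
                                       comparisons_g = c(0.4, 1.4)),
               "standard")
})

test_that("response tabulation counts and validates forces", {
  tr <- data.frame(comparison_g = rep(6.0, 32), response_stronger = TRUE)
  tab <- tabulate_responses(tr)
  expect_equal(tab$fraction_stronger, 1.0)
  expect_error(tabulate_responses(tr[0, ]), "no trials")
  des <- constant_stimuli_design()
  bad <- data.frame(comparison_g = 3.3, response_stronger = TRUE)
  expect_error(tabulate_responses(bad, des), "3.3")

  set.seed(4)
  sim <- simulate_tct_responses(generate_tct_trials(des), pse = 1.4,
                                slope_b = 2)
  tab2 <- tabulate_responses(sim, des)
  # independent group-by count
  oracle <- tapply(sim$response_stronger, sim$comparison_g, sum)
  expect_equal(tab2$n_stronger, as.vector(oracle))
})

test_that("the fit recovers exact logistic fractions", {
  x <- c(0.4, 0.6, 1.0, 2.0, 4.0, 6.0)
  tab <- data.frame(comparison_g = x, n_trials = 1e6,
                    n_stronger = round(plogis(-2.8 + 2 * x) * 1e6))
  f <- fit_logistic(tab, ridge = 0)
  expect_equal(f$a, -2.8, tolerance = 1e-4)
  expect_equal(f$b, 2.0, tolerance = 1e-4)
  expect_true(f$converged)
  expect_equal(f$pse, 1.4, tolerance = 1e-4)
})

test_that("the fit matches a coarse grid-search MLE oracle", {
  des <- constant_stimuli_design()
  x <- des$comparisons_g
  grid_mle <- function(n, k) {
    a_grid <- seq(-8, 2, by = 0.05)
    b_grid <- seq(0.2, 6, by = 0.025)
    best <- c(NA, NA)
    best_ll <- -Inf
    for (a in a_grid) {
      p <- plogis(outer(b_grid, x) + a)
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      ll <- as.vector(log(p) %*% k + log(1 - p) %*% (n - k))
      j <- which.max(ll)
      if (ll[j] > best_ll) {
        best_ll <- ll[j]
        best <- c(a, b_grid[j])
      }
    }
    best
  }
  set.seed(7)
  for (i in 1:5) {
    a0 <- runif(1, -4, -1)
    b0 <- runif(1, 1, 3)
    n <- rep(32, 6)
    k <- rbinom(6, n, plogis(a0 + b0 * x))
    if (all(k == 0 | k == n)) next
    tab <- data.frame(comparison_g = x, n_trials = n, n_stronger = k)
    f <- fit_logistic(tab)
    oracle <- grid_mle(n, k)
    expect_lt(abs(f$a - oracle[1]), 0.1)
    expect_lt(abs(f$b - oracle[2]), 0.05)
  }
})

test_that("symmetric response fractions put the PSE at the standard force", {
  x <- c(0.4, 0.9, 1.4, 1.9, 2.4)
  frac <- c(0.05, 0.25, 0.5, 0.75, 0.95)
  tab <- data.frame(comparison_g = x, n_trials = 1000,
                    n_stronger = round(frac * 1000))
  f <- fit_logistic(tab)
  expect_equal(f$pse, 1.4, tolerance = 1e-6)
})

test_that("the slope at the PSE is b/4 and matches a finite difference", {
  x <- c(0.4, 0.6, 1.0, 2.0, 4.0, 6.0)
  for (b0 in c(2.0, 0.4)) {
    tab <- data.frame(comparison_g = x, n_trials = 1e6,
                      n_stronger = round(plogis(b0 * (x - 1.4)) * 1e6))
    f <- fit_logistic(tab, ridge = 0)
    expect_equal(slope_at_pse(f), b0 / 4, tolerance = 1e-3)
    h <- 1e-6
    fd <- (predict_psychometric(f, f$pse + h) -
             predict_psychometric(f, f$pse - h)) / (2 * h)
    expect_equal(fd, f$b / 4, tolerance = 1e-6)
    # F(pse) = 0.5 to machine precision
    expect_equal(predict_psychometric(f, f$pse), 0.5, tolerance = 1e-12)
  }
})

test_that("shifting all forces shifts the PSE and leaves the slope unchanged", {
  des <- constant_stimuli_design()
  set.seed(12)
  tr <- simulate_tct_responses(generate_tct_trials(des), pse = 1.4, slope_b = 2)
  tab <- tabulate_responses(tr, des)
  f0 <- fit_logistic(tab)
  shifted <- tab
  shifted$comparison_g <- tab$comparison_g + 3
  f1 <- fit_logistic(shifted)
  expect_equal(f1$pse, f0$pse + 3, tolerance = 1e-4)
  expect_equal(f1$slope_at_pse, f0$slope_at_pse, tolerance = 1e-5)
})

test_that("separable tables are flagged and slope_at_pse refuses them", {
  tab <- data.frame(comparison_g = c(0.4, 0.6, 1.0, 2.0, 4.0, 6.0),
                    n_trials = 32, n_stronger = c(0, 0, 0, 32, 32, 32))
  expect_warning(f <- fit_logistic(tab), "converge")
  expect_false(f$converged)
  expect_error(slope_at_pse(f), "converged")
  expect_error(fit_logistic(data.frame(comparison_g = 1, n_trials = 32,
                                       n_stronger = 16)), "2 distinct")
})

test_that("slope recovery error shrinks with more trials per force", {
  des32 <- constant_stimuli_design()
  des128 <- constant_stimuli_design(trials_per_comparison = 128)
  err <- function(des, seeds) {
    vapply(seeds, function(s) {
      set.seed(s)
      tr <- simulate_tct_responses(generate_tct_trials(des), pse = 1.4,
                                   slope_b = 2)
      f <- fit_logistic(tabulate_responses(tr, des))
      abs(f$slope_at_pse - 0.5)
    }, numeric(1))
  }
  e32 <- err(des32, 1:40)
  e128 <- err(des128, 1:40)
  expect_lt(median(e128), median(e32))
})
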