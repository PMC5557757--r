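test_that("identical spec and seed give bit-identical cohorts", {
  a <- generate_cohort(cohort_spec(n_asd = 12, n_td = 10, seed = 99))
  b <- generate_cohort(cohort_spec(n_asd = 12, n_td = 10, seed = 99))
  expect_identical(a$participants, b$participants)
  expect_identical(a$latent, b$latent)
  c2 <- generate_cohort(cohort_spec(n_asd = 12, n_td = 10, seed = 100))
  expect_false(identical(a$latent$trait, c2$latent$trait))
})

test_that("invalid cohort specs are rejected with the offending field named", {
  expect_error(cohort_spec(n_asd = 0), "n_asd")
  expect_error(cohort_spec(trial_amp_sd = -1), "trial_amp_sd")
  expect_error(cohort_spec(scr_amp_sd = c(asd_weak = -0.1, td_weak = 0.3,
                                          asd_strong = 1, td_strong = 0.5)),
               "scr_amp_sd")
  expect_error(cohort_spec(amp_trait_share = 0.8, amp_shared_share = 0.5),
               "amp_trait_share")
  expect_error(cohort_spec(trait_questionnaire_loading = 1.5), "loading")
})

test_that("zero trait loading decouples SCR amplitude from questionnaires", {
  coh <- generate_cohort(cohort_spec(n_asd = 10000, n_td = 10,
                                     trait_questionnaire_loading = 0,
                                     seed = 3))
  a <- coh$latent$group == "asd" & coh$latent$responder
  r <- cor(coh$latent$amp_mean_weak[a], coh$participants$srs2_total[a])
  expect_lt(abs(r), 0.1)
})

test_that("positive loading produces the closed-form within-group correlation", {
  # amp = m + s(sqrt(wt) T + ...), score = mu + sd(lambda T + sqrt(1-l^2) e)
  # => cor(amp, score) = lambda * sqrt(wt) for responders within one group
  lam <- 0.7
  wt <- 0.2
  coh <- generate_cohort(cohort_spec(n_asd = 10000, n_td = 10,
                                     trait_questionnaire_loading = lam,
                                     amp_trait_share = wt, seed = 4))
  a <- coh$latent$group == "asd" & coh$latent$responder
  r <- cor(coh$latent$amp_mean_weak[a], coh$participants$srs2_total[a])
  expect_equal(r, lam * sqrt(wt), tolerance = 0.05)
  expect_gt(r, 0)
})

test_that("default spec reproduces the configured SCR amplitude cell means", {
  coh <- generate_cohort(cohort_spec(n_asd = 8000, n_td = 8000, seed = 2))
  lat <- coh$latent[coh$latent$responder, ]
  asd <- lat$group == "asd"
  expect_equal(mean(lat$amp_mean_weak[asd]), 1.025, tolerance = 0.03)
  expect_equal(mean(lat$amp_mean_strong[asd]), 2.165, tolerance = 0.04)
  expect_equal(mean(lat$amp_mean_weak[!asd]), 0.489, tolerance = 0.03)
  expect_equal(mean(lat$amp_mean_strong[!asd]), 1.332, tolerance = 0.04)
  # within-participant weak-strong correlation equals the configured shares
  expect_equal(cor(lat$amp_mean_weak[asd], lat$amp_mean_strong[asd]),
               0.5, tolerance = 0.05)
})

test_that("observer p_correct is nondecreasing and hits the logistic midpoint", {
  set.seed(11)
  for (i in 1:20) {
    obs <- observer_spec(threshold = runif(1, 1, 50),
                         spread = runif(1, 0.1, 10),
                         guess_rate = sample(c(0, 0.5), 1),
                         lapse_rate = runif(1, 0, 0.1))
    p <- p_correct(obs, seq(0, 100, length.out = 200))
    expect_true(all(diff(p) >= -1e-12))
  }
  obs <- observer_spec(threshold = 5, spread = 2, guess_rate = 0.5,
                       lapse_rate = 0)
  expect_equal(p_correct(obs, 5), 0.75)
  expect_equal(p_correct(obs, 1e9), 1, tolerance = 1e-9)
})

test_that("empirical 2IFC proportion correct matches the formula", {
  obs <- observer_spec(threshold = 10, spread = 3, lapse_rate = 0.05)
  level <- 12
  p_true <- p_correct(obs, level)
  set.seed(42)
  n <- 10000
  hits <- mean(simulate_2ifc_response(obs, rep(level, n)))
  se <- sqrt(p_true * (1 - p_true) / n)
  expect_lt(abs(hits - p_true), 3 * se)
})

test_that("ratings are clipped to 0..10, degenerate ratings hit the mean, and strong exceeds weak", {
  m <- c(intensity = 6.4, pain = 2.2, unpleasant = 3.7)
  expect_identical(simulate_ratings(m, sd = 0),
                   c(intensity = 6L, pain = 2L, unpleasant = 4L))
  set.seed(1)
  for (i in 1:50) {
    r <- simulate_ratings(c(intensity = runif(1, -5, 15), pain = runif(1, -5, 15),
                            unpleasant = runif(1, -5, 15)), sd = 4)
    expect_true(all(r >= 0 & r <= 10))
  }
  set.seed(2)
  weak <- replicate(2000, simulate_ratings(c(intensity = 3.5, pain = 1.2,
                                             unpleasant = 2.2))["intensity"])
  strong <- replicate(2000, simulate_ratings(c(intensity = 7.5, pain = 4.2,
                                               unpleasant = 5.3))["intensity"])
  expect_gt(mean(strong), mean(weak))
})

test_that("trace simulator honours the identity, unit-kernel and linearity contracts", {
  # zero amplitudes, zero noise, zero drift: constant at the tonic level
  ev <- data.frame(onset_s = c(10, 30), offset_s = c(11, 31))
  tr0 <- simulate_sc_trace(ev, c(0, 0), tonic_level = 5.5, noise_sd = 0,
                           latency_jitter_sd = 0)
  expect_equal(unique(tr0$conductance), 5.5)

  # single event of amplitude A: post-offset max minus pre-onset value is A
  # up to one sample's discretisation of the kernel maximum
  ev1 <- data.frame(onset_s = 10, offset_s = 11)
  tr1 <- simulate_sc_trace(ev1, 1.7, tonic_level = 5, noise_sd = 0,
                           latency_jitter_sd = 0, sampling_rate = 200)
  delta <- max(tr1$conductance[tr1$time > 11]) - tr1$conductance[max(which(tr1$time < 10))]
  expect_equal(delta, 1.7, tolerance = 1e-4)

  # two events superpose linearly on the tonic level
  both <- simulate_sc_trace(ev, c(1.2, 0.8), tonic_level = 5, noise_sd = 0,
                            latency_jitter_sd = 0, duration_s = 60)
  one <- simulate_sc_trace(ev[1, ], 1.2, tonic_level = 0, noise_sd = 0,
                           latency_jitter_sd = 0, duration_s = 60)
  two <- simulate_sc_trace(ev[2, ], 0.8, tonic_level = 0, noise_sd = 0,
                           latency_jitter_sd = 0, duration_s = 60)
  expect_equal(both$conductance, 5 + one$conductance + two$conductance,
               tolerance = 1e-12)

  expect_error(simulate_sc_trace(ev1, -0.5, tonic_level = 5), "nonnegative")
  expect_error(simulate_sc_trace(data.frame(onset_s = c(1, 3), offset_s = c(4, 5)),
                                 c(1, 1), tonic_level = 5), "overlap")
})

test_that("simulated peak latencies centre on the calibration target", {
  set.seed(8)
  lats <- replicate(300, {
    ev <- data.frame(onset_s = 10, offset_s = 11)
    tr <- simulate_sc_trace(ev, 1.5, tonic_level = 5, noise_sd = 0.01)
    extract_event_scr(tr, ev)$peak_latency_s
  })
  expect_lt(abs(mean(lats) - 4.593), 1)
})

test_that("trace round-trips through the two-column CSV schema", {
  ev <- data.frame(onset_s = 5, offset_s = 6)
  tr <- simulate_sc_trace(ev, 1, tonic_level = 5, duration_s = 25)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(tr, path)
  rt <- read_trace_csv(path)
  expect_equal(rt$conductance, tr$conductance)
  expect_equal(rt$sampling_rate, tr$sampling_rate)
})
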