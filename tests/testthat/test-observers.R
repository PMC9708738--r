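test_that("observer parameter validation enforces the model's ranges", {
  expect_error(observer_params(w_prior = 1.2), "\\[0, 1\\]")
  expect_error(observer_params(lapse = 0.6), "\\[0, 0.5\\]")
  expect_error(observer_params(sigma_s = -1), ">= 0")
  expect_error(observer_params(sigma_s = 1, weber_k = 0.1), "not both")
})

test_that("veridical and pure-prior observers bracket the model", {
  sched <- build_reproduction_schedule(default_space_levels(), 6, 1)

  verid <- observer_params(w_prior = 0, sigma_s = 0, sigma_m = 0, bias = 0)
  d <- simulate_reproduction(verid, sched, 2)
  expect_equal(d$response, d$stimulus)
  expect_equal(summarize_reproduction(d)$regression_index, 0, tolerance = 1e-12)

  prior <- observer_params(w_prior = 1, sigma_s = 0, sigma_m = 0, bias = 0)
  d2 <- simulate_reproduction(prior, sched, 2)
  expect_equal(d2$response, rep(mean(sched$levels), 66))
  expect_equal(summarize_reproduction(d2)$regression_index, 1, tolerance = 1e-12)
})

test_that("running-mean prior tracks the measurement history", {
  sched <- build_reproduction_schedule(default_space_levels(), 2, 7)
  obs <- observer_params(w_prior = 0.6, prior_mode = "running_mean",
                         sigma_s = 0, sigma_m = 0, bias = 0)
  d <- simulate_reproduction(obs, sched, 1)
  S <- d$stimulus
  # independent loop oracle: noiseless measurements equal the stimuli
  expected <- numeric(length(S))
  for (i in seq_along(S)) {
    mu_p <- if (i == 1) S[1] else mean(S[seq_len(i - 1)])
    expected[i] <- 0.6 * mu_p + 0.4 * S[i]
  }
  expect_equal(d$response, expected, tolerance = 1e-12)
})

test_that("reproduction rejects non-reproduction schedules and clips at 0", {
  sched <- build_reproduction_schedule(default_space_levels(), 2, 1)
  bad <- sched; bad$task <- "discrimination"
  obs <- observer_params()
  expect_error(simulate_reproduction(obs, bad, 1), "not a reproduction")

  sinker <- observer_params(w_prior = 0, sigma_s = 0, sigma_m = 0, bias = -50)
  expect_warning(d <- simulate_reproduction(sinker, sched, 1), "clipped")
  expect_true(all(d$response == 0))
})

test_that("discrimination choices follow the psychometric law", {
  obs <- observer_params(sigma_d = 1, lapse = 0)
  # symmetric case: equal magnitudes, no lapse
  draws <- vapply(1:4000, function(i) {
    simulate_discrimination_choice(obs, 10, 10, i) == "comparison_longer"
  }, logical(1))
  expect_equal(mean(draws), 0.5, tolerance = 3 * sqrt(0.25 / 4000))

  # closed-form CDF check at one unit above the standard
  n <- 20000
  draws <- vapply(seq_len(n), function(i) {
    simulate_discrimination_choice(obs, 10, 11, i) == "comparison_longer"
  }, logical(1))
  p <- pnorm(1)
  expect_equal(mean(draws), p, tolerance = 3 * sqrt(p * (1 - p) / n))

  # step-observer limit with a lapse: comparison >> standard
  lapser <- observer_params(sigma_d = 0, lapse = 0.2)
  draws <- vapply(1:4000, function(i) {
    simulate_discrimination_choice(lapser, 10, 100, i) == "comparison_longer"
  }, logical(1))
  expect_equal(mean(draws), 1 - 0.1, tolerance = 3 * sqrt(0.09 / 4000))

  expect_error(simulate_discrimination_choice(obs, -1, 10, 1), "positive")
})

test_that("pointing cycles over the five targets with isotropic noise", {
  exact <- observer_params(sigma_m = 0)
  d <- simulate_pointing(exact, 5, 1)
  expect_equal(nrow(d), 5)
  expect_equal(pointing_error(d), rep(0, 5))
  expect_equal(nrow(unique(d[c("x_s", "y_s")])), 5)  # each target once

  noisy <- observer_params(sigma_m = 1)
  d2 <- simulate_pointing(noisy, 4000, 2)
  # mean radial error of isotropic unit noise is the Rayleigh mean
  r <- pointing_error(d2)
  ray_mean <- sqrt(pi / 2)
  ray_sd <- sqrt(2 - pi / 2)
  expect_equal(mean(r), ray_mean, tolerance = 3 * ray_sd / sqrt(4000))
})

test_that("rhythm intervals have the configured variability", {
  quiet <- observer_params(rhythm_noise = 0)
  iv <- simulate_rhythm(quiet, 10, 0.8, 1)
  expect_equal(rhythm_variability(iv), 0)

  noisy <- observer_params(rhythm_noise = 0.1)
  iv2 <- simulate_rhythm(noisy, 20000, 0.8, 2)
  # SE of the SD estimate is ~0.1/sqrt(2n) = 5e-4; allow 3 SE
  expect_equal(rhythm_variability(iv2), 0.1, tolerance = 0.015)
  expect_equal(mean(iv2), 0.8, tolerance = 3 * 0.1 / sqrt(20000))
})

test_that("simulation functions leave the caller's RNG stream untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(simulate_reproduction(
    observer_params(), build_reproduction_schedule(1:5, 2, 3), 4))
  expect_identical(.Random.seed, before)
})
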