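test_that("fresh staircases start at the prior mode", {
  qs <- quest_config_space()
  st <- quest_init(qs)
  expect_equal(quest_recommend(st, qs), 12.0, tolerance = 1e-9)

  qt <- quest_config_time()
  expect_equal(quest_recommend(quest_init(qt), qt), 1.7, tolerance = 1e-9)

  # posterior normalizes on init
  expect_equal(sum(quest_posterior(st)), 1, tolerance = 1e-9)
})

test_that("a near-flat prior yields a near-uniform posterior", {
  qc <- quest_config(guess = 10, prior_sd = 1e6, grid_min = 4, grid_max = 20,
                     grid_n = 101)
  p <- quest_posterior(quest_init(qc))
  expect_lt(max(p) - min(p), 1e-8)
})

test_that("config validation rejects impossible staircases", {
  expect_error(quest_config(guess = 25, prior_sd = 1, grid_min = 4,
                            grid_max = 20), "inside")
  expect_error(quest_config(guess = 10, prior_sd = 1, grid_min = 4,
                            grid_max = 20, grid_n = 2), ">= 3")
  expect_error(quest_config(guess = 10, prior_sd = 1, grid_min = 4,
                            grid_max = 20, min_trials = 60, max_trials = 50),
               "min_trials")
})

test_that("a single update matches the hand-multiplied posterior", {
  qc <- quest_config(guess = 10, prior_sd = 2, grid_min = 6, grid_max = 14,
                     grid_n = 3, beta = 1, delta = 0.02, gamma = 0.5)
  st <- quest_init(qc)
  grid <- c(6, 10, 14)
  st2 <- quest_update(st, 11, TRUE, qc)
  # brute-force oracle on the 3-point grid
  prior <- dnorm(grid, 10, 2)
  psi <- 0.5 + 0.48 * pnorm(1 * (11 - grid))
  manual <- prior * psi / sum(prior * psi)
  expect_equal(quest_posterior(st2), manual, tolerance = 1e-12)

  st3 <- quest_update(st, 11, FALSE, qc)
  manual3 <- prior * (1 - psi) / sum(prior * (1 - psi))
  expect_equal(quest_posterior(st3), manual3, tolerance = 1e-12)
})

test_that("updates renormalize and commute", {
  qc <- quest_config_space()
  st <- quest_init(qc)
  a <- quest_update(quest_update(st, 11, TRUE, qc), 9, FALSE, qc)
  b <- quest_update(quest_update(st, 9, FALSE, qc), 11, TRUE, qc)
  expect_equal(sum(quest_posterior(a)), 1, tolerance = 1e-9)
  expect_equal(quest_posterior(a), quest_posterior(b), tolerance = 1e-12)
  expect_equal(a$n_trials, 2L)
  expect_error(quest_update(st, Inf, TRUE, qc), "finite")
  expect_error(quest_update(st, 30, TRUE, qc), "grid bounds")
})

test_that("recommendations stay on-grid and respond to evidence", {
  qc <- quest_config_space()
  st <- quest_init(qc)
  grid <- seq(qc$grid_min, qc$grid_max, length.out = qc$grid_n)
  # repeated 'comparison longer' at a fixed high intensity pushes the
  # threshold estimate down, never off the grid
  rec <- numeric(12)
  for (i in 1:12) {
    x <- quest_recommend(st, qc)
    rec[i] <- x
    expect_true(any(abs(grid - x) < 1e-9))
    st <- quest_update(st, 12, TRUE, qc)
  }
  expect_true(all(diff(rec) <= 1e-9))
  expect_lt(rec[12], rec[1])
})

test_that("alternative placement rules stay on-grid", {
  for (rule in c("mean", "quantile")) {
    qc <- quest_config_space(rule = rule, quantile_q = 0.5)
    st <- quest_update(quest_init(qc), 11, TRUE, qc)
    x <- quest_recommend(st, qc)
    grid <- seq(qc$grid_min, qc$grid_max, length.out = qc$grid_n)
    expect_true(any(abs(grid - x) < 1e-9))
  }
})

test_that("the stopping rule honors the 50-trial floor", {
  qc <- quest_config_time()
  st <- quest_init(qc)
  st$n_trials <- 49L
  expect_false(quest_should_stop(st, qc))
  st$n_trials <- qc$max_trials
  expect_true(quest_should_stop(st, qc))

  exact50 <- quest_config_time(min_trials = 50, max_trials = 50)
  ses <- run_discrimination_session(exact50, observer_params(sigma_d = 0.3),
                                    time_standard(), 5)
  expect_equal(nrow(ses), 50)
})

test_that("the posterior-SD stop ends sessions between the bounds", {
  qc <- quest_config_space(min_trials = 10, max_trials = 200, sd_stop = 1)
  ses <- run_discrimination_session(qc, observer_params(sigma_d = 1),
                                    10, 3)
  expect_gte(nrow(ses), 10)
  expect_lt(nrow(ses), 200)
  expect_lte(quest_posterior_sd(attr(ses, "state")), 1)
})

test_that("sessions are deterministic and well-formed", {
  qc <- quest_config_space()
  obs <- observer_params(sigma_d = 1)
  a <- run_discrimination_session(qc, obs, 10, 42)
  b <- run_discrimination_session(qc, obs, 10, 42)
  expect_equal(as.data.frame(a), as.data.frame(b))
  expect_true(all(a$comparison_position %in% 1:2))
  # choice encodes 'which position was longer'
  expect_equal(a$choice == a$comparison_position, a$comparison_judged_longer)
  expect_true(all(a$standard == 10))
})

test_that("a noiseless observer drives the threshold estimate to the standard", {
  qc <- quest_config_space(min_trials = 150, max_trials = 150)
  obs <- observer_params(sigma_d = 0, lapse = 0)
  ses <- run_discrimination_session(qc, obs, 10, 8)
  final <- quest_recommend(attr(ses, "state"), qc)
  # the step observer's responses flip exactly at the standard; the
  # posterior mode should approach it within a few grid steps
  expect_lt(abs(final - 10), 0.25)
})
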