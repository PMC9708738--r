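test_that("the offset is the mean response minus the mean stimulus", {
  d <- data.frame(stimulus = c(6, 10, 14), response = c(6, 10, 14))
  expect_equal(compute_offset(d), 0)
  d$response <- d$stimulus + 0.5
  expect_equal(compute_offset(d), 0.5)

  # a time session underestimated by a constant 0.120 s
  tm <- data.frame(stimulus = rep(default_time_levels(), 6))
  tm$response <- tm$stimulus - 0.120
  expect_equal(mean(tm$stimulus), 1.535)
  expect_equal(compute_offset(tm), -0.120)
  expect_error(compute_offset(data.frame(stimulus = numeric(0),
                                         response = numeric(0))), "no trials")
})

test_that("offset correction recentres responses exactly", {
  d <- data.frame(stimulus = c(10, 10), response = c(11, 9))
  expect_equal(compute_offset(d), 0)
  expect_equal(offset_correct(d, 0), d)

  set.seed(4)
  d2 <- data.frame(stimulus = rep(default_space_levels(), 6))
  d2$response <- d2$stimulus + rnorm(66, -0.3, 1)
  corr <- offset_correct(d2, compute_offset(d2))
  expect_equal(mean(corr$response), mean(corr$stimulus), tolerance = 1e-12)
})

test_that("the response line and regression index follow OLS", {
  d <- data.frame(stimulus = c(6, 10, 14), response = c(8, 10, 12))
  line <- fit_response_line(d)
  expect_equal(unname(line["slope"]), 0.5, tolerance = 1e-12)
  expect_equal(unname(line["intercept"]), 5, tolerance = 1e-12)
  expect_equal(regression_index(unname(line["slope"])), 0.5)

  ident <- data.frame(stimulus = 1:5, response = 1:5)
  expect_equal(unname(fit_response_line(ident)["slope"]), 1, tolerance = 1e-12)
  flat <- data.frame(stimulus = 1:5, response = rep(3, 5))
  expect_equal(unname(fit_response_line(flat)["slope"]), 0, tolerance = 1e-12)

  expect_equal(regression_index(1), 0)
  expect_equal(regression_index(0), 1)
  expect_error(fit_response_line(data.frame(stimulus = c(2, 2),
                                            response = c(1, 3))), "distinct")
})

test_that("per-stimulus errors decompose into bias, CV and their RMS", {
  d <- data.frame(stimulus = c(6, 6), response = c(6.5, 7.5))
  e <- per_stimulus_errors(d, s_bar = 10)
  expect_equal(e$bias_cd, 0.1)
  expect_equal(e$cv, 0.05)            # population SD 0.5, N denominator
  expect_equal(e$rmse, sqrt(0.0125))

  # 3-4-5 identity: mean 13 (bias 0.3), population SD 4 (cv 0.4)
  d2 <- data.frame(stimulus = c(10, 10), response = c(9, 17))
  e2 <- per_stimulus_errors(d2, s_bar = 10)
  expect_equal(e2$bias_cd, 0.3)
  expect_equal(e2$cv, 0.4)
  expect_equal(e2$rmse, 0.5)

  perfect <- data.frame(stimulus = rep(c(6, 10), each = 3),
                        response = rep(c(6, 10), each = 3))
  e3 <- per_stimulus_errors(perfect)
  expect_equal(e3$bias_cd, c(0, 0))
  expect_equal(e3$cv, c(0, 0))
  expect_equal(e3$rmse, c(0, 0))

  expect_error(per_stimulus_errors(d, s_bar = 10,
                                   levels = default_space_levels()),
               "no trials")
})

test_that("error-decomposition invariants hold on random balanced sessions", {
  set.seed(11)
  for (rep in 1:5) {
    d <- data.frame(stimulus = rep(default_space_levels(), 6))
    d$response <- 0.6 * d$stimulus + 4 + rnorm(66, 0.5, 0.8)
    s <- summarize_reproduction(d)
    per <- s$per_stimulus
    # balanced design: signed bias_cd averages to zero after correction,
    # which is why the aggregate must use magnitudes
    expect_equal(mean(per$bias_cd), 0, tolerance = 1e-12)
    expect_gt(s$aggregate_bias, 0)
    # rmse identity and dominance
    expect_equal(per$rmse, sqrt(per$bias_cd^2 + per$cv^2), tolerance = 1e-12)
    expect_true(all(per$rmse >= pmax(abs(per$bias_cd), per$cv) - 1e-12))
    # slope/RI consistency
    expect_equal(s$regression_index, 1 - s$slope, tolerance = 1e-12)
    # RI unaffected by a constant added to all responses
    d2 <- d; d2$response <- d2$response + 2.3
    expect_equal(summarize_reproduction(d2)$regression_index,
                 s$regression_index, tolerance = 1e-10)
  }
})

test_that("summaries of idealized observers hit the theoretical endpoints", {
  sched <- build_reproduction_schedule(default_space_levels(), 6, 2)
  verid <- simulate_reproduction(
    observer_params(w_prior = 0, sigma_s = 0, sigma_m = 0), sched, 3)
  s <- summarize_reproduction(verid)
  expect_equal(s$offset, 0, tolerance = 1e-12)
  expect_equal(s$regression_index, 0, tolerance = 1e-12)
  expect_equal(s$aggregate_rmse, 0, tolerance = 1e-12)

  pure <- simulate_reproduction(
    observer_params(w_prior = 1, sigma_s = 0, sigma_m = 0), sched, 3)
  s2 <- summarize_reproduction(pure)
  expect_equal(s2$regression_index, 1, tolerance = 1e-12)
  expect_equal(s2$per_stimulus$cv, rep(0, 11))
})

test_that("the RI estimator recovers a moderate generative prior weight", {
  res <- run_recovery(w_values = 0.43, n_participants = 40, seed = 5)
  # MC standard error of the mean RI is about 0.008 at this n
  expect_equal(res$mean_ri, 0.43, tolerance = 0.03)
})

test_that("rms aggregation is available and dominates the absolute mean", {
  set.seed(21)
  d <- data.frame(stimulus = rep(default_space_levels(), 6))
  d$response <- 0.7 * d$stimulus + 3 + rnorm(66, 0, 1)
  s_abs <- summarize_reproduction(d, aggregate = "absolute_mean")
  s_rms <- summarize_reproduction(d, aggregate = "rms")
  expect_gte(s_rms$aggregate_bias, s_abs$aggregate_bias)
  expect_gte(s_rms$aggregate_cv, s_abs$aggregate_cv - 1e-12)
})
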