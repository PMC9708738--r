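test_that("cohort specs validate their fields by name", {
  expect_error(cohort_spec(list()), "named list")
  sp <- tiny_cohort_spec()
  bad <- sp$groups
  bad$A$n <- 0
  expect_error(cohort_spec(bad), "`n` must be >= 1")
  bad <- sp$groups
  bad$A$space <- "nope"
  expect_error(cohort_spec(bad), "`space` must be a condition_spec")
  expect_error(condition_spec(w_prior = c(0.4), bias = c(0, 0.1),
                              sigma_d = c(1, 0.1),
                              noise = list(type = "constant", value = 1)),
               "w_prior")
  expect_error(condition_spec(w_prior = c(0.4, 0.1), bias = c(0, 0.1),
                              sigma_d = c(1, 0.1),
                              noise = list(type = "banana", value = 1)),
               "noise")
})

test_that("a simulated cohort covers all six tasks for every participant", {
  cohort <- simulate_cohort(tiny_cohort_spec(), seed = 7)
  ids <- unique(cohort$participants$participant)
  expect_length(ids, 4)
  # two reproduction sessions (space, time) of 22 trials each (2 sets x 11)
  counts <- table(cohort$reproduction$participant,
                  cohort$reproduction$condition)
  expect_true(all(counts == 22))
  # adaptive sessions honor the 50-trial floor
  dcounts <- table(cohort$discrimination$participant,
                   cohort$discrimination$condition)
  expect_true(all(dcounts >= 50))
  expect_true(all(table(cohort$pointing$participant) == 50))
  expect_true(all(table(cohort$rhythm$participant) == 45))
})

test_that("cohort simulation is deterministic and substream-isolated", {
  a <- simulate_cohort(tiny_cohort_spec(), seed = 3)
  b <- simulate_cohort(tiny_cohort_spec(), seed = 3)
  expect_identical(a, b)
  # growing group B must not perturb existing participants' data
  bigger <- simulate_cohort(tiny_cohort_spec(n2 = 3), seed = 3)
  keep <- a$reproduction$participant %in% c("A_01", "A_02", "B_01", "B_02")
  expect_equal(a$reproduction[keep, ],
               bigger$reproduction[bigger$reproduction$participant %in%
                                     c("A_01", "A_02", "B_01", "B_02"), ])
})

test_that("trial logs round-trip losslessly through annotated CSV", {
  cohort <- simulate_cohort(tiny_cohort_spec(), seed = 5)
  dir <- withr::local_tempdir()
  write_trial_logs(cohort, dir)
  expect_true(file.exists(file.path(dir, "manifest.txt")))
  back <- read_trial_logs(dir)
  for (tb in c("participants", "reproduction", "discrimination", "pointing",
               "rhythm")) {
    expect_equal(back[[tb]], cohort[[tb]], ignore_attr = TRUE)
  }
  expect_identical(back$seed, cohort$seed)
})

test_that("a corrupted log directory is refused with a precise message", {
  cohort <- simulate_cohort(tiny_cohort_spec(), seed = 5)
  dir <- withr::local_tempdir()
  write_trial_logs(cohort, dir)
  # drop a data row from one table
  p <- file.path(dir, "rhythm.csv")
  writeLines(head(readLines(p), -1), p)
  expect_error(read_trial_logs(dir), "rhythm")
  expect_error(read_trial_logs(withr::local_tempdir()), "manifest")
})

test_that("the analysis suite runs end-to-end on a simulated cohort", {
  cohort <- simulate_cohort(tiny_cohort_spec(), seed = 11)
  an <- analyze_cohort(cohort, pse = "standard")
  expect_s3_class(an, "cohort_analysis")
  expect_equal(nrow(an$fits), 8)            # 4 participants x 2 conditions
  expect_true(all(an$fits$converged))
  expect_true(all(is.finite(an$fits$wf)))
  expect_equal(nrow(an$central_tendency), 8)
  expect_equal(sort(unique(an$metrics_long$metric)),
               c("bias_cd", "cv", "offset", "ri", "rmse", "wf"))
  # group tests present for RI/offset per group x condition plus MW rows
  expect_gte(nrow(an$group_tests), 8)
  dir <- withr::local_tempdir()
  write_analysis(an, dir)
  expect_setequal(list.files(dir),
                  c("fits.csv", "central_tendency.csv", "controls.csv",
                    "metrics_long.csv", "group_tests.csv"))
})

test_that("a noiseless veridical cohort yields numerically zero indices", {
  null_cond <- condition_spec(w_prior = c(0, 0), bias = c(0, 0),
                              sigma_d = c(0.3, 0),
                              noise = list(type = "constant", value = 0),
                              sigma_m = 0)
  spec <- cohort_spec(groups = list(
    Z = list(n = 2, space = null_cond, time = null_cond,
             pointing_sigma = c(0.1, 0), rhythm_noise = c(0.05, 0))
  ), n_sets = 2)
  cohort <- simulate_cohort(spec, seed = 2)
  an <- analyze_cohort(cohort)
  expect_true(all(abs(an$central_tendency$ri) < 1e-10))
  expect_true(all(abs(an$central_tendency$offset) < 1e-10))
  expect_true(all(an$central_tendency$agg_rmse < 1e-10))
})

test_that("the default cohort encodes the study's group sizes and design", {
  spec <- default_cohort_spec()
  expect_equal(vapply(spec$groups, `[[`, numeric(1), "n"),
               c(YA = 25, OA = 21))
  expect_equal(spec$n_sets, 6L)
  # prior weights and offsets sit at the groups' reported levels
  expect_equal(spec$groups$YA$space$w_prior[1], 0.426)
  expect_equal(spec$groups$OA$time$bias[1], -0.120)
})
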