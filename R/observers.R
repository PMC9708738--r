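# Parametric Bayesian central-tendency observers. Each observer combines a
# noisy sensory measurement with a prior over stimulus magnitude; the
# weight given to the prior models context dependency (regression to the
# mean). Discrimination behaviour follows a cumulative-Gaussian
# psychometric law with a lapse rate.

#' Construct generative observer parameters
#'
#' A simulated participant. On a reproduction trial with stimulus `S` the
#' observer takes a measurement `m = S + eps_s`, forms a percept
#' `p = w_prior * mu_p + (1 - w_prior) * m`, and responds
#' `R = p + bias + eps_m`, clipped at 0. Under `prior_mode =
#' "static_mean"`, `mu_p` is the mean of the schedule levels (so the
#' expected response slope is `1 - w_prior` and the expected regression
#' index equals `w_prior` exactly); under `"running_mean"` it is the mean
#' of all previous measurements (first trial: the current measurement).
#' On a two-interval discrimination trial the observer reports the
#' comparison as longer with probability
#' `lapse/2 + (1 - lapse) * pnorm((comparison - standard) / sigma_d)`.
#'
#' @param w_prior prior weight in \[0, 1\]; 0 = veridical, 1 = pure prior.
#' @param prior_mode `"static_mean"` (default) or `"running_mean"`.
#' @param sigma_s constant sensory noise SD, in stimulus units. Mutually
#'   exclusive with `weber_k`.
#' @param weber_k scalar-variability coefficient: sensory noise SD
#'   `= weber_k * S` (the standard assumption for interval timing).
#' @param sigma_m motor/execution noise SD, in stimulus units. Also the
#'   isotropic 2-D noise scale of the pointing control task.
#' @param bias constant response offset, in stimulus units (the generative
#'   analogue of the measured Offset).
#' @param lapse probability in \[0, 0.5\] of a stimulus-independent
#'   discrimination response; split equally between the two choices.
#' @param sigma_d discrimination noise SD, in stimulus units; the
#'   generative differential threshold.
#' @param rhythm_noise SD (s) of inter-press interval noise in the rhythm
#'   control task.
#' @return an `observer_params` object.
#' @export
observer_params <- function(w_prior = 0.5,
                            prior_mode = c("static_mean", "running_mean"),
                            sigma_s = NULL, weber_k = NULL,
                            sigma_m = 0, bias = 0, lapse = 0.02,
                            sigma_d = 1, rhythm_noise = 0.07) {
  prior_mode <- match.arg(prior_mode)
  if (!is.null(sigma_s) && !is.null(weber_k)) {
    stop("supply `sigma_s` (constant noise) or `weber_k` (scalar noise), not both",
         call. = FALSE)
  }
  if (is.null(sigma_s) && is.null(weber_k)) sigma_s <- 0
  for (nm in c("w_prior", "sigma_m", "bias", "lapse", "sigma_d",
               "rhythm_noise")) {
    stop_if_not_scalar_number(get(nm), nm)
  }
  if (w_prior < 0 || w_prior > 1) stop("`w_prior` must lie in [0, 1]", call. = FALSE)
  if (lapse < 0 || lapse > 0.5) stop("`lapse` must lie in [0, 0.5]", call. = FALSE)
  if (!is.null(sigma_s) && sigma_s < 0) stop("`sigma_s` must be >= 0", call. = FALSE)
  if (!is.null(weber_k) && weber_k < 0) stop("`weber_k` must be >= 0", call. = FALSE)
  if (sigma_m < 0 || sigma_d < 0 || rhythm_noise < 0) {
    stop("noise scales must be >= 0", call. = FALSE)
  }
  structure(
    list(w_prior = w_prior, prior_mode = prior_mode, sigma_s = sigma_s,
         weber_k = weber_k, sigma_m = sigma_m, bias = bias, lapse = lapse,
         sigma_d = sigma_d, rhythm_noise = rhythm_noise),
    class = "observer_params"
  )
}

#' @export
print.observer_params <- function(x, ...) {
  noise <- if (is.null(x$weber_k)) sprintf("sigma_s=%.3g", x$sigma_s)
           else sprintf("weber_k=%.3g", x$weber_k)
  cat(sprintf(
    "<observer_params> w=%.3g (%s), %s, sigma_m=%.3g, bias=%.3g, lapse=%.3g, sigma_d=%.3g\n",
    x$w_prior, x$prior_mode, noise, x$sigma_m, x$bias, x$lapse, x$sigma_d))
  invisible(x)
}

sensory_sd <- function(params, S) {
  if (!is.null(params$weber_k)) params$weber_k * S
  else rep(params$sigma_s, length(S))
}

#' Simulate a reproduction session
#'
#' Runs the generative model of [observer_params()] over every trial of a
#' reproduction schedule. Responses are clipped at 0 (negative lengths or
#' durations are meaningless); clipping events are counted and warned
#' about.
#'
#' @param params an `observer_params`.
#' @param schedule a reproduction `stimulus_schedule`.
#' @param seed integer seed.
#' @return data frame with `trial_index`, `set_index`, `stimulus`,
#'   `response`.
#' @export
simulate_reproduction <- function(params, schedule, seed) {
  stopifnot(inherits(params, "observer_params"),
            inherits(schedule, "stimulus_schedule"))
  if (schedule$task != "reproduction") {
    stop("`schedule` is not a reproduction schedule", call. = FALSE)
  }
  S <- schedule$trials$magnitude
  n <- length(S)
  with_seed(seed, {
    m <- S + stats::rnorm(n, 0, sensory_sd(params, S))
    mu_p <- if (params$prior_mode == "static_mean") {
      rep(mean(schedule$levels), n)
    } else {
      # running mean of previous measurements; first trial uses the
      # current measurement, making the first percept the measurement
      c(m[1], cumsum(m)[-n] / seq_len(n - 1))
    }
    p <- params$w_prior * mu_p + (1 - params$w_prior) * m
    R <- p + params$bias + stats::rnorm(n, 0, params$sigma_m)
    clipped <- sum(R < 0)
    if (clipped > 0) {
      warning(sprintf("%d response(s) clipped at 0", clipped), call. = FALSE)
      R <- pmax(R, 0)
    }
    data.frame(trial_index = schedule$trials$trial_index,
               set_index = schedule$trials$set_index,
               stimulus = S, response = R)
  })
}

# P(comparison judged longer) under the observer's psychometric law.
# sigma_d = 0 degenerates to a step function; an exactly equal pair with
# no lapse is resolved by a fair coin (p = 0.5).
choice_prob <- function(params, standard, comparison) {
  base <- if (params$sigma_d > 0) {
    stats::pnorm((comparison - standard) / params$sigma_d)
  } else {
    ifelse(comparison > standard, 1, ifelse(comparison < standard, 0, 0.5))
  }
  params$lapse / 2 + (1 - params$lapse) * base
}

#' Simulate one two-interval discrimination choice
#'
#' A single Bernoulli draw from the observer's psychometric law:
#' `P(comparison longer) = lapse/2 + (1 - lapse) *
#' pnorm((comparison - standard) / sigma_d)`. With `sigma_d = 0` the law
#' degenerates to a step function; an exactly equal pair with no lapse is
#' resolved by a fair coin.
#'
#' @inheritParams simulate_reproduction
#' @param standard,comparison positive magnitudes.
#' @return `"comparison_longer"` or `"standard_longer"`.
#' @export
simulate_discrimination_choice <- function(params, standard, comparison, seed) {
  stopifnot(inherits(params, "observer_params"))
  stop_if_not_scalar_number(standard, "standard")
  stop_if_not_scalar_number(comparison, "comparison")
  if (standard <= 0 || comparison <= 0) {
    stop("magnitudes must be positive", call. = FALSE)
  }
  p <- choice_prob(params, standard, comparison)
  longer <- with_seed(seed, stats::runif(1) < p)
  if (longer) "comparison_longer" else "standard_longer"
}

# Pointing target positions (cm) on the touchscreen active area
# (43.69 x 24.07 cm): the four corners 2 cm in from the frame, plus the
# screen center.
default_pointing_targets <- function() {
  w <- 43.69; h <- 24.07
  data.frame(
    x = c(2, w - 2, 2, w - 2, w / 2),
    y = c(h - 2, h - 2, 2, 2, h / 2)
  )
}

#' Simulate the pointing control task
#'
#' Targets cycle over the five screen positions (four corners 2 cm from
#' the frame plus the center); each touch is the target plus isotropic
#' zero-mean 2-D Gaussian noise with scale `sigma_m`.
#'
#' @inheritParams simulate_reproduction
#' @param n_trials number of pointing trials (the experiment used 50).
#' @param targets optional data frame with `x`, `y` target coordinates
#'   (cm) to cycle over.
#' @return data frame with `trial` (0-based), `x_s`, `y_s`, `x_r`, `y_r`.
#' @export
simulate_pointing <- function(params, n_trials, seed,
                              targets = default_pointing_targets()) {
  stopifnot(inherits(params, "observer_params"), n_trials >= 1)
  n_trials <- as.integer(n_trials)
  idx <- rep_len(seq_len(nrow(targets)), n_trials)
  with_seed(seed, {
    data.frame(
      trial = seq_len(n_trials) - 1L,
      x_s = targets$x[idx], y_s = targets$y[idx],
      x_r = targets$x[idx] + stats::rnorm(n_trials, 0, params$sigma_m),
      y_r = targets$y[idx] + stats::rnorm(n_trials, 0, params$sigma_m)
    )
  })
}

#' Simulate the rhythm synchronization control task
#'
#' Inter-press intervals are the target interval plus zero-mean Gaussian
#' noise of scale `rhythm_noise`.
#'
#' @inheritParams simulate_reproduction
#' @param n_intervals number of inter-press intervals (>= 2).
#' @param target_interval pacing interval in seconds.
#' @return numeric vector of inter-press intervals (s).
#' @export
simulate_rhythm <- function(params, n_intervals, target_interval, seed) {
  stopifnot(inherits(params, "observer_params"), n_intervals >= 2)
  stop_if_not_scalar_number(target_interval, "target_interval")
  with_seed(seed, {
    pmax(target_interval + stats::rnorm(n_intervals, 0, params$rhythm_noise), 0)
  })
}
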