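# QUEST Bayesian adaptive staircase (Watson & Pelli style): a discretized
# posterior over the discrimination threshold, updated trial by trial, with
# the next comparison placed at the posterior mode. The assumed
# psychometric family is a cumulative Gaussian on the linear stimulus axis
# with guess rate gamma (0.5 for the two-interval "which is longer"
# judgment) and lapse delta:
#   psi(x; T) = gamma + (1 - gamma - delta) * pnorm(beta * (x - T))
# The posterior is stored in log space to avoid underflow on long sessions.

#' Configure a QUEST staircase
#'
#' The experiment's staircases started at 12.0 cm with prior SD 3.6 cm
#' (space; standard 10 cm) and at 1.7 s with prior SD 0.52 s (time;
#' standard 1.535 s); [quest_config_space()] and [quest_config_time()]
#' encode these. The assumed slope defaults to `1 / (0.1 * guess-scale)`
#' via the convenience constructors; sessions run at least `min_trials`
#' (the experiment fixed a floor of 50) and stop at `max_trials` unless a
#' posterior-SD criterion `sd_stop` is supplied.
#'
#' @param guess prior threshold estimate (the staircase's starting value).
#' @param prior_sd SD of the Gaussian prior over the threshold.
#' @param grid_min,grid_max bounds of the threshold grid; must bracket
#'   `guess`.
#' @param grid_n number of grid points (>= 3).
#' @param beta assumed psychometric slope (1/units).
#' @param delta assumed lapse rate.
#' @param gamma assumed guess rate (0.5 for two-interval forced choice).
#' @param rule placement rule: `"mode"` (default), `"mean"`, or
#'   `"quantile"` with `quantile_q`.
#' @param quantile_q quantile used when `rule = "quantile"`.
#' @param min_trials,max_trials session length bounds.
#' @param sd_stop optional posterior-SD stopping criterion (same units as
#'   the grid); `NULL` disables it.
#' @return a `quest_config` object.
#' @export
quest_config <- function(guess, prior_sd, grid_min, grid_max, grid_n = 401,
                         beta = 1, delta = 0.02, gamma = 0.5,
                         rule = c("mode", "mean", "quantile"),
                         quantile_q = 0.5,
                         min_trials = 50, max_trials = 60, sd_stop = NULL) {
  rule <- match.arg(rule)
  for (nm in c("guess", "prior_sd", "grid_min", "grid_max", "beta",
               "delta", "gamma")) stop_if_not_scalar_number(get(nm), nm)
  if (!(grid_min < guess && guess < grid_max)) {
    stop("`guess` must lie strictly inside [grid_min, grid_max]", call. = FALSE)
  }
  if (grid_n < 3) stop("`grid_n` must be >= 3", call. = FALSE)
  if (prior_sd <= 0) stop("`prior_sd` must be positive", call. = FALSE)
  if (min_trials > max_trials) {
    stop("`min_trials` must not exceed `max_trials`", call. = FALSE)
  }
  if (!is.null(sd_stop)) stop_if_not_scalar_number(sd_stop, "sd_stop")
  structure(
    list(guess = guess, prior_sd = prior_sd, grid_min = grid_min,
         grid_max = grid_max, grid_n = as.integer(grid_n), beta = beta,
         delta = delta, gamma = gamma, rule = rule, quantile_q = quantile_q,
         min_trials = as.integer(min_trials),
         max_trials = as.integer(max_trials), sd_stop = sd_stop),
    class = "quest_config"
  )
}

#' @rdname quest_config
#' @param standard the discrimination standard; sets the default slope
#'   `beta = 1 / (0.1 * standard)`.
#' @param ... passed on to [quest_config()].
#' @export
quest_config_space <- function(standard = space_standard(), ...) {
  args <- utils::modifyList(
    list(guess = 12.0, prior_sd = 3.6, grid_min = 4, grid_max = 20,
         grid_n = 401, beta = 1 / (0.1 * standard)),
    list(...))
  do.call(quest_config, args)
}

#' @rdname quest_config
#' @export
quest_config_time <- function(standard = time_standard(), ...) {
  args <- utils::modifyList(
    list(guess = 1.7, prior_sd = 0.52, grid_min = 0.5, grid_max = 2.9,
         grid_n = 401, beta = 1 / (0.1 * standard)),
    list(...))
  do.call(quest_config, args)
}

quest_grid <- function(config) {
  seq(config$grid_min, config$grid_max, length.out = config$grid_n)
}

#' Initialize a QUEST staircase
#'
#' The posterior starts as the Gaussian prior `N(guess, prior_sd^2)`
#' discretized on the grid and renormalized; the history is empty.
#'
#' @param config a `quest_config`.
#' @return a `quest_state`: log-posterior over the grid, trial history,
#'   and trial count.
#' @export
quest_init <- function(config) {
  stopifnot(inherits(config, "quest_config"))
  grid <- quest_grid(config)
  lp <- stats::dnorm(grid, config$guess, config$prior_sd, log = TRUE)
  structure(
    list(log_posterior = lp - log_sum_exp(lp), grid = grid,
         history = data.frame(intensity = numeric(0), response = logical(0)),
         n_trials = 0L),
    class = "quest_state"
  )
}

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Posterior over the threshold grid
#'
#' @param state a `quest_state`.
#' @return numeric vector of posterior probabilities (sums to 1).
#' @export
quest_posterior <- function(state) {
  stopifnot(inherits(state, "quest_state"))
  p <- exp(state$log_posterior - max(state$log_posterior))
  p / sum(p)
}

#' Posterior standard deviation of the threshold
#'
#' @param state a `quest_state`.
#' @return posterior SD in grid units.
#' @export
quest_posterior_sd <- function(state) {
  p <- quest_posterior(state)
  mu <- sum(p * state$grid)
  sqrt(sum(p * (state$grid - mu)^2))
}

#' Recommend the next comparison intensity
#'
#' Under the default mode rule, the grid value maximizing the posterior;
#' ties are broken toward the grid value nearest the prior guess. The mean
#' and quantile rules snap to the nearest grid value, so recommendations
#' are always on-grid.
#'
#' @param state a `quest_state`.
#' @param config the matching `quest_config`.
#' @return a magnitude on the grid, within `[grid_min, grid_max]`.
#' @export
quest_recommend <- function(state, config) {
  stopifnot(inherits(state, "quest_state"), inherits(config, "quest_config"))
  p <- quest_posterior(state)
  g <- state$grid
  x <- switch(config$rule,
    mode = {
      mx <- max(p)
      cand <- which(p >= mx * (1 - 1e-12))
      cand[which.min(abs(g[cand] - config$guess))]
    },
    mean = which.min(abs(g - sum(p * g))),
    quantile = which(cumsum(p) >= config$quantile_q)[1]
  )
  g[x]
}

#' Bayes-update the staircase with one trial
#'
#' Multiplies the posterior by the assumed psychometric likelihood
#' `psi(intensity; T)` when the comparison was judged longer, or
#' `1 - psi` otherwise, renormalizes, and appends the trial to the
#' history. Updates commute: the posterior after a set of trials does not
#' depend on their order.
#'
#' @param state a `quest_state`.
#' @param intensity the comparison magnitude shown (within grid bounds).
#' @param response `TRUE` if the comparison was judged longer.
#' @param config the matching `quest_config`.
#' @return the updated `quest_state`.
#' @export
quest_update <- function(state, intensity, response, config) {
  stopifnot(inherits(state, "quest_state"), inherits(config, "quest_config"))
  stop_if_not_scalar_number(intensity, "intensity")
  if (intensity < config$grid_min || intensity > config$grid_max) {
    stop("`intensity` is outside the grid bounds", call. = FALSE)
  }
  stopifnot(is.logical(response), length(response) == 1L, !is.na(response))
  psi <- config$gamma +
    (1 - config$gamma - config$delta) *
      stats::pnorm(config$beta * (intensity - state$grid))
  ll <- if (response) log(psi) else log1p(-psi)
  lp <- state$log_posterior + ll
  state$log_posterior <- lp - log_sum_exp(lp)
  state$history <- rbind(state$history,
                         data.frame(intensity = intensity, response = response))
  state$n_trials <- state$n_trials + 1L
  state
}

#' Session stopping rule
#'
#' `TRUE` once at least `min_trials` have run and either `max_trials` is
#' reached or the posterior SD has dropped to `sd_stop` (when set). The
#' experiment fixed only the 50-trial floor.
#'
#' @inheritParams quest_recommend
#' @return logical.
#' @export
quest_should_stop <- function(state, config) {
  stopifnot(inherits(state, "quest_state"), inherits(config, "quest_config"))
  if (state$n_trials < config$min_trials) return(FALSE)
  if (state$n_trials >= config$max_trials) return(TRUE)
  !is.null(config$sd_stop) && quest_posterior_sd(state) <= config$sd_stop
}

#' Run a full adaptive discrimination session
#'
#' Loops recommend -> observer choice -> Bayes update until the stopping
#' rule fires. The comparison's position (first or second interval) is
#' randomized per trial; the recorded choice is "which position was
#' longer" (1 or 2), mapped internally to `comparison_judged_longer`.
#'
#' @param config a `quest_config`.
#' @param observer an `observer_params` describing the simulated
#'   participant.
#' @param standard the standard magnitude (10 cm or 1.535 s).
#' @param seed integer seed; identical seeds give identical sessions.
#' @return data frame of class `discrimination_session` with columns
#'   `trial_index`, `standard`, `comparison`, `comparison_position`,
#'   `choice`, `comparison_judged_longer`; the final `quest_state` is
#'   attached as attribute `"state"`.
#' @export
run_discrimination_session <- function(config, observer, standard, seed) {
  stopifnot(inherits(config, "quest_config"),
            inherits(observer, "observer_params"))
  stop_if_not_scalar_number(standard, "standard")
  with_seed(seed, {
    state <- quest_init(config)
    rows <- vector("list", config$max_trials)
    repeat {
      x <- quest_recommend(state, config)
      pos <- sample.int(2L, 1L)
      longer <- stats::runif(1) < choice_prob(observer, standard, x)
      state <- quest_update(state, x, longer, config)
      rows[[state$n_trials]] <- data.frame(
        trial_index = state$n_trials - 1L, standard = standard,
        comparison = x, comparison_position = pos,
        choice = if (longer) pos else 3L - pos,
        comparison_judged_longer = longer
      )
      if (quest_should_stop(state, config)) break
    }
    out <- do.call(rbind, rows[seq_len(state$n_trials)])
    attr(out, "state") <- state
    class(out) <- c("discrimination_session", class(out))
    out
  })
}
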