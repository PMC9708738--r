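# Reproduction-task metric suite: Offset, offset-corrected responses,
# regression index (1 - response slope), and the per-stimulus
# BiasCD/CV/RMSE error decomposition, all normalized by the mean stimulus.

check_repro_trials <- function(trials) {
  stopifnot(is.data.frame(trials),
            all(c("stimulus", "response") %in% names(trials)))
  if (nrow(trials) == 0L) stop("no trials supplied", call. = FALSE)
  if (any(!is.finite(trials$stimulus)) || any(!is.finite(trials$response))) {
    stop("non-finite stimulus or response", call. = FALSE)
  }
  if (any(trials$stimulus <= 0)) stop("stimuli must be positive", call. = FALSE)
  invisible(trials)
}

#' Reproduction offset
#'
#' Mean response minus mean stimulus over a session: the participant's
#' constant tendency to over- or underestimate, independent of stimulus
#' history.
#'
#' @param trials data frame with `stimulus` and `response` columns.
#' @return the offset, in stimulus units.
#' @export
compute_offset <- function(trials) {
  check_repro_trials(trials)
  mean(trials$response) - mean(trials$stimulus)
}

#' Offset-correct responses
#'
#' Subtracts a constant offset from every response (`R' = R - Offset`).
#' With the session's own offset, the corrected mean response equals the
#' mean stimulus exactly.
#'
#' @inheritParams compute_offset
#' @param offset finite scalar, typically [compute_offset()] of the same
#'   trials.
#' @return the trials with `response` replaced by `R - offset`.
#' @export
offset_correct <- function(trials, offset) {
  check_repro_trials(trials)
  stop_if_not_scalar_number(offset, "offset")
  trials$response <- trials$response - offset
  trials
}

#' Ordinary least-squares response line
#'
#' Regresses responses on stimuli; the slope feeds the regression index.
#'
#' @inheritParams compute_offset
#' @return named numeric vector `c(slope, intercept)`.
#' @export
fit_response_line <- function(trials) {
  check_repro_trials(trials)
  if (length(unique(trials$stimulus)) < 2L) {
    stop("need >= 2 distinct stimulus values to fit a line", call. = FALSE)
  }
  co <- stats::coef(stats::lm(response ~ stimulus, data = trials))
  c(slope = unname(co[2]), intercept = unname(co[1]))
}

#' Regression index
#'
#' The difference in slope between the identity line and the fitted
#' response line: `1 - slope`. 0 means veridical reproduction; 1 means
#' complete regression to the stimulus mean.
#'
#' @param slope fitted response slope.
#' @return dimensionless regression index.
#' @export
regression_index <- function(slope) {
  stop_if_not_scalar_number(slope, "slope")
  1 - slope
}

#' Per-stimulus accuracy/precision error decomposition
#'
#' For each stimulus level `S_i` of an offset-corrected session:
#' accuracy error `BiasCD_i = (R_Mi - S_i) / S_bar` (mean response minus
#' stimulus, normalized by the mean stimulus), precision error
#' `CV_i = sd(R'_i) / S_bar` with the population (N-denominator) SD, and
#' `RMSE_i = sqrt(BiasCD_i^2 + CV_i^2)`.
#'
#' @param trials offset-corrected trials (`stimulus`, `response`).
#' @param s_bar mean stimulus; defaults to `mean(trials$stimulus)`.
#' @param levels optional full vector of design levels; an error is
#'   raised if any has no trials.
#' @return data frame with one row per level: `level`, `n`,
#'   `response_mean`, `bias_cd`, `cv`, `rmse`.
#' @export
per_stimulus_errors <- function(trials, s_bar = mean(trials$stimulus),
                                levels = NULL) {
  check_repro_trials(trials)
  stop_if_not_scalar_number(s_bar, "s_bar")
  if (s_bar <= 0) stop("`s_bar` must be positive", call. = FALSE)
  present <- sort(unique(trials$stimulus))
  if (!is.null(levels)) {
    missing <- setdiff(round(levels, 12), round(present, 12))
    if (length(missing) > 0L) {
      stop(sprintf("level(s) with no trials: %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
  }
  out <- do.call(rbind, lapply(present, function(s) {
    r <- trials$response[trials$stimulus == s]
    bias <- (mean(r) - s) / s_bar
    cv <- sd_pop(r) / s_bar
    data.frame(level = s, n = length(r), response_mean = mean(r),
               bias_cd = bias, cv = cv, rmse = sqrt(bias^2 + cv^2))
  }))
  rownames(out) <- NULL
  out
}

#' Summarize one reproduction session
#'
#' The full metric pipeline for one participant and condition: offset,
#' offset correction, OLS response line, regression index, per-stimulus
#' BiasCD/CV/RMSE, and their aggregates across levels.
#'
#' On a balanced design the equal-weight mean of the *signed* `bias_cd`
#' values is algebraically zero after offset correction, so the aggregate
#' accuracy error uses magnitudes: `aggregate_bias = mean(|bias_cd_i|)`
#' (default), with a root-mean-square alternative. `aggregate_cv` and
#' `aggregate_rmse` average the (already non-negative) per-level values
#' the same way.
#'
#' @param trials raw (uncorrected) reproduction trials for one
#'   participant and condition.
#' @param levels optional design levels passed to
#'   [per_stimulus_errors()].
#' @param aggregate `"absolute_mean"` (default) or `"rms"`.
#' @return a `central_tendency_summary`: list with `offset`, `slope`,
#'   `intercept`, `regression_index`, `mean_stimulus`, `per_stimulus`
#'   (data frame), `aggregate_bias`, `aggregate_cv`, `aggregate_rmse`,
#'   `n_trials`.
#' @export
summarize_reproduction <- function(trials, levels = NULL,
                                   aggregate = c("absolute_mean", "rms")) {
  aggregate <- match.arg(aggregate)
  check_repro_trials(trials)
  offset <- compute_offset(trials)
  corrected <- offset_correct(trials, offset)
  line <- fit_response_line(corrected)
  per <- per_stimulus_errors(corrected, s_bar = mean(trials$stimulus),
                             levels = levels)
  agg <- switch(aggregate,
    absolute_mean = function(v) mean(abs(v)),
    rms = function(v) sqrt(mean(v^2)))
  structure(
    list(offset = offset, slope = unname(line["slope"]),
         intercept = unname(line["intercept"]),
         regression_index = regression_index(unname(line["slope"])),
         mean_stimulus = mean(trials$stimulus), per_stimulus = per,
         aggregate_bias = agg(per$bias_cd), aggregate_cv = agg(per$cv),
         aggregate_rmse = agg(per$rmse), n_trials = nrow(trials),
         aggregate_rule = aggregate),
    class = "central_tendency_summary"
  )
}

#' @export
print.central_tendency_summary <- function(x, ...) {
  cat(sprintf(
    paste0("<central_tendency_summary> offset=%.4g, slope=%.4g, RI=%.4g\n",
           "  aggregate bias=%.4g cv=%.4g rmse=%.4g (%s over %d levels, %d trials)\n"),
    x$offset, x$slope, x$regression_index, x$aggregate_bias, x$aggregate_cv,
    x$aggregate_rmse, x$aggregate_rule, nrow(x$per_stimulus), x$n_trials))
  invisible(x)
}
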