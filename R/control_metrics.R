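# Control-task metrics: pointing execution error (motor precision on the
# touchscreen) and rhythm synchronization variability.

#' Pointing execution error
#'
#' Euclidean distance between the on-screen target and the touch, in cm.
#' Accepts either four coordinate vectors or a data frame with columns
#' `x_s`, `y_s`, `x_r`, `y_r` (as produced by [simulate_pointing()]).
#'
#' @param x_s,y_s target coordinates (cm), or a data frame as `x_s`.
#' @param x_r,y_r touch coordinates (cm).
#' @return numeric vector of per-trial distances.
#' @export
pointing_error <- function(x_s, y_s = NULL, x_r = NULL, y_r = NULL) {
  if (is.data.frame(x_s)) {
    df <- x_s
    stopifnot(all(c("x_s", "y_s", "x_r", "y_r") %in% names(df)))
    return(pointing_error(df$x_s, df$y_s, df$x_r, df$y_r))
  }
  stopifnot(is.numeric(x_s), is.numeric(y_s), is.numeric(x_r), is.numeric(y_r),
            all(is.finite(c(x_s, y_s, x_r, y_r))))
  sqrt((x_r - x_s)^2 + (y_r - y_s)^2)
}

#' Participant-level pointing summary
#'
#' Median pointing error over trials, the study's per-participant summary
#' (group comparisons are rank-based).
#'
#' @param trials data frame with `x_s`, `y_s`, `x_r`, `y_r`.
#' @return median distance (cm).
#' @export
pointing_summary <- function(trials) {
  stats::median(pointing_error(trials))
}

#' Rhythm synchronization variability
#'
#' Population (N-denominator) standard deviation of the inter-keypress
#' intervals, per the task's printed formula.
#'
#' @param intervals numeric vector of inter-press intervals (s), length
#'   >= 2, all positive.
#' @return SD in seconds.
#' @export
rhythm_variability <- function(intervals) {
  stopifnot(is.numeric(intervals))
  if (length(intervals) < 2L) {
    stop("need >= 2 intervals to compute variability", call. = FALSE)
  }
  if (any(!is.finite(intervals)) || any(intervals <= 0)) {
    stop("intervals must be finite and positive", call. = FALSE)
  }
  sd_pop(intervals)
}

#' Inter-press intervals from keypress timestamps
#'
#' Differences of consecutive timestamps; only intervals after the
#' participant starts pressing enter the computation (the initial
#' watch-and-internalize appearances produce no presses).
#'
#' @param timestamps increasing keypress times (s).
#' @return numeric vector of intervals.
#' @export
press_intervals <- function(timestamps) {
  stopifnot(is.numeric(timestamps), length(timestamps) >= 2L)
  d <- diff(timestamps)
  if (any(d <= 0)) stop("timestamps must be strictly increasing", call. = FALSE)
  d
}
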