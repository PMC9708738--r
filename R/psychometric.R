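# Maximum-likelihood cumulative-Gaussian psychometric fitting. The
# differential threshold is the fitted SD; perceptual acuity is the Weber
# fraction, threshold / standard.

#' Fit a cumulative-Gaussian psychometric function
#'
#' Maximum-likelihood fit of
#' `P(comparison judged longer | c) = lapse/2 + (1 - lapse) *
#' pnorm((c - mu) / sigma)` to two-interval discrimination data. `mu` is
#' the point of subjective equality and `sigma` the differential
#' threshold. Optimization uses a fixed multi-start grid followed by
#' `optim(method = "L-BFGS-B")`, so fits are deterministic given the data.
#' Non-identifiable inputs (a single comparison level, or responses all in
#' one category) return `converged = FALSE` with a diagnostic message
#' rather than a silent number.
#'
#' @param trials data frame with columns `comparison` (magnitude) and
#'   `comparison_judged_longer` (logical or 0/1), e.g. the output of
#'   [run_discrimination_session()].
#' @param lapse either a fixed lapse rate in \[0, 0.1\] (default 0.01; a
#'   tiny fixed lapse stabilizes the MLE against stray errors — use 0 for
#'   the plain cumulative Gaussian) or `"free"` to estimate it within
#'   \[0, 0.1\].
#' @param pse `"free"` (default) to estimate the PSE, or a fixed
#'   magnitude (typically the standard) to constrain it. Adaptive
#'   staircases concentrate comparisons near one point, where a free-PSE
#'   fit identifies the threshold only weakly; constraining the PSE to
#'   the standard restores identifiability when the observer is known to
#'   be unbiased.
#' @return a `psychometric_fit`: list with `mu`, `sigma`, `lapse`,
#'   `log_lik`, `n_trials`, `converged`, `message`.
#' @export
fit_cumulative_gaussian <- function(trials, lapse = 0.01, pse = "free") {
  stopifnot(is.data.frame(trials),
            all(c("comparison", "comparison_judged_longer") %in% names(trials)))
  x_all <- trials$comparison
  y_all <- as.logical(trials$comparison_judged_longer)
  stopifnot(all(is.finite(x_all)), !anyNA(y_all))
  n_trials <- length(x_all)

  fail <- function(msg) {
    structure(list(mu = NA_real_, sigma = NA_real_, lapse = NA_real_,
                   log_lik = NA_real_, n_trials = n_trials,
                   converged = FALSE, message = msg),
              class = "psychometric_fit")
  }
  # aggregate to (level, n longer, n trials)
  agg <- stats::aggregate(cbind(k = y_all, n = rep(1, n_trials)),
                          by = list(x = x_all), FUN = sum)
  if (nrow(agg) < 2L) return(fail("only one distinct comparison level"))
  if (sum(agg$k) == 0L || sum(agg$k) == sum(agg$n)) {
    return(fail("all responses in one category; threshold non-identifiable"))
  }

  free_lapse <- identical(lapse, "free")
  if (!free_lapse) {
    stop_if_not_scalar_number(lapse, "lapse")
    if (lapse < 0 || lapse > 0.1) stop("fixed `lapse` must lie in [0, 0.1]",
                                       call. = FALSE)
  }
  free_pse <- identical(pse, "free")
  if (!free_pse) stop_if_not_scalar_number(pse, "pse")

  span <- diff(range(agg$x))
  nll <- function(par) {
    i <- 1L
    if (free_pse) { mu <- par[i]; i <- i + 1L } else mu <- pse
    sigma <- exp(par[i]); i <- i + 1L
    lam <- if (free_lapse) par[i] else lapse
    p <- lam / 2 + (1 - lam) * stats::pnorm((agg$x - mu) / sigma)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(agg$k * log(p) + (agg$n - agg$k) * log1p(-p))
  }

  sg_starts <- log(pmax(span * c(0.05, 0.2, 0.5, 1), 1e-6))
  starts <- if (free_pse) {
    mu_starts <- unique(c(min(agg$x), stats::median(rep(agg$x, agg$n)),
                          sum(agg$x * agg$n) / sum(agg$n), max(agg$x)))
    expand.grid(mu = mu_starts, ls = sg_starts)
  } else {
    data.frame(ls = sg_starts)
  }
  lower <- c(if (free_pse) min(agg$x) - 2 * span,
             log(max(span, 1e-6) * 1e-4))
  upper <- c(if (free_pse) max(agg$x) + 2 * span,
             log(max(span, 1e-6) * 20))
  if (free_lapse) {
    starts$lam <- 0.02
    lower <- c(lower, 0); upper <- c(upper, 0.1)
  }

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(as.numeric(starts[i, ]), nll, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) return(fail("optimization failed from every start"))

  i <- 1L
  if (free_pse) { mu_hat <- best$par[i]; i <- i + 1L } else mu_hat <- pse
  sigma_hat <- exp(best$par[i]); i <- i + 1L
  lapse_hat <- if (free_lapse) best$par[i] else lapse
  structure(
    list(mu = mu_hat, sigma = sigma_hat, lapse = lapse_hat,
         log_lik = -best$value, n_trials = n_trials,
         converged = TRUE, message = "ok"),
    class = "psychometric_fit"
  )
}

#' @export
print.psychometric_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf(
      "<psychometric_fit> mu=%.4g sigma=%.4g lapse=%.3g logLik=%.2f (n=%d)\n",
      x$mu, x$sigma, x$lapse, x$log_lik, x$n_trials))
  } else {
    cat(sprintf("<psychometric_fit> NOT converged: %s (n=%d)\n",
                x$message, x$n_trials))
  }
  invisible(x)
}

#' Weber fraction
#'
#' The differential threshold divided by the standard magnitude; the
#' study's index of perceptual acuity.
#'
#' @param threshold differential threshold (fitted psychometric SD), >= 0.
#' @param standard standard magnitude, > 0.
#' @return dimensionless ratio `threshold / standard`.
#' @examples
#' weber_fraction(1.0, 10) # 0.1
#' @export
weber_fraction <- function(threshold, standard) {
  stopifnot(is.numeric(threshold), is.numeric(standard))
  if (any(standard <= 0)) stop("`standard` must be positive", call. = FALSE)
  if (any(threshold < 0)) stop("`threshold` must be >= 0", call. = FALSE)
  threshold / standard
}
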