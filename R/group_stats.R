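# Group-level statistics used on the derived metrics: one-sample t tests
# with Cohen's d, and the Mann-Whitney U test (normal approximation with
# tie correction and continuity correction; exact enumeration for small
# samples). Implemented from the definitions so printed statistics can be
# audited from summary values alone.

new_group_comparison <- function(method, statistic, df = NULL, n = NULL,
                                 p_value, effect_size, alternative) {
  structure(
    list(method = method, statistic = statistic, df = df, n = n,
         p_value = p_value, effect_size = effect_size,
         alternative = alternative),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  stat <- paste(sprintf("%s=%.4g", names(x$statistic), x$statistic),
                collapse = ", ")
  dfs <- if (!is.null(x$df)) sprintf(", df=%s", paste(x$df, collapse = ","))
         else ""
  cat(sprintf("<group_comparison> %s: %s%s, p=%.4g, effect=%.4g (%s)\n",
              x$method, stat, dfs, x$p_value, x$effect_size, x$alternative))
  invisible(x)
}

#' One-sample t test with Cohen's d
#'
#' `t = (M - mu0) / (SD / sqrt(n))` with the sample (n-1) SD, `df = n-1`,
#' and standardized effect size `d = (M - mu0) / SD`.
#'
#' @param values numeric sample, length >= 2, with nonzero SD.
#' @param mu0 null value (default 0).
#' @param alternative `"two.sided"` (default), `"less"`, or `"greater"`.
#' @return a `group_comparison` with the t statistic, df, p value, and
#'   Cohen's d.
#' @export
one_sample_t <- function(values, mu0 = 0,
                         alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(is.numeric(values), all(is.finite(values)))
  if (length(values) < 2L) stop("need n >= 2", call. = FALSE)
  s <- stats::sd(values)
  if (s == 0) stop("sample SD is zero; t is undefined", call. = FALSE)
  one_sample_t_from_summary(mean(values), s, length(values), mu0, alternative)
}

#' One-sample t test from summary statistics
#'
#' The same computation as [one_sample_t()] but from a reported mean, SD
#' and n, so printed group statistics can be recomputed from a summary
#' table without the raw data.
#'
#' @param M sample mean.
#' @param SD sample (n-1 denominator) standard deviation, > 0.
#' @param n sample size, >= 2.
#' @inheritParams one_sample_t
#' @return a `group_comparison`.
#' @examples
#' # d and t from a group's summary cell
#' one_sample_t_from_summary(M = 0.426, SD = 0.195, n = 25)
#' @export
one_sample_t_from_summary <- function(M, SD, n, mu0 = 0,
                                      alternative = c("two.sided", "less",
                                                      "greater")) {
  alternative <- match.arg(alternative)
  stop_if_not_scalar_number(M, "M")
  stop_if_not_scalar_number(SD, "SD")
  if (SD <= 0) stop("`SD` must be positive", call. = FALSE)
  if (n < 2) stop("need n >= 2", call. = FALSE)
  t <- (M - mu0) / (SD / sqrt(n))
  df <- n - 1
  p <- switch(alternative,
    two.sided = 2 * stats::pt(-abs(t), df),
    less = stats::pt(t, df),
    greater = stats::pt(t, df, lower.tail = FALSE))
  new_group_comparison("one_sample_t", c(t = t), df = df, n = n,
                       p_value = p, effect_size = (M - mu0) / SD,
                       alternative = alternative)
}

# Exact null distribution of U1 by enumeration of all choose(N, n1)
# assignments of the pooled (mid-)ranks to group 1.
mw_exact_dist <- function(r, n1) {
  N <- length(r)
  sets <- utils::combn(N, n1)
  apply(sets, 2, function(idx) sum(r[idx])) - n1 * (n1 + 1) / 2
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples. `U` counts, over all
#' cross-group pairs, the times an `x` value exceeds a `y` value, with
#' half credit for ties. For `n1 + n2 <= 12` (default) the p value is
#' computed by exact enumeration of all rank assignments; otherwise by
#' the normal approximation with tie-corrected variance and a 0.5
#' continuity correction. The reported effect size is the rank-biserial
#' correlation `1 - 2U/(n1 n2)`.
#'
#' @param x,y numeric samples (non-empty).
#' @param alternative `"two.sided"` (default), `"less"`, or `"greater"`.
#' @param exact force (`TRUE`) or suppress (`FALSE`) exact enumeration;
#'   `NULL` chooses by total sample size.
#' @return a `group_comparison` with `U` (and `z` for the approximate
#'   test), sample sizes, p value, and rank-biserial effect size.
#' @export
mann_whitney <- function(x, y,
                         alternative = c("two.sided", "less", "greater"),
                         exact = NULL) {
  alternative <- match.arg(alternative)
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) == 0L || length(y) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))                      # midranks give ties 0.5 credit
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (is.null(exact)) exact <- N <= 12

  if (exact) {
    dist <- mw_exact_dist(r, n1)
    ge <- mean(dist >= U); le <- mean(dist <= U)
    p <- switch(alternative,
      two.sided = min(1, 2 * min(ge, le)),
      greater = ge,
      less = le)
    return(new_group_comparison("mann_whitney_exact", c(U = U),
                                n = c(n1 = n1, n2 = n2), p_value = p,
                                effect_size = 1 - 2 * U / (n1 * n2),
                                alternative = alternative))
  }

  mu <- n1 * n2 / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  v <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (v <= 0) stop("all pooled values tied; U variance is zero", call. = FALSE)
  cc <- 0.5
  z <- switch(alternative,
    two.sided = sign(U - mu) * max(0, abs(U - mu) - cc) / sqrt(v),
    greater = (U - mu - cc) / sqrt(v),
    less = (U - mu + cc) / sqrt(v))
  p <- switch(alternative,
    two.sided = 2 * stats::pnorm(-abs(z)),
    greater = stats::pnorm(z, lower.tail = FALSE),
    less = stats::pnorm(z))
  new_group_comparison("mann_whitney", c(U = U, z = z),
                       n = c(n1 = n1, n2 = n2), p_value = min(1, p),
                       effect_size = 1 - 2 * U / (n1 * n2),
                       alternative = alternative)
}
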