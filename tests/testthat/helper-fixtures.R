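# Shared fixtures, all built in code.

# A tiny two-group cohort spec for fast end-to-end tests.
tiny_cohort_spec <- function(n1 = 2, n2 = 2) {
  sp <- condition_spec(w_prior = c(0.4, 0.1), bias = c(-0.05, 0.05),
                       sigma_d = c(1, 0.2),
                       noise = list(type = "constant", value = 1.5),
                       sigma_m = 0.4)
  tm <- condition_spec(w_prior = c(0.3, 0.1), bias = c(-0.05, 0.03),
                       sigma_d = c(0.3, 0.05),
                       noise = list(type = "weber", value = 0.15),
                       sigma_m = 0.05)
  cohort_spec(groups = list(
    A = list(n = n1, space = sp, time = tm,
             pointing_sigma = c(0.17, 0.03), rhythm_noise = c(0.06, 0.01)),
    B = list(n = n2, space = sp, time = tm,
             pointing_sigma = c(0.21, 0.03), rhythm_noise = c(0.08, 0.01))
  ), n_sets = 2)
}

# Binomial psychometric dataset at fixed comparison levels.
make_psychometric_data <- function(levels, mu, sigma, n_per_level,
                                   lapse = 0, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(levels, function(x) {
    p <- lapse / 2 + (1 - lapse) * pnorm((x - mu) / sigma)
    data.frame(comparison = x,
               comparison_judged_longer = runif(n_per_level) < p)
  }))
}

# Dense brute-force (mu, sigma) grid maximum of the binomial
# log-likelihood; the independent oracle for the MLE.
grid_search_psychometric <- function(trials, mu_grid, sigma_grid,
                                     lapse = 0) {
  agg <- aggregate(cbind(k = trials$comparison_judged_longer,
                         n = rep(1, nrow(trials))),
                   by = list(x = trials$comparison), FUN = sum)
  best <- list(ll = -Inf)
  for (mu in mu_grid) for (sg in sigma_grid) {
    p <- lapse / 2 + (1 - lapse) * pnorm((agg$x - mu) / sg)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    ll <- sum(agg$k * log(p) + (agg$n - agg$k) * log1p(-p))
    if (ll > best$ll) best <- list(ll = ll, mu = mu, sigma = sg)
  }
  best
}
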