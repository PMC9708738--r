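# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `code`,
#' and restores the previous state on exit, so simulation functions never
#' perturb the user's random stream.
#'
#' @param seed single integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  code
}

# Deterministically derive a substream seed from a master seed and integer
# keys (participant index, task index, ...). Adding a participant or task
# never perturbs another's stream. Modulus < 2^31 keeps the result a valid
# R integer seed.
mix_seed <- function(seed, ...) {
  keys <- c(...)
  s <- as.numeric(seed) %% 2147483629
  for (k in keys) {
    s <- (s * 69069 + as.numeric(k) + 1) %% 2147483629
  }
  as.integer(s)
}

# Population (N-denominator) standard deviation.
sd_pop <- function(x) {
  sqrt(mean((x - mean(x))^2))
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}
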