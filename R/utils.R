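#' @keywords internal
"_PACKAGE"

# Classed conditions so callers (and the test suite) can distinguish bad
# configuration from bad data from numerical failure.
stop_config <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("mc_config_error", "mc_error")))
}

stop_schema <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("mc_schema_error", "mc_error")))
}

stop_data <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("mc_data_error", "mc_error")))
}

stop_convergence <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("mc_convergence_error", "mc_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is untouched. seed = NULL runs under the ambient RNG.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic per-stage seed derived from a manifest seed, so every stage
# draws from its own named substream (kept below 2^31).
substream_seed <- function(seed, name) {
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 31 + k) %% 2147480009
  as.integer((as.numeric(seed) %% 2147480009 * 7919 + h) %% 2147480009)
}

# 32-bit FNV-1a over a character scalar, as 8 hex digits; used for config
# hashes in run manifests.
fnv1a32 <- function(x) {
  h <- 2166136261
  for (k in utf8ToInt(x)) {
    h <- h - (h %% 256) + bitwXor(h %% 256, k %% 256)   # xor low byte
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

# Moment matching for a log-normal: given the target mean m and sd s of the
# concentration itself, return (mu, sigma) of log(X).
lognormal_params <- function(m, s) {
  if (m <= 0) stop_config("log-normal moment matching needs mean > 0, got %g", m)
  sigma2 <- log(1 + (s / m)^2)
  c(mu = log(m) - sigma2 / 2, sigma = sqrt(sigma2))
}

# Stationary AR(1) noise: `n_series` independent series of length `n_time`,
# marginal sd `sigma`, lag-1 correlation `rho`. Returned as a matrix
# (series x time).
ar1_noise <- function(n_series, n_time, rho, sigma) {
  z <- matrix(stats::rnorm(n_series * n_time), n_series, n_time)
  e <- matrix(0, n_series, n_time)
  e[, 1] <- sigma * z[, 1]
  if (n_time > 1) {
    innov_sd <- sigma * sqrt(1 - rho^2)
    for (t in 2:n_time) e[, t] <- rho * e[, t - 1] + innov_sd * z[, t]
  }
  e
}

# Format a numeric for CSV so read -> write -> read is lossless.
format_full <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("")
    sprintf("%.17g", v)
  }, character(1))
  out
}
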