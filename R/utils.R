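# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Classed conditions so callers can distinguish configuration problems,
# malformed data, and model failures.
stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("cfmrd_config_error", "cfmrd_error")))
}

stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("cfmrd_data_error", "cfmrd_error")))
}

stop_model <- function(...) {
  stop(errorCondition(paste0(...), class = c("cfmrd_model_error", "cfmrd_error")))
}

# log(exp(a) + exp(b)) without overflow, vectorized.
logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  # both -Inf: log(0 + 0)
  out <- m + log1p(exp(pmin(a, b) - m))
  out[!is.finite(m)] <- -Inf
  out
}

# Deterministic positional hash in [0, 1): used by the synthetic genome so
# covariate tracks are a pure function of (chrom, position, salt) and never
# depend on stored state or the RNG stream.
position_hash <- function(chrom_index, pos, salt = 0) {
  x <- sin(pos * 12.9898e-3 + chrom_index * 78.233 + salt * 37.719) * 43758.5453
  x - floor(x)
}
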