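# Internal helpers: condition classes and seeded RNG scopes.

dp_stop <- function(class, msg, call. = FALSE) {
  stop(structure(
    class = c(paste0("deafPU_", class, "_error"), "deafPU_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

stop_config <- function(msg) dp_stop("config", msg)
stop_data   <- function(msg) dp_stop("data", msg)
stop_domain <- function(msg) dp_stop("domain", msg)
stop_usage  <- function(msg) dp_stop("usage", msg)

# All stochastic operations take an explicit seed and run inside a local RNG
# scope, so the caller's .Random.seed is never consumed or clobbered.
with_rng <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop_config("'seed' must be a single finite integer")
  withr::with_seed(as.integer(seed), code)
}

# Independent per-iteration seeds derived from one master seed.
derive_seeds <- function(seed, n) {
  with_rng(seed, sample.int(.Machine$integer.max - 1L, n))
}

is_prob <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0 & x <= 1)

check_scalar_prob <- function(x, name, allow_zero = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_domain(sprintf("'%s' must be a single finite number", name))
  lo_ok <- if (allow_zero) x >= 0 else x > 0
  if (!lo_ok || x > 1)
    stop_domain(sprintf("'%s' must be in %s0, 1]", name, if (allow_zero) "[" else "("))
  invisible(x)
}
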