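# Internal helpers: seed management and small validators.

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG
# state. `seed = NULL` evaluates as-is.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number or NULL", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Stable 31-bit hash of a string, used to derive per-neuron child seeds from
# one root seed so results do not depend on neuron processing order.
string_hash31 <- function(x) {
  h <- 0
  for (c in utf8ToInt(as.character(x))) h <- (h * 31 + c) %% 2147483629
  h
}

child_seed <- function(root_seed, id) {
  if (is.null(root_seed)) return(NULL)
  as.integer((as.numeric(root_seed) + string_hash31(id)) %% 2147483647)
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  invisible(x)
}

# #{spikes in [lo, hi)} for sorted spike times; windows half-open on the
# right so a spike on a shared boundary is counted exactly once.
count_in_windows <- function(spikes, lo, hi) {
  n_lt <- function(x) findInterval(x, spikes, left.open = TRUE)
  n_lt(hi) - n_lt(lo)
}
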