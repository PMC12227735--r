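# Independent oracles used to freeze expected values. These deliberately
# use naive algorithms and RNG streams distinct from the implementation.

# Naive O(n * w) window counter.
oracle_window_rates <- function(spikes, interval, W = 60, step = 15) {
  lo <- interval[1]
  out_lo <- c()
  while (lo + W <= interval[2] + 1e-9) {
    out_lo <- c(out_lo, lo)
    lo <- lo + step
  }
  vapply(out_lo, function(l) sum(spikes >= l & spikes < l + W) / W, 0)
}

# Exact permutation p-value (upper tail, ties counted half) for the
# concordance surrogate test by full enumeration of the n! re-pairings
# (n <= 7).
oracle_exact_concordance_p <- function(pol1, pol2) {
  n <- length(pol1)
  a1 <- pol1 == "activated"
  a2 <- pol2 == "activated"
  obs <- 100 * mean(a1 == a2)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  vals <- vapply(perms(seq_len(n)), function(p) 100 * mean(a1 == a2[p]), 0)
  mean(vals > obs) + 0.5 * mean(vals == obs)
}

# Second implementation of the (uncorrected) ISI-shuffle null: permutation
# via order(runif()) rather than sample.int, counting via the naive oracle.
oracle_null_values <- function(baseline, baseline_mean, n_windows,
                               W = 60, step = 15, n_shuffles = 300) {
  isis <- diff(baseline)
  t0 <- baseline[1]
  vapply(seq_len(n_shuffles), function(b) {
    surr <- t0 + cumsum(c(0, isis[order(runif(length(isis)))]))
    r <- oracle_window_rates(surr, c(t0, t0 + W + step * (n_windows - 1)),
                             W, step)
    pct <- 100 * (r - baseline_mean) / baseline_mean
    if (abs(max(pct)) >= abs(min(pct))) max(pct) else min(pct)
  }, 0)
}

# Regular spike train at `rate` Hz covering [0, duration].
regular_train <- function(rate, duration, id = "reg") {
  spike_train(id, seq(1 / (2 * rate), duration, by = 1 / rate), 0, duration)
}
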