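# Rule-based electrophysiological unit screening: the putative-dopamine
# waveform criteria and the opto-tagging permutation test.

#' Putative dopamine neuron screen
#'
#' Applies the four in vivo identification criteria, all as strict
#' inequalities: (i) triphasic action potential with marked negative
#' deflection, (ii) total duration > 2.0 ms, (iii) start-to-trough width
#' > 1.1 ms, (iv) slow firing rate, between 1 and 10 Hz exclusive.
#'
#' @param features A [waveform_features()] object.
#' @return List with `putative_da` (logical) and `reasons` (character vector
#'   naming every failed criterion; empty when all pass).
#' @examples
#' is_putative_da(waveform_features(2.5, 1.3, 4, TRUE))$putative_da
#' @export
is_putative_da <- function(features) {
  if (!inherits(features, "waveform_features"))
    stop("`features` must be a waveform_features object", call. = FALSE)
  reasons <- character(0)
  if (!features$is_triphasic)
    reasons <- c(reasons, "(i) not triphasic")
  if (!(features$total_duration_ms > 2.0))
    reasons <- c(reasons, "(ii) total duration <= 2.0 ms")
  if (!(features$start_to_trough_ms > 1.1))
    reasons <- c(reasons, "(iii) start-to-trough width <= 1.1 ms")
  if (!(features$mean_rate_hz < 10 && features$mean_rate_hz > 1))
    reasons <- c(reasons, "(iv) firing rate outside (1, 10) Hz")
  list(putative_da = length(reasons) == 0L, reasons = reasons)
}

#' Opto-tagging assessment by circular-shift permutation
#'
#' A unit is opto-tagged when its firing probability within a short window
#' after light onset (default 10 ms) significantly exceeds chance. The
#' observed statistic is the fraction of pulses with at least one spike in
#' `(onset, onset + tag_window]`. The null preserves the spike train's
#' autostructure by circularly shifting the pulse onsets by uniform random
#' offsets within the epoch; the p-value uses the add-one permutation
#' formula. Tagged iff `p < alpha` and the observed statistic exceeds the
#' null mean.
#'
#' @param x A [spike_train()] or sorted numeric spike times (s).
#' @param pulses A [light_pulse_train()] or numeric pulse onsets (s); at
#'   least 10 pulses.
#' @param tag_window Post-onset window (s), default 0.010; must be shorter
#'   than the smallest inter-pulse interval.
#' @param n_permutations Number of circular shifts, default 1000.
#' @param alpha Significance level, default 0.05.
#' @param epoch Numeric `c(start, end)` (s); defaults to the spike train's
#'   epoch.
#' @param seed Optional seed.
#' @return An object of class `opto_tag_result`: list with
#'   `p_spike_baseline` (null mean), `p_spike_post_onset`, `p_value`,
#'   `tagged`, `n_pulses`, `tag_window`.
#' @export
opto_tag_test <- function(x, pulses, tag_window = 0.010,
                          n_permutations = 1000, alpha = 0.05,
                          epoch = NULL, seed = NULL) {
  if (inherits(pulses, "light_pulse_train")) pulses <- pulses$pulse_onsets
  pulses <- as.numeric(pulses)
  if (length(pulses) == 0L) stop("no light pulses supplied", call. = FALSE)
  if (length(pulses) < 10L)
    stop("need at least 10 light pulses", call. = FALSE)
  if (inherits(x, "spike_train")) {
    if (is.null(epoch)) epoch <- c(x$epoch_start, x$epoch_end)
    spikes <- x$spike_times
  } else {
    spikes <- sort(as.numeric(x))
    if (is.null(epoch)) epoch <- range(spikes)
  }
  stopifnot_scalar_number(tag_window, "tag_window", positive = TRUE)
  if (tag_window >= min(diff(pulses)))
    stop("tag window is longer than the smallest inter-pulse interval",
         call. = FALSE)
  span <- epoch[2L] - epoch[1L]
  stat <- function(onsets)
    mean(count_in_windows(spikes, onsets, onsets + tag_window) > 0)
  observed <- stat(pulses)
  null <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(b) {
      shift <- runif(1, 0, span)
      stat(epoch[1L] + (pulses - epoch[1L] + shift) %% span)
    }, 0)
  })
  p <- (1 + sum(null >= observed)) / (n_permutations + 1)
  structure(list(p_spike_baseline = mean(null),
                 p_spike_post_onset = observed,
                 p_value = p,
                 tagged = p < alpha && observed > mean(null),
                 n_pulses = length(pulses), tag_window = tag_window),
            class = "opto_tag_result")
}

#' @export
print.opto_tag_result <- function(x, ...) {
  cat(sprintf(
    "<opto_tag_result> P(spike | pulse, %g ms) = %.3f vs null %.3f; p = %.4g -> %s\n",
    1000 * x$tag_window, x$p_spike_post_onset, x$p_spike_baseline,
    x$p_value, if (x$tagged) "tagged" else "not tagged"))
  invisible(x)
}
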