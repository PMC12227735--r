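# Postsynaptic-current analysis: biexponential kernels, template
# construction from example events, scaled-template matched detection with
# a 3 x noise-SD amplitude rule, and evoked-response amplitude.

#' Biexponential synaptic-event kernel
#'
#' `exp(-t/tau_decay) - exp(-t/tau_rise)`, sampled at `sampling_rate` over
#' `length_ms`, peak-normalised to magnitude 1 with the requested sign
#' (negative for inward currents).
#'
#' @param tau_rise_ms,tau_decay_ms Rise and decay time constants (ms);
#'   `tau_decay_ms > tau_rise_ms > 0`.
#' @param length_ms Kernel length (ms), default 8 decay constants.
#' @param sampling_rate Sampling rate (Hz), default 10000.
#' @param sign `-1` (inward, default) or `+1`.
#' @return Numeric kernel with unit peak magnitude.
#' @export
biexp_kernel <- function(tau_rise_ms = 1, tau_decay_ms = 8,
                         length_ms = 8 * tau_decay_ms,
                         sampling_rate = 10000, sign = -1) {
  if (tau_decay_ms <= tau_rise_ms || tau_rise_ms <= 0)
    stop("need tau_decay_ms > tau_rise_ms > 0", call. = FALSE)
  t <- seq(0, length_ms / 1000, by = 1 / sampling_rate)
  k <- exp(-1000 * t / tau_decay_ms) - exp(-1000 * t / tau_rise_ms)
  sign * k / max(abs(k))
}

#' Build an event template from example currents
#'
#' Averages at least 15 aligned example snippets, subtracts the pre-onset
#' baseline of each, and normalises the average to unit peak magnitude
#' (sign preserved).
#'
#' @param trace A [current_trace()].
#' @param example_onsets Event onset times (s), at least 15,
#'   non-overlapping given the template length.
#' @param length_ms Template length after the onset (ms), default 20.
#' @param pre_ms Pre-onset baseline span (ms), default 2.
#' @return An object of class `event_template`: list with `waveform` (unit
#'   peak magnitude), `length_ms`, `sampling_rate`, `n_source_events`,
#'   `peak_sign`.
#' @export
build_template <- function(trace, example_onsets, length_ms = 20,
                           pre_ms = 2) {
  stopifnot(inherits(trace, "current_trace"))
  onsets <- sort(as.numeric(example_onsets))
  if (length(onsets) < 15L)
    stop(sprintf("need at least 15 example currents, got %d", length(onsets)),
         call. = FALSE)
  if (any(diff(onsets) < length_ms / 1000))
    stop("example events overlap within the template length", call. = FALSE)
  fs <- trace$sampling_rate
  n_pre <- max(1L, round(pre_ms / 1000 * fs))
  n_len <- round(length_ms / 1000 * fs)
  idx0 <- round(onsets * fs) + 1L
  if (any(idx0 - n_pre < 1L) || any(idx0 + n_len - 1L > length(trace$samples)))
    stop("example events fall outside the trace", call. = FALSE)
  snippets <- vapply(idx0, function(i) {
    base <- mean(trace$samples[(i - n_pre):(i - 1L)])
    trace$samples[i:(i + n_len - 1L)] - base
  }, numeric(n_len))
  avg <- rowMeans(snippets)
  peak <- avg[which.max(abs(avg))]
  if (peak == 0) stop("degenerate template: flat average", call. = FALSE)
  structure(list(waveform = avg / abs(peak), length_ms = length_ms,
                 sampling_rate = fs, n_source_events = length(onsets),
                 peak_sign = sign(peak)),
            class = "event_template")
}

#' Robust noise standard deviation of a current trace
#'
#' Estimated from first differences (a one-lag high-pass, which removes
#' slow drift and most event energy) with the scaled median absolute
#' deviation: `mad(diff(x)) / sqrt(2)`. Samples covered by
#' `exclusion_mask` (e.g. detected events) are dropped from the
#' differences.
#'
#' @param trace A [current_trace()] or numeric samples.
#' @param exclusion_mask Optional logical vector (TRUE = excluded), same
#'   length as the samples.
#' @param min_samples_s Minimum unmasked span (s), default 0.1.
#' @return Noise SD in the trace's units (pA).
#' @export
estimate_noise_sd <- function(trace, exclusion_mask = NULL,
                              min_samples_s = 0.1) {
  if (inherits(trace, "current_trace")) {
    x <- trace$samples
    fs <- trace$sampling_rate
  } else {
    x <- as.numeric(trace)
    fs <- 10000
  }
  n <- length(x)
  if (is.null(exclusion_mask)) exclusion_mask <- rep(FALSE, n)
  if (length(exclusion_mask) != n)
    stop("`exclusion_mask` must match the trace length", call. = FALSE)
  keep <- !exclusion_mask[-n] & !exclusion_mask[-1L]
  if (sum(keep) < min_samples_s * fs)
    stop("fewer than the required unmasked samples for noise estimation",
         call. = FALSE)
  mad(diff(x)[keep]) / sqrt(2)
}

#' Matched-template detection of synaptic events
#'
#' Classical scaled-template search: at every offset the template is fitted
#' to the trace segment by least squares in scale and offset; the detection
#' statistic is the fitted scale divided by its standard error. Local
#' maxima of the statistic above `criterion_threshold` become candidates;
#' candidates are kept only if the fitted peak amplitude is at least
#' `min_amplitude_sd` (default 3) times the noise SD, and overlapping
#' candidates are resolved greedily to the higher-scoring one with a
#' refractory span of one template length.
#'
#' @param trace A [current_trace()].
#' @param template An [build_template()] result (or numeric kernel with
#'   unit peak magnitude).
#' @param noise_sd Noise SD (pA); estimated with [estimate_noise_sd()] when
#'   `NULL`. Must be positive.
#' @param criterion_threshold Detection-statistic threshold, default 4.
#' @param min_amplitude_sd Amplitude rule in noise SDs, default 3.
#' @return A data.frame with `onset_s`, `amplitude_pA` (signed) and `score`,
#'   ordered by onset. Attribute `noise_sd` records the SD used.
#' @export
detect_events <- function(trace, template, noise_sd = NULL,
                          criterion_threshold = 4, min_amplitude_sd = 3) {
  stopifnot(inherits(trace, "current_trace"))
  w <- if (inherits(template, "event_template")) template$waveform
       else as.numeric(template)
  y <- trace$samples
  L <- length(w)
  N <- length(y)
  if (L >= N) stop("template must be shorter than the trace", call. = FALSE)
  if (is.null(noise_sd)) noise_sd <- estimate_noise_sd(trace)
  if (!is.numeric(noise_sd) || noise_sd <= 0)
    stop("`noise_sd` must be positive", call. = FALSE)

  n_off <- N - L + 1L
  Sw <- sum(w); Sww <- sum(w^2)
  Swc <- Sww - Sw^2 / L
  cy <- c(0, cumsum(y)); cyy <- c(0, cumsum(y^2))
  idx <- seq_len(n_off)
  Sy <- cy[idx + L] - cy[idx]
  Syy <- cyy[idx + L] - cyy[idx]
  conv <- stats::filter(y, rev(w), method = "convolution", sides = 1)
  Swy <- as.numeric(conv[idx + L - 1L])

  a <- (Swy - Sw * Sy / L) / Swc
  b <- (Sy - a * Sw) / L
  sse <- pmax(Syy - 2 * a * Swy - 2 * b * Sy + a^2 * Sww +
                2 * a * b * Sw + L * b^2, 0)
  se_a <- sqrt(sse / (L - 2)) / sqrt(Swc)
  score <- a / pmax(se_a, .Machine$double.eps)

  up <- c(TRUE, diff(score) > 0)
  down <- c(diff(score) <= 0, TRUE)
  cand <- which(up & down & score > criterion_threshold)
  peak_sign <- sign(w[which.max(abs(w))])
  amp <- a[cand] * peak_sign
  keep <- abs(amp) >= min_amplitude_sd * noise_sd
  cand <- cand[keep]; amp <- amp[keep]

  if (length(cand)) {
    ord <- order(score[cand], decreasing = TRUE)
    accepted <- integer(0)
    for (i in ord) {
      if (!length(accepted) || all(abs(cand[i] - cand[accepted]) >= L))
        accepted <- c(accepted, i)
    }
    accepted <- sort(accepted)
    cand <- cand[accepted]; amp <- amp[accepted]
  }
  out <- data.frame(onset_s = (cand - 1L) / trace$sampling_rate,
                    amplitude_pA = amp, score = score[cand])
  attr(out, "noise_sd") <- noise_sd
  out
}

#' Evoked-response amplitude relative to baseline
#'
#' The extremal value (largest deviation from the pre-stimulus baseline
#' mean) within the post-stimulus window, minus that baseline mean; the
#' sign is preserved.
#'
#' @param trace A [current_trace()].
#' @param stim_time Stimulus time (s).
#' @param pre_window,post_window Numeric `c(start, end)` windows (s); the
#'   pre window must end at or before the stimulus, the post window must
#'   start at or after it, and the two must not overlap.
#' @return Signed amplitude (pA).
#' @export
evoked_amplitude <- function(trace, stim_time, pre_window, post_window) {
  stopifnot(inherits(trace, "current_trace"))
  if (pre_window[2L] > post_window[1L])
    stop("pre and post windows overlap", call. = FALSE)
  if (post_window[1L] < stim_time)
    stop("post window must start at or after the stimulus", call. = FALSE)
  fs <- trace$sampling_rate
  slice <- function(win) {
    i0 <- max(1L, floor(win[1L] * fs) + 1L)
    i1 <- min(length(trace$samples), ceiling(win[2L] * fs))
    if (i1 < i0) stop("window outside the trace", call. = FALSE)
    trace$samples[i0:i1]
  }
  base <- mean(slice(pre_window))
  post <- slice(post_window)
  dev <- post - base
  dev[which.max(abs(dev))]
}
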