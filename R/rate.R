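# Sliding-window firing-rate estimation, baseline normalisation and the
# signed extremal-variation response statistic.

#' Windowed firing-rate trace
#'
#' Estimates firing frequency on sliding windows (default 60 s windows every
#' 15 s). Windows are half-open `[lo, hi)` and fully contained in
#' `interval`; centers sit at `interval[1] + window_length/2 + k * step`.
#'
#' @param x A [spike_train()] or a sorted numeric vector of spike times (s).
#' @param interval Numeric `c(start, end)` (s). Defaults to the epoch for a
#'   `spike_train`; required for a bare numeric vector.
#' @param window_length Window length (s), default 60.
#' @param step Step between window centers (s), default 15; must satisfy
#'   `window_length >= step > 0`.
#' @return An object of class `rate_trace`: list with `window_centers` (s),
#'   `rates` (Hz), `window_length`, `step`.
#' @examples
#' st <- spike_train("u1", seq(0.25, 300, by = 0.5), 0, 300)
#' rt <- compute_rate_trace(st)
#' all(rt$rates == 2)
#' @export
compute_rate_trace <- function(x, interval = NULL, window_length = 60,
                               step = 15) {
  if (inherits(x, "spike_train")) {
    if (is.null(interval)) interval <- c(x$epoch_start, x$epoch_end)
    spikes <- x$spike_times
  } else {
    if (is.null(interval))
      stop("`interval` is required when `x` is a numeric vector", call. = FALSE)
    spikes <- as.numeric(x)
    if (is.unsorted(spikes)) spikes <- sort(spikes)
  }
  stopifnot_scalar_number(window_length, "window_length", positive = TRUE)
  stopifnot_scalar_number(step, "step", positive = TRUE)
  if (window_length < step)
    stop("`window_length` must be >= `step`", call. = FALSE)
  span <- interval[2L] - interval[1L]
  if (span < window_length)
    stop("`interval` is shorter than one window", call. = FALSE)
  n_win <- floor((span - window_length) / step) + 1L
  lo <- interval[1L] + step * (seq_len(n_win) - 1L)
  hi <- lo + window_length
  counts <- count_in_windows(spikes, lo, hi)
  structure(list(window_centers = lo + window_length / 2,
                 rates = counts / window_length,
                 window_length = window_length, step = step),
            class = "rate_trace")
}

#' @export
print.rate_trace <- function(x, ...) {
  cat(sprintf("<rate_trace> %d windows of %g s every %g s; mean %.2f Hz\n",
              length(x$rates), x$window_length, x$step, mean(x$rates)))
  invisible(x)
}

#' Normalise a rate trace to its baseline mean
#'
#' Maps every window to its percent change from the baseline mean rate,
#' `100 * (rate - baseline_mean) / baseline_mean`. The baseline mean is the
#' mean over windows fully contained in `baseline_interval`.
#'
#' @param trace A [compute_rate_trace()] result.
#' @param baseline_interval Numeric `c(start, end)` (s) of the baseline,
#'   which must precede the response being scored.
#' @param baseline_mean_hz Optional externally supplied baseline mean (Hz);
#'   used by the bootstrap so that surrogates are normalised to the original
#'   baseline mean.
#' @return An object of class `response_profile` with `window_centers`,
#'   `pct` (% change per window), `baseline_mean_hz`, `window_length`,
#'   `step`.
#' @export
normalize_to_baseline <- function(trace, baseline_interval = NULL,
                                  baseline_mean_hz = NULL) {
  stopifnot(inherits(trace, "rate_trace"))
  if (is.null(baseline_mean_hz)) {
    if (is.null(baseline_interval))
      stop("supply `baseline_interval` or `baseline_mean_hz`", call. = FALSE)
    half <- trace$window_length / 2
    in_base <- trace$window_centers - half >= baseline_interval[1L] &
      trace$window_centers + half <= baseline_interval[2L]
    if (!any(in_base))
      stop("no window fully contained in the baseline interval", call. = FALSE)
    baseline_mean_hz <- mean(trace$rates[in_base])
  }
  if (baseline_mean_hz == 0)
    stop("silent baseline: baseline mean rate is 0 Hz", call. = FALSE)
  structure(list(window_centers = trace$window_centers,
                 pct = 100 * (trace$rates - baseline_mean_hz) / baseline_mean_hz,
                 baseline_mean_hz = baseline_mean_hz,
                 window_length = trace$window_length, step = trace$step),
            class = "response_profile")
}

#' Signed extremal variation within the response period
#'
#' The response statistic: the maximal and minimal normalised rate over
#' windows whose centers fall in `response_window` (an interval open at the
#' left, closed at the right), and whichever of the two has the larger
#' magnitude. On an exact non-zero tie the maximum (activation) is returned
#' and `tie` is set.
#'
#' @param profile A [normalize_to_baseline()] result.
#' @param response_window Numeric `c(start, end)` (s); a window belongs to
#'   the response period iff its center lies in `(start, end]`.
#' @return List with `max_pct`, `min_pct`, `delta_f_pct`, `tie`,
#'   `n_windows`.
#' @export
extremal_variation <- function(profile, response_window) {
  stopifnot(inherits(profile, "response_profile"))
  sel <- profile$window_centers > response_window[1L] &
    profile$window_centers <= response_window[2L]
  if (!any(sel)) stop("no window center falls in the response window",
                      call. = FALSE)
  v <- profile$pct[sel]
  mx <- max(v); mn <- min(v)
  tie <- abs(mx) == abs(mn) && mx != 0
  delta_f <- if (abs(mx) >= abs(mn)) mx else mn
  list(max_pct = mx, min_pct = mn, delta_f_pct = delta_f, tie = tie,
       n_windows = sum(sel))
}

#' Average normalised time courses across neurons
#'
#' Per-window mean and standard error of the mean across a set of response
#' profiles aligned on the injection (identical window grid required).
#' With a single profile the SEM is defined as 0 (with a warning).
#'
#' @param profiles List of [normalize_to_baseline()] results with identical
#'   `window_centers`, `window_length` and `step`.
#' @return A data.frame with `window_center`, `mean_pct`, `sem_pct`, `n`.
#' @export
aggregate_time_courses <- function(profiles) {
  if (!length(profiles)) stop("no profiles to aggregate", call. = FALSE)
  stopifnot(all(vapply(profiles, inherits, TRUE, "response_profile")))
  ref <- profiles[[1L]]
  same <- vapply(profiles, function(p) {
    isTRUE(all.equal(p$window_centers, ref$window_centers)) &&
      p$window_length == ref$window_length && p$step == ref$step
  }, TRUE)
  if (!all(same))
    stop("profiles have mixed window grids; align them first", call. = FALSE)
  m <- do.call(rbind, lapply(profiles, `[[`, "pct"))
  n <- nrow(m)
  sem <- if (n == 1L) {
    warning("single profile: SEM reported as 0")
    rep(0, ncol(m))
  } else {
    apply(m, 2L, stats::sd) / sqrt(n)
  }
  data.frame(window_center = ref$window_centers, mean_pct = colMeans(m),
             sem_pct = sem, n = n)
}
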