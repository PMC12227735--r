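#' Spike train of one neuron in one recording session
#'
#' Container for ordered spike times with explicit recording-epoch bounds.
#' Times are seconds throughout the package.
#'
#' @param neuron_id Character scalar identifying the unit.
#' @param spike_times Numeric vector of spike times (s), strictly increasing.
#' @param epoch_start,epoch_end Recording epoch bounds (s). When omitted they
#'   are inferred as `[first spike - 1, last spike + 1]` and flagged in the
#'   `epoch_inferred` attribute.
#'
#' @return An object of class `spike_train`: a list with elements
#'   `neuron_id`, `spike_times`, `epoch_start`, `epoch_end`.
#' @examples
#' st <- spike_train("u1", c(0.5, 1.0, 1.5))
#' n_spikes(st)
#' @export
spike_train <- function(neuron_id, spike_times, epoch_start = NULL,
                        epoch_end = NULL) {
  if (length(neuron_id) != 1L || is.na(neuron_id))
    stop("`neuron_id` must be a single non-missing value", call. = FALSE)
  spike_times <- as.numeric(spike_times)
  if (anyNA(spike_times) || any(!is.finite(spike_times)))
    stop("spike times must be finite", call. = FALSE)
  if (is.unsorted(spike_times, strictly = TRUE))
    stop(sprintf("spike times of neuron '%s' must be strictly increasing",
                 neuron_id), call. = FALSE)
  inferred <- is.null(epoch_start) || is.null(epoch_end)
  if (inferred && length(spike_times) == 0L)
    stop("epoch bounds are required for an empty spike train", call. = FALSE)
  if (is.null(epoch_start)) epoch_start <- spike_times[1L] - 1
  if (is.null(epoch_end)) epoch_end <- spike_times[length(spike_times)] + 1
  stopifnot_scalar_number(epoch_start, "epoch_start")
  stopifnot_scalar_number(epoch_end, "epoch_end")
  if (epoch_end <= epoch_start)
    stop("`epoch_end` must be greater than `epoch_start`", call. = FALSE)
  if (length(spike_times) &&
      (spike_times[1L] < epoch_start ||
       spike_times[length(spike_times)] > epoch_end))
    stop(sprintf("neuron '%s' has spike times outside the epoch", neuron_id),
         call. = FALSE)
  structure(
    list(neuron_id = as.character(neuron_id), spike_times = spike_times,
         epoch_start = epoch_start, epoch_end = epoch_end),
    epoch_inferred = inferred, class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> neuron '%s': %d spikes in [%.3f, %.3f] s (%.2f Hz)\n",
              x$neuron_id, length(x$spike_times), x$epoch_start, x$epoch_end,
              length(x$spike_times) / (x$epoch_end - x$epoch_start)))
  invisible(x)
}

#' @rdname spike_train
#' @param x A `spike_train`.
#' @export
n_spikes <- function(x) length(x$spike_times)

.substances <- c("saline", "nicotine", "ethanol", "co-injection")
# Dose units accepted per substance (saline doses are ignored).
.dose_units <- list(nicotine = "ug/kg", ethanol = "mg/kg",
                    `co-injection` = c("ug/kg", "mg/kg"))

normalize_units <- function(u) {
  u <- gsub("µ|μ", "u", tolower(trimws(u)))
  gsub("\\s", "", u)
}

#' Intravenous injection event
#'
#' @param time Injection time (s).
#' @param substance One of `"saline"`, `"nicotine"`, `"ethanol"`,
#'   `"co-injection"`.
#' @param dose Dose, required (> 0) for anything but saline.
#' @param dose_units `"ug/kg"` (nicotine) or `"mg/kg"` (ethanol); either for
#'   co-injection. Micro signs are normalised to `"u"`.
#' @return An object of class `injection_event`.
#' @examples
#' injection_event(300, "nicotine", 30, "ug/kg")
#' @export
injection_event <- function(time, substance, dose = NA_real_,
                            dose_units = NA_character_) {
  stopifnot_scalar_number(time, "time")
  substance <- match.arg(substance, .substances)
  if (substance == "saline") {
    dose <- NA_real_
    dose_units <- NA_character_
  } else {
    stopifnot_scalar_number(dose, "dose", positive = TRUE)
    dose_units <- normalize_units(dose_units)
    allowed <- .dose_units[[substance]]
    if (is.na(dose_units) || !dose_units %in% allowed)
      stop(sprintf("dose units for %s must be %s, got '%s'", substance,
                   paste(allowed, collapse = " or "), dose_units),
           call. = FALSE)
  }
  structure(list(time = time, substance = substance, dose = dose,
                 dose_units = dose_units), class = "injection_event")
}

#' Optogenetic light-pulse train
#'
#' @param pulse_onsets Pulse onset times (s), increasing.
#' @param pulse_width Pulse duration (s), > 0.
#' @param pattern Stimulation pattern label.
#' @return An object of class `light_pulse_train`.
#' @export
light_pulse_train <- function(pulse_onsets, pulse_width = 0.005,
                              pattern = c("regular_10Hz", "burst_20Hz",
                                          "continuous")) {
  pattern <- match.arg(pattern)
  pulse_onsets <- as.numeric(pulse_onsets)
  if (is.unsorted(pulse_onsets, strictly = TRUE))
    stop("pulse onsets must be strictly increasing", call. = FALSE)
  stopifnot_scalar_number(pulse_width, "pulse_width", positive = TRUE)
  structure(list(pulse_onsets = pulse_onsets, pulse_width = pulse_width,
                 pattern = pattern), class = "light_pulse_train")
}

#' Voltage-clamp current trace
#'
#' @param samples Current samples (pA), finite.
#' @param sampling_rate Sampling rate (Hz), > 0.
#' @param stim_times Optional stimulation times (s).
#' @return An object of class `current_trace`.
#' @export
current_trace <- function(samples, sampling_rate, stim_times = NULL) {
  samples <- as.numeric(samples)
  if (any(!is.finite(samples)))
    stop("current samples must be finite", call. = FALSE)
  stopifnot_scalar_number(sampling_rate, "sampling_rate", positive = TRUE)
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 stim_times = stim_times), class = "current_trace")
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf("<current_trace> %d samples at %g Hz (%.2f s)\n",
              length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate))
  invisible(x)
}

#' Extracellular waveform features of a unit
#'
#' Features used by the putative-dopamine screen (supplied by the spike
#' sorter, not computed here).
#'
#' @param total_duration_ms Total action-potential duration (ms), > 0.
#' @param start_to_trough_ms Width from start to negative trough (ms), > 0.
#' @param mean_rate_hz Mean firing rate (Hz), >= 0.
#' @param is_triphasic Logical: typical triphasic waveform with marked
#'   negative deflection.
#' @return An object of class `waveform_features`.
#' @seealso [is_putative_da()]
#' @export
waveform_features <- function(total_duration_ms, start_to_trough_ms,
                              mean_rate_hz, is_triphasic) {
  stopifnot_scalar_number(total_duration_ms, "total_duration_ms", positive = TRUE)
  stopifnot_scalar_number(start_to_trough_ms, "start_to_trough_ms", positive = TRUE)
  stopifnot_scalar_number(mean_rate_hz, "mean_rate_hz")
  if (mean_rate_hz < 0) stop("`mean_rate_hz` must be >= 0", call. = FALSE)
  if (!is.logical(is_triphasic) || length(is_triphasic) != 1L ||
      is.na(is_triphasic))
    stop("`is_triphasic` must be TRUE or FALSE", call. = FALSE)
  structure(list(total_duration_ms = total_duration_ms,
                 start_to_trough_ms = start_to_trough_ms,
                 mean_rate_hz = mean_rate_hz,
                 is_triphasic = is_triphasic), class = "waveform_features")
}

#' Recorded neuron with its session metadata
#'
#' @param neuron_id Unit identifier; must match the spike train's.
#' @param train A [spike_train()].
#' @param injections List of [injection_event()]s, sorted by time, all inside
#'   the epoch.
#' @param projection Projection target: `"NAc"`, `"Amg"` or `"unknown"`.
#' @param coordinates_mm Optional named numeric `(AP, ML, DV)` in mm.
#' @param waveform Optional [waveform_features()].
#' @return An object of class `neuron_record`.
#' @export
neuron_record <- function(neuron_id, train, injections = list(),
                          projection = c("unknown", "NAc", "Amg"),
                          coordinates_mm = NULL, waveform = NULL) {
  projection <- match.arg(projection)
  if (!inherits(train, "spike_train"))
    stop("`train` must be a spike_train", call. = FALSE)
  if (!identical(as.character(neuron_id), train$neuron_id))
    stop("`neuron_id` does not match the spike train's", call. = FALSE)
  if (!all(vapply(injections, inherits, TRUE, "injection_event")))
    stop("`injections` must be a list of injection_event objects",
         call. = FALSE)
  times <- vapply(injections, `[[`, 0, "time")
  if (is.unsorted(times))
    stop("injections must be sorted by time", call. = FALSE)
  if (length(times) && (min(times) < train$epoch_start ||
                        max(times) > train$epoch_end))
    stop("injection times must lie within the epoch", call. = FALSE)
  if (!is.null(coordinates_mm)) {
    coordinates_mm <- as.numeric(coordinates_mm)
    if (length(coordinates_mm) != 3L)
      stop("`coordinates_mm` must be (AP, ML, DV)", call. = FALSE)
    names(coordinates_mm) <- c("AP", "ML", "DV")
  }
  if (!is.null(waveform) && !inherits(waveform, "waveform_features"))
    stop("`waveform` must be a waveform_features object", call. = FALSE)
  structure(list(neuron_id = as.character(neuron_id), train = train,
                 injections = injections, projection = projection,
                 coordinates_mm = coordinates_mm, waveform = waveform),
            class = "neuron_record")
}
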