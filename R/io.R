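# Readers and writers for the package's plain-text interchange formats:
# spike tables (CSV), session metadata (JSON, optionally YAML), current
# traces (CSV or raw float + JSON sidecar), and result reports.

#' Read a spike-time table
#'
#' Expects a CSV with header `neuron_id,spike_time_s`; rows may interleave
#' neurons. Times are sorted per neuron; exact duplicate timestamps within a
#' neuron are a validation error.
#'
#' @param path Path to the CSV file.
#' @param epoch Optional numeric `c(start, end)` (s) applied to every train.
#'   When `NULL` the epoch is inferred per neuron as
#'   `[first spike - 1, last spike + 1]`.
#' @return A named list of [spike_train()] objects (possibly empty).
#' @seealso [write_spike_table()]
#' @export
read_spike_table <- function(path, epoch = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- read.csv(path, colClasses = c("character", "character"),
                 strip.white = TRUE)
  required <- c("neuron_id", "spike_time_s")
  if (!identical(names(df)[seq_along(required)], required))
    stop(sprintf("%s: header must be '%s'", path,
                 paste(required, collapse = ",")), call. = FALSE)
  if (nrow(df) == 0L) return(list())
  t <- suppressWarnings(as.numeric(df$spike_time_s))
  bad <- which(is.na(t) | !is.finite(t))
  if (length(bad))
    stop(sprintf("%s: malformed spike_time_s at line %d ('%s')", path,
                 bad[1L] + 1L, df$spike_time_s[bad[1L]]), call. = FALSE)
  out <- lapply(split(t, df$neuron_id), function(ts) sort(ts))
  mapply(function(ts, id) {
    if (anyDuplicated(ts))
      stop(sprintf("%s: duplicate spike times for neuron '%s'", path, id),
           call. = FALSE)
    spike_train(id, ts, epoch_start = epoch[1L], epoch_end = epoch[2L])
  }, out, names(out), SIMPLIFY = FALSE)
}

#' Write spike trains to a spike-time table
#'
#' Times are serialised with 17 significant digits so that a read/write
#' round trip reproduces them bit-exactly.
#'
#' @param trains A `spike_train` or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spike_table <- function(trains, path) {
  if (inherits(trains, "spike_train")) trains <- list(trains)
  lines <- "neuron_id,spike_time_s"
  for (tr in trains) {
    if (!inherits(tr, "spike_train"))
      stop("`trains` must contain spike_train objects", call. = FALSE)
    if (length(tr$spike_times))
      lines <- c(lines, sprintf("%s,%.17g", tr$neuron_id, tr$spike_times))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read session metadata
#'
#' Parses injection events, light pulses, projection label and coordinates
#' from a structured-text file. JSON is the canonical dialect; YAML is
#' accepted only when requested explicitly.
#'
#' @param path Path to the metadata file.
#' @param format `"json"` (default) or `"yaml"`.
#' @return A list with elements `injections` (list of [injection_event()]),
#'   `light_pulses` ([light_pulse_train()] or `NULL`), `projection`,
#'   `coordinates_mm`, and `config` (named list of analysis overrides).
#' @export
read_session_metadata <- function(path, format = c("json", "yaml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- if (format == "json") {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required for YAML metadata", call. = FALSE)
    yaml::read_yaml(path)
  }
  injections <- lapply(raw$injections, function(inj) {
    if (is.null(inj$time)) stop("injection entry lacks 'time'", call. = FALSE)
    if (is.null(inj$substance))
      stop("injection entry lacks 'substance'", call. = FALSE)
    if (!inj$substance %in% .substances)
      stop(sprintf("unknown substance '%s'", inj$substance), call. = FALSE)
    injection_event(inj$time, inj$substance,
                    dose = if (is.null(inj$dose)) NA_real_ else inj$dose,
                    dose_units = if (is.null(inj$units)) NA_character_
                                 else inj$units)
  })
  pulses <- NULL
  if (!is.null(raw$light_pulses)) {
    lp <- raw$light_pulses
    pulses <- light_pulse_train(
      unlist(lp$pulse_onsets),
      pulse_width = if (is.null(lp$pulse_width)) 0.005 else lp$pulse_width,
      pattern = if (is.null(lp$pattern)) "regular_10Hz" else lp$pattern)
  }
  projection <- if (is.null(raw$projection)) "unknown" else raw$projection
  if (!projection %in% c("NAc", "Amg", "unknown"))
    stop(sprintf("unknown projection '%s'", projection), call. = FALSE)
  coords <- if (is.null(raw$coordinates_mm)) NULL else
    as.numeric(unlist(raw$coordinates_mm))
  list(injections = injections, light_pulses = pulses,
       projection = projection, coordinates_mm = coords,
       config = if (is.null(raw$config)) list() else raw$config)
}

#' Read a sampled current trace
#'
#' CSV traces have header `time_s,current_pA`; the sampling rate is taken
#' from the time column. Raw little-endian float32/float64 arrays are read
#' when a JSON sidecar (`<path>.json`) provides `sampling_rate` and
#' `dtype`.
#'
#' @param path Path to the trace file.
#' @return A [current_trace()].
#' @export
read_current_trace <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::fromJSON(sidecar)
    dtype <- if (is.null(meta$dtype)) "float64" else meta$dtype
    size <- if (dtype == "float32") 4L else 8L
    n <- file.size(path) / size
    x <- readBin(path, what = "double", n = n, size = size, endian = "little")
    return(current_trace(x, meta$sampling_rate))
  }
  df <- read.csv(path)
  if (!all(c("time_s", "current_pA") %in% names(df)))
    stop(sprintf("%s: header must contain time_s,current_pA", path),
         call. = FALSE)
  dt <- diff(df$time_s)
  if (any(dt <= 0)) stop(sprintf("%s: time_s must increase", path), call. = FALSE)
  current_trace(df$current_pA, sampling_rate = 1 / stats::median(dt))
}

#' Write a result report with a reproducibility manifest
#'
#' Writes `results` as a deterministic CSV (17 significant digits for
#' doubles) plus a JSON manifest recording the configuration, the seed and
#' the package version. Reruns with identical inputs are byte-identical.
#'
#' @param results A data.frame of results.
#' @param path Output CSV path; the manifest goes to
#'   `<path without extension>_manifest.json`.
#' @param config Named list of analysis parameters to record.
#' @param seed The root seed used for the run (may be `NULL`).
#' @return Invisibly, c(csv = path, manifest = manifest_path).
#' @export
write_report <- function(results, path, config = list(), seed = NULL) {
  if (!is.data.frame(results)) stop("`results` must be a data.frame", call. = FALSE)
  fmt <- function(col) {
    if (is.double(col)) ifelse(is.na(col), "NA", sprintf("%.17g", col))
    else as.character(col)
  }
  cells <- vapply(results, fmt, character(nrow(results)))
  if (nrow(results) == 1L) cells <- matrix(cells, nrow = 1L)
  lines <- paste(names(results), collapse = ",")
  if (nrow(results) > 0L)
    lines <- c(lines, apply(cells, 1L, paste, collapse = ","))
  tryCatch(writeLines(lines, path),
           error = function(e) stop(sprintf("cannot write report to %s: %s",
                                            path, conditionMessage(e)),
                                    call. = FALSE))
  manifest_path <- paste0(tools::file_path_sans_ext(path), "_manifest.json")
  manifest <- list(config = config,
                   seed = if (is.null(seed)) NA else seed,
                   n_rows = nrow(results),
                   package = "spikeboot",
                   package_version = as.character(packageVersion("spikeboot")))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(csv = path, manifest = manifest_path))
}

#' Write detected synaptic events to CSV
#'
#' @param events Data frame from [detect_events()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path) {
  lines <- c("onset_s,amplitude_pA,score",
             sprintf("%.17g,%.17g,%.17g", events$onset_s,
                     events$amplitude_pA, events$score))
  writeLines(lines, path)
  invisible(path)
}
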