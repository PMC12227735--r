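# Synthetic-data generators: inhomogeneous gamma-renewal spike trains,
# mixed neuron populations with a tunable cross-drug concordance, and
# noisy current traces with biexponential events. Every generator emits
# ground truth so downstream stages can be scored.

#' Specification of one simulated neuron
#'
#' Defaults emulate a dopamine neuron firing tonically in the 1-10 Hz range
#' with ISIs more regular than Poisson (gamma shape 2), and an
#' injection-locked rate modulation of either polarity lasting a 3-min
#' response period.
#'
#' @param baseline_rate_hz Baseline rate (Hz), > 0; default 5.
#' @param isi_shape Gamma ISI shape `kappa >= 1` (1 = Poisson); default 2.
#' @param modulation_amplitude_pct Signed peak rate modulation (%), one
#'   value per injection (recycled); e.g. `+40` doubles .4 of the rate.
#' @param onset_latency_s Latency from injection to modulation onset (s).
#' @param response_duration_s Modulation duration (s), default 180.
#' @param kernel `"plateau"` (linear 10 s ramps, default) or
#'   `"difference_of_exponentials"`.
#' @param ramp_s Ramp length for the plateau kernel (s), default 10.
#' @param seed Optional seed.
#' @return An object of class `neuron_sim_spec`.
#' @export
neuron_sim_spec <- function(baseline_rate_hz = 5, isi_shape = 2,
                            modulation_amplitude_pct = 0,
                            onset_latency_s = 0, response_duration_s = 180,
                            kernel = c("plateau",
                                       "difference_of_exponentials"),
                            ramp_s = 10, seed = NULL) {
  kernel <- match.arg(kernel)
  stopifnot_scalar_number(baseline_rate_hz, "baseline_rate_hz", positive = TRUE)
  stopifnot_scalar_number(isi_shape, "isi_shape", positive = TRUE)
  if (isi_shape < 1) stop("`isi_shape` must be >= 1", call. = FALSE)
  stopifnot_scalar_number(response_duration_s, "response_duration_s",
                          positive = TRUE)
  structure(list(baseline_rate_hz = baseline_rate_hz, isi_shape = isi_shape,
                 modulation_amplitude_pct = modulation_amplitude_pct,
                 onset_latency_s = onset_latency_s,
                 response_duration_s = response_duration_s,
                 kernel = kernel, ramp_s = ramp_s, seed = seed),
            class = "neuron_sim_spec")
}

# Unit-peak response kernel g(s) supported on [latency, latency + duration].
response_kernel_value <- function(s, kernel, latency, duration, ramp) {
  g <- numeric(length(s))
  u <- s - latency
  inside <- u >= 0 & u <= duration
  if (kernel == "plateau") {
    ramp <- min(ramp, duration / 2)
    ui <- u[inside]
    gi <- pmin(1, ui / ramp, (duration - ui) / ramp)
    g[inside] <- pmax(0, gi)
  } else {
    tau_d <- duration / 4
    tau_r <- duration / 20
    ui <- u[inside]
    raw <- exp(-ui / tau_d) - exp(-ui / tau_r)
    s_peak <- log(tau_d / tau_r) / (1 / tau_r - 1 / tau_d)
    g[inside] <- raw / (exp(-s_peak / tau_d) - exp(-s_peak / tau_r))
  }
  g
}

#' Simulate one spike train as a time-rescaled gamma renewal process
#'
#' Intensity `lambda(t) = lambda0 * max(0, 1 + sum_j (m_j/100) *
#' g(t - t_j))` where `g` is the unit response kernel; spikes are generated
#' by drawing a unit-rate gamma renewal process (shape `kappa`, rate
#' `kappa`) in rescaled time and mapping back through the inverse
#' cumulative intensity. Deterministic for a fixed seed.
#'
#' @param spec A [neuron_sim_spec()].
#' @param epoch Numeric `c(start, end)` (s).
#' @param injection_times Numeric injection times (s), possibly empty.
#' @param neuron_id Identifier for the emitted train, default `"sim"`.
#' @param seed Optional seed overriding `spec$seed`.
#' @return A [spike_train()].
#' @export
simulate_neuron <- function(spec, epoch, injection_times = numeric(0),
                            neuron_id = "sim", seed = NULL) {
  stopifnot(inherits(spec, "neuron_sim_spec"))
  if (is.null(seed)) seed <- spec$seed
  lambda0 <- spec$baseline_rate_hz
  kappa <- spec$isi_shape
  m <- rep_len(spec$modulation_amplitude_pct,
               max(1L, length(injection_times)))
  dt <- 0.01
  grid <- seq(epoch[1L], epoch[2L], by = dt)
  mod <- numeric(length(grid))
  for (j in seq_along(injection_times)) {
    mod <- mod + (m[j] / 100) *
      response_kernel_value(grid - injection_times[j], spec$kernel,
                            spec$onset_latency_s, spec$response_duration_s,
                            spec$ramp_s)
  }
  lam <- lambda0 * pmax(0, 1 + mod)
  cum <- c(0, cumsum((lam[-1L] + lam[-length(lam)]) / 2 * dt))
  total <- cum[length(cum)]
  times <- with_seed(seed, {
    n_draw <- ceiling(total + 10 * sqrt(max(total, 1) / kappa) + 50)
    rescaled <- cumsum(rgamma(n_draw, shape = kappa, rate = kappa))
    rescaled <- rescaled[rescaled <= total]
    if (length(rescaled))
      approx(cum, grid, xout = rescaled, ties = "ordered")$y
    else numeric(0)
  })
  times <- times[c(TRUE, diff(times) > 0)]
  spike_train(neuron_id, times, epoch_start = epoch[1L],
              epoch_end = epoch[2L])
}

#' Specification of a simulated two-drug population
#'
#' Defaults mirror the composition reported for paired nicotine/ethanol
#' injections in vivo: ~57% activated, ~39% inhibited, ~4% non-responsive
#' neurons to the first drug, with a cross-drug polarity concordance of
#' 0.8 and a planted response magnitude of 40%.
#'
#' @param n_neurons Number of neurons.
#' @param fractions Named numeric `(activated, inhibited, nonresponsive)`
#'   summing to 1 (composition for drug 1).
#' @param cross_drug_concordance Probability `rho` that the drug-2 polarity
#'   equals the drug-1 polarity (responsive neurons only).
#' @param projection_polarity_map Named character mapping each drug-1 label
#'   to a projection target (`"NAc"`, `"Amg"`, `"unknown"`).
#' @param amplitude_pct Planted absolute response magnitude (%), default 40.
#' @param baseline_rate_hz,isi_shape Baseline train parameters.
#' @param seed Optional root seed; per-neuron streams are derived from it.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n_neurons = 72,
                            fractions = c(activated = 41 / 72,
                                          inhibited = 28 / 72,
                                          nonresponsive = 3 / 72),
                            cross_drug_concordance = 0.8,
                            projection_polarity_map = c(
                              activated = "NAc", inhibited = "Amg",
                              nonresponsive = "unknown"),
                            amplitude_pct = 40, baseline_rate_hz = 5,
                            isi_shape = 2, seed = NULL) {
  if (!all(c("activated", "inhibited", "nonresponsive") %in% names(fractions)))
    stop("`fractions` must name activated, inhibited, nonresponsive",
         call. = FALSE)
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-8)
    stop("`fractions` must be non-negative and sum to 1", call. = FALSE)
  rho <- cross_drug_concordance
  if (rho < 0 || rho > 1)
    stop("`cross_drug_concordance` must be in [0, 1]", call. = FALSE)
  if (!all(projection_polarity_map %in% c("NAc", "Amg", "unknown")))
    stop("projection map values must be NAc, Amg or unknown", call. = FALSE)
  if (!all(names(fractions)[fractions > 0] %in%
           names(projection_polarity_map)))
    stop("projection map lacks an entry for a populated label", call. = FALSE)
  structure(list(n_neurons = n_neurons, fractions = fractions,
                 cross_drug_concordance = rho,
                 projection_polarity_map = projection_polarity_map,
                 amplitude_pct = amplitude_pct,
                 baseline_rate_hz = baseline_rate_hz,
                 isi_shape = isi_shape, seed = seed),
            class = "population_spec")
}

#' Default two-drug injection protocol
#'
#' Drug 1 at 300 s (after a 5-min baseline), drug 2 at 900 s so that its
#' own 5-min baseline is clear of the first response period; epoch ends
#' 190 s after the second injection.
#'
#' @param t_inject Injection times (s), default `c(300, 900)`.
#' @param substances Substance per injection.
#' @param doses,dose_units Dose metadata per injection.
#' @param epoch Recording epoch `c(start, end)` (s).
#' @return A list protocol understood by [simulate_population()].
#' @export
two_drug_protocol <- function(t_inject = c(300, 900),
                              substances = c("nicotine", "ethanol"),
                              doses = c(30, 250),
                              dose_units = c("ug/kg", "mg/kg"),
                              epoch = c(0, max(t_inject) + 190)) {
  list(t_inject = t_inject, substances = substances, doses = doses,
       dose_units = dose_units, epoch = epoch)
}

#' Draw ground-truth two-drug polarity pairs
#'
#' The polarity layer of the population generator: drug-1 labels drawn from
#' `fractions`; a responsive neuron's drug-2 polarity equals its drug-1
#' polarity with probability `rho`, and is flipped otherwise;
#' non-responsive neurons stay non-responsive to both drugs.
#'
#' @param n Number of neurons.
#' @param fractions Named numeric `(activated, inhibited, nonresponsive)`
#'   summing to 1.
#' @param rho Cross-drug concordance probability in `[0, 1]`.
#' @param seed Optional seed.
#' @return Data frame with `polarity_drug1`, `polarity_drug2`.
#' @export
simulate_polarity_pairs <- function(n, fractions = c(activated = 41 / 72,
                                                     inhibited = 28 / 72,
                                                     nonresponsive = 3 / 72),
                                    rho = 0.8, seed = NULL) {
  if (rho < 0 || rho > 1) stop("`rho` must be in [0, 1]", call. = FALSE)
  labels <- c("activated", "inhibited", "nonresponsive")
  if (!all(labels %in% names(fractions)))
    stop("`fractions` must name activated, inhibited, nonresponsive",
         call. = FALSE)
  draws <- with_seed(seed, {
    pol1 <- sample(labels, n, replace = TRUE, prob = fractions[labels])
    same <- runif(n) < rho
    list(pol1 = pol1, same = same)
  })
  pol1 <- draws$pol1
  pol2 <- ifelse(pol1 == "nonresponsive", "nonresponsive",
                 ifelse(draws$same, pol1,
                        ifelse(pol1 == "activated", "inhibited",
                               "activated")))
  data.frame(polarity_drug1 = pol1, polarity_drug2 = pol2)
}

#' Simulate a population of two-drug neuron records with ground truth
#'
#' Drug-1 polarities are drawn from `fractions`; a responsive neuron's
#' drug-2 polarity equals its drug-1 polarity with probability `rho` (and
#' is flipped otherwise); non-responsive neurons stay non-responsive to
#' both. Projection targets follow the polarity map. Each neuron's spike
#' train is an independent gamma-renewal train modulated at both
#' injections.
#'
#' @param spec A [population_spec()].
#' @param protocol A [two_drug_protocol()].
#' @return A list with `records` (list of [neuron_record()]) and `truth`
#'   (data.frame: `neuron_id`, `polarity_drug1`, `polarity_drug2`,
#'   `projection`, `amplitude1_pct`, `amplitude2_pct`).
#' @export
simulate_population <- function(spec, protocol = two_drug_protocol()) {
  stopifnot(inherits(spec, "population_spec"))
  n <- spec$n_neurons
  pairs <- simulate_polarity_pairs(n, spec$fractions,
                                   rho = spec$cross_drug_concordance,
                                   seed = spec$seed)
  pol1 <- pairs$polarity_drug1
  pol2 <- pairs$polarity_drug2
  amp <- function(pol) switch(pol, activated = spec$amplitude_pct,
                              inhibited = -spec$amplitude_pct, 0)
  ids <- sprintf("n%03d", seq_len(n))
  records <- vector("list", n)
  for (i in seq_len(n)) {
    nspec <- neuron_sim_spec(baseline_rate_hz = spec$baseline_rate_hz,
                             isi_shape = spec$isi_shape,
                             modulation_amplitude_pct = c(amp(pol1[i]),
                                                          amp(pol2[i])))
    train <- simulate_neuron(nspec, epoch = protocol$epoch,
                             injection_times = protocol$t_inject,
                             neuron_id = ids[i],
                             seed = child_seed(spec$seed, ids[i]))
    injections <- mapply(injection_event, protocol$t_inject,
                         protocol$substances, protocol$doses,
                         protocol$dose_units, SIMPLIFY = FALSE)
    records[[i]] <- neuron_record(
      ids[i], train, injections = injections,
      projection = unname(spec$projection_polarity_map[pol1[i]]))
  }
  names(records) <- ids
  truth <- data.frame(neuron_id = ids, polarity_drug1 = pol1,
                      polarity_drug2 = pol2,
                      projection = unname(spec$projection_polarity_map[pol1]),
                      amplitude1_pct = vapply(pol1, amp, 0),
                      amplitude2_pct = vapply(pol2, amp, 0))
  rownames(truth) <- NULL
  list(records = records, truth = truth)
}

#' Simulate a noisy current trace with planted synaptic events
#'
#' Gaussian baseline noise plus biexponential events at Poisson times (or
#' at `event_times` when given) and optional evoked events at `stim_times`.
#' The planted events are returned as ground truth.
#'
#' @param duration_s Trace duration (s).
#' @param sampling_rate Sampling rate (Hz), >= 1000; default 10000.
#' @param noise_sd_pA Gaussian noise SD (pA), >= 0.
#' @param event_rate_hz Poisson rate of spontaneous events (Hz).
#' @param amplitude_mean_pA Mean signed event amplitude (pA), default -50
#'   (inward).
#' @param amplitude_sd_pA SD of event amplitudes (pA), default 0.
#' @param tau_rise_ms,tau_decay_ms Event kinetics (ms).
#' @param event_times Optional explicit event onsets (s), overriding the
#'   Poisson draw.
#' @param stim_times Optional stimulation times (s); each adds an evoked
#'   event of amplitude `evoked_amplitude_pA`.
#' @param evoked_amplitude_pA Amplitude of evoked events (pA).
#' @param seed Optional seed.
#' @return A [current_trace()] with attribute `ground_truth`: data.frame
#'   `onset_s`, `amplitude_pA`, `evoked`.
#' @export
simulate_current_trace <- function(duration_s, sampling_rate = 10000,
                                   noise_sd_pA = 5, event_rate_hz = 0,
                                   amplitude_mean_pA = -50,
                                   amplitude_sd_pA = 0, tau_rise_ms = 1,
                                   tau_decay_ms = 8, event_times = NULL,
                                   stim_times = NULL,
                                   evoked_amplitude_pA = amplitude_mean_pA,
                                   seed = NULL) {
  if (sampling_rate < 1000)
    stop("`sampling_rate` must be at least 1 kHz", call. = FALSE)
  if (noise_sd_pA < 0) stop("`noise_sd_pA` must be >= 0", call. = FALSE)
  n <- round(duration_s * sampling_rate)
  kern <- biexp_kernel(tau_rise_ms, tau_decay_ms,
                       sampling_rate = sampling_rate, sign = 1)
  out <- with_seed(seed, {
    x <- rnorm(n, sd = noise_sd_pA)
    onsets <- if (!is.null(event_times)) sort(as.numeric(event_times))
              else if (event_rate_hz > 0)
                sort(runif(rpois(1, event_rate_hz * duration_s), 0,
                           duration_s - length(kern) / sampling_rate))
              else numeric(0)
    amps <- if (length(onsets))
      amplitude_mean_pA + rnorm(length(onsets), sd = amplitude_sd_pA)
    else numeric(0)
    evoked <- rep(FALSE, length(onsets))
    if (!is.null(stim_times)) {
      onsets <- c(onsets, stim_times)
      amps <- c(amps, rep(evoked_amplitude_pA, length(stim_times)))
      evoked <- c(evoked, rep(TRUE, length(stim_times)))
    }
    for (k in seq_along(onsets)) {
      i0 <- round(onsets[k] * sampling_rate) + 1L
      ii <- i0:min(n, i0 + length(kern) - 1L)
      if (ii[1L] > n) next
      x[ii] <- x[ii] + amps[k] * kern[seq_along(ii)]
    }
    ord <- order(onsets)
    list(x = x, truth = data.frame(onset_s = onsets[ord],
                                   amplitude_pA = amps[ord],
                                   evoked = evoked[ord]))
  })
  trace <- current_trace(out$x, sampling_rate, stim_times = stim_times)
  attr(trace, "ground_truth") <- out$truth
  trace
}
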