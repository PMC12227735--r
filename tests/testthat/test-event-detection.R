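test_that("templates average example currents and normalise the peak", {
  onsets <- seq(0.2, 9.5, length.out = 15)
  # identical noise-free events: template reproduces the kernel
  tr <- simulate_current_trace(10, noise_sd_pA = 0, event_times = onsets,
                               amplitude_mean_pA = -60, seed = 1)
  tpl <- build_template(tr, onsets)
  expect_equal(tpl$n_source_events, 15L)
  expect_equal(max(abs(tpl$waveform)), 1)
  expect_equal(tpl$peak_sign, -1)
  kern <- biexp_kernel(sign = -1)
  expect_equal(tpl$waveform, kern[seq_along(tpl$waveform)], tolerance = 1e-6)

  expect_error(build_template(tr, onsets[1:14]), "at least 15")
  expect_error(build_template(tr, rep(0.2, 15) + 1e-4 * (0:14)), "overlap")

  # with noise, the average is closer to the truth than any single snippet
  onsets20 <- seq(0.2, 9.5, length.out = 20)
  trn <- simulate_current_trace(10, noise_sd_pA = 4, event_times = onsets20,
                                amplitude_mean_pA = -60, seed = 2)
  tpln <- build_template(trn, onsets20)
  m <- length(tpln$waveform)
  shape_true <- 60 * biexp_kernel(sign = -1)[1:m] # the planted -60 pA event
  fs <- trn$sampling_rate
  l2_tpl <- sqrt(sum((60 * tpln$waveform - shape_true)^2))
  l2_single <- vapply(onsets20, function(o) {
    i <- round(o * fs) + 1L
    snip <- trn$samples[i:(i + m - 1L)]
    sqrt(sum((snip - shape_true)^2))
  }, 0)
  expect_lt(l2_tpl, min(l2_single))
})

test_that("noise SD estimation is robust to embedded events", {
  set.seed(91)
  pure <- current_trace(rnorm(20000, sd = 5), 10000)
  expect_lt(abs(estimate_noise_sd(pure) - 5), 0.5)

  expect_equal(estimate_noise_sd(current_trace(rep(3.3, 5000), 10000)), 0)

  # rare large events, masked out: estimate tracks sigma, not the events
  onsets <- seq(0.5, 4.5, by = 0.5)
  tr <- simulate_current_trace(5, noise_sd_pA = 5, event_times = onsets,
                               amplitude_mean_pA = -300, seed = 92)
  mask <- rep(FALSE, length(tr$samples))
  for (o in onsets) {
    i <- round(o * 10000) + 1L
    mask[i:(i + 900)] <- TRUE
  }
  expect_lt(abs(estimate_noise_sd(tr, mask) - 5), 0.5)

  expect_error(estimate_noise_sd(pure, rep(TRUE, 20000)), "unmasked")
})

test_that("detector finds strong planted events and honours the 3-sigma rule", {
  onsets <- seq(0.3, 9.7, length.out = 20)
  tpl_src <- simulate_current_trace(10, noise_sd_pA = 1,
                                    event_times = seq(0.3, 9.7,
                                                      length.out = 16),
                                    amplitude_mean_pA = -50, seed = 101)
  tpl <- build_template(tpl_src, seq(0.3, 9.7, length.out = 16))

  # 5-sigma events: all detected, amplitudes within 20%
  tr5 <- simulate_current_trace(10, noise_sd_pA = 5, event_times = onsets,
                                amplitude_mean_pA = -25, seed = 102)
  ev <- detect_events(tr5, tpl, noise_sd = 5)
  hits <- vapply(onsets, function(o) any(abs(ev$onset_s - o) < 0.01), TRUE)
  expect_true(all(hits))
  matched <- vapply(onsets,
                    function(o) ev$amplitude_pA[which.min(abs(ev$onset_s - o))],
                    0)
  expect_true(all(abs(matched + 25) / 25 < 0.20))

  # 2-sigma events: all rejected by the amplitude rule
  tr2 <- simulate_current_trace(10, noise_sd_pA = 5, event_times = onsets,
                                amplitude_mean_pA = -10, seed = 103)
  expect_equal(nrow(detect_events(tr2, tpl, noise_sd = 5)), 0L)

  # pure noise: no false positives over 10 s at the default criterion
  tr0 <- simulate_current_trace(10, noise_sd_pA = 5, seed = 104)
  expect_equal(nrow(detect_events(tr0, tpl, noise_sd = 5)), 0L)

  expect_error(detect_events(tr5, tpl, noise_sd = 0), "positive")
})

test_that("detection is equivariant under amplitude rescaling", {
  onsets <- seq(0.4, 4.6, length.out = 8)
  tpl_src <- simulate_current_trace(10, noise_sd_pA = 1,
                                    event_times = seq(0.3, 9.7,
                                                      length.out = 15),
                                    amplitude_mean_pA = -50, seed = 111)
  tpl <- build_template(tpl_src, seq(0.3, 9.7, length.out = 15))
  tr <- simulate_current_trace(5, noise_sd_pA = 5, event_times = onsets,
                               amplitude_mean_pA = -30, seed = 112)
  ev1 <- detect_events(tr, tpl, noise_sd = 5)
  scaled <- current_trace(tr$samples * 7, tr$sampling_rate)
  ev7 <- detect_events(scaled, tpl, noise_sd = 35)
  expect_equal(ev7$onset_s, ev1$onset_s)
  expect_equal(ev7$amplitude_pA, 7 * ev1$amplitude_pA, tolerance = 1e-9)
  expect_equal(ev7$score, ev1$score, tolerance = 1e-9)
})

test_that("evoked amplitude is the extremal deviation from baseline", {
  flat <- current_trace(rep(0, 10000), 10000)
  expect_equal(evoked_amplitude(flat, 0.5, c(0.1, 0.5), c(0.5, 0.9)), 0)

  stepped <- current_trace(c(rep(0, 5000), rep(-50, 5000)), 10000)
  expect_equal(evoked_amplitude(stepped, 0.5, c(0.1, 0.5), c(0.5, 0.9)), -50)

  expect_error(evoked_amplitude(flat, 0.5, c(0.1, 0.6), c(0.5, 0.9)),
               "overlap")
  expect_error(evoked_amplitude(flat, 0.5, c(0.1, 0.4), c(0.45, 0.9)),
               "after the stimulus")

  # biexponential of known peak on a noisy baseline; the recovered peak
  # carries the baseline error plus near-peak noise
  tr <- simulate_current_trace(2, noise_sd_pA = 1, stim_times = 1,
                               evoked_amplitude_pA = -80, seed = 121)
  amp <- evoked_amplitude(tr, 1, c(0.2, 1), c(1, 1.2))
  expect_lt(abs(amp + 80), 4)
})
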