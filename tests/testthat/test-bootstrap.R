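test_that("ISI shuffling conserves count, span and the ISI multiset", {
  set.seed(41)
  base <- cumsum(rgamma(100, 2, 10))
  surr <- shuffle_isis(base)
  expect_equal(length(surr), length(base))
  expect_equal(surr[1], base[1])
  expect_equal(max(surr), max(base))
  expect_equal(sort(diff(surr)), sort(diff(base)))

  # a regular train is invariant under shuffling
  reg <- seq(0, 10, by = 0.5)
  expect_equal(shuffle_isis(reg), reg)

  expect_error(shuffle_isis(c(1, 2)), "insufficient baseline")
})

test_that("ISI shuffles are uniform over orderings", {
  # 4 spikes with 3 distinct ISIs: 3! = 6 equally likely surrogate orders
  base <- c(0, 1, 3, 6)
  set.seed(42)
  keys <- replicate(6000, paste(diff(shuffle_isis(base)), collapse = "|"))
  freq <- table(keys)
  expect_length(freq, 6L)
  mc_se <- sqrt((1 / 6) * (5 / 6) / 6000)
  expect_true(all(abs(freq / 6000 - 1 / 6) < 3 * mc_se))
})

test_that("null distribution is reproducible and degenerate for regular trains", {
  set.seed(43)
  base <- cumsum(rgamma(1500, 2, 10))
  a <- build_null_distribution(base, 5, 10, n_shuffles = 50, seed = 7)
  b <- build_null_distribution(base, 5, 10, n_shuffles = 50, seed = 7)
  expect_identical(a$values, b$values)
  expect_length(a$values, 50L)

  # 0.25 s ISI is exactly representable, so every shuffle is bit-identical
  reg <- seq(0, 299.75, by = 0.25)
  nd <- build_null_distribution(reg, 5, 10, n_shuffles = 20, seed = 1)
  expect_equal(length(unique(nd$values)), 1L)

  expect_error(build_null_distribution(base[1:50], 5, 10),
               "shorter than")
})

test_that("uncorrected null mean matches an independent re-implementation", {
  set.seed(44)
  base <- cumsum(rexp(1500, 5))
  base <- base[base < 300]
  m <- length(base) / 300
  nd <- build_null_distribution(base, m, 10, n_shuffles = 400,
                                variance_correction = FALSE, seed = 9)
  set.seed(45)
  oracle <- oracle_null_values(base, m, 10, n_shuffles = 400)
  se <- sqrt(var(nd$values) / 400 + var(oracle) / 400)
  expect_lt(abs(mean(nd$values) - mean(oracle)), 3 * se)
})

test_that("mid-rank percentile counts ties as half", {
  expect_equal(percentile_of(5, c(-10, 0, 10, 20)), 0.5)
  expect_equal(percentile_of(100, c(-10, 0, 10, 20)), 1)
  expect_equal(percentile_of(-100, c(-10, 0, 10, 20)), 0)
  # observation equal to a degenerate null sits at the mid-rank
  expect_equal(percentile_of(3, rep(3, 100)), 0.5)
  expect_error(percentile_of(1, numeric(0)), "empty null")
})

test_that("the percentile rule assigns labels and flags tail/sign conflicts", {
  expect_equal(classify_response(8, 0.50)$label, "nonresponsive")
  expect_equal(classify_response(35, 0.99)$label, "activated")
  expect_equal(classify_response(35, 0.95)$label, "activated")
  expect_equal(classify_response(-40, 0.01)$label, "inhibited")
  expect_equal(classify_response(-40, 0.05)$label, "inhibited")
  # boundary just inside the acceptance region
  expect_equal(classify_response(10, 0.9499)$label, "nonresponsive")
  # extreme percentile but contradictory sign -> flagged, not relabelled
  conf <- classify_response(-12, 0.99)
  expect_equal(conf$label, "nonresponsive")
  expect_true(conf$conflict)
  conf0 <- classify_response(0, 0.99)
  expect_true(conf0$conflict)
})

test_that("classification power is nondecreasing in modulation amplitude", {
  # common random numbers: same per-neuron seeds across amplitude levels
  amps <- c(0, 15, 30, 60)
  n_per <- 40
  power <- vapply(amps, function(m) {
    mean(vapply(seq_len(n_per), function(i) {
      st <- simulate_neuron(
        neuron_sim_spec(modulation_amplitude_pct = m, seed = 600 + i),
        epoch = c(0, 490), injection_times = 300)
      classify_drug_response(st, 300, n_shuffles = 300,
                             seed = 700 + i)$label != "nonresponsive"
    }, TRUE))
  }, 0)
  expect_true(all(diff(power) >= -1 / n_per))
  expect_gt(power[4], 0.95)
  expect_lt(power[1], 0.3)
})

test_that("classification is deterministic given seed and config", {
  st <- simulate_neuron(neuron_sim_spec(modulation_amplitude_pct = 25,
                                        seed = 50),
                        epoch = c(0, 490), injection_times = 300)
  a <- classify_drug_response(st, 300, n_shuffles = 200, seed = 13)
  b <- classify_drug_response(st, 300, n_shuffles = 200, seed = 13)
  expect_identical(a[c("delta_f_pct", "percentile", "label")],
                   b[c("delta_f_pct", "percentile", "label")])
})

test_that("drug-vs-saline contrast follows the normality screen", {
  # identical pairs: no difference, no rejection
  x <- c(10, 12, 14, 16, 18)
  res <- contrast_drug_vs_saline(x, x)
  expect_equal(res$p_value, 1)
  expect_false(res$significant)

  # constant +30 shift with tiny noise: rejected
  set.seed(51)
  sal <- rnorm(12, 5, 1)
  res <- contrast_drug_vs_saline(sal + 30 + rnorm(12, 0, 0.1), sal)
  expect_true(res$significant)
  expect_equal(res$mean_difference, 30, tolerance = 0.05)

  # skewed differences route to the rank test
  set.seed(52)
  sal2 <- rnorm(20)
  res <- contrast_drug_vs_saline(sal2 + rexp(20)^3, sal2)
  expect_equal(res$test, "paired wilcoxon")

  expect_error(contrast_drug_vs_saline(1:2, 3:4), "3 pairs")
})

test_that("Holm adjustment matches the hand computation", {
  out <- adjust_contrasts(c(0.01, 0.04, 0.03), alpha = 0.05)
  expect_equal(out$p_holm, c(0.03, 0.06, 0.06))
  expect_equal(out$reject, c(TRUE, FALSE, FALSE))
})

test_that("dose-response polarity comes from the first significant dose", {
  expect_equal(first_significant_dose(c(125, 250),
                                      c("nonresponsive", "inhibited")),
               "inhibited")
  expect_equal(first_significant_dose(c(125, 250, 500),
                                      c("activated", "inhibited",
                                        "inhibited")),
               "activated")
  expect_equal(first_significant_dose(c(125, 250),
                                      rep("nonresponsive", 2)),
               "unclassified")
  expect_error(first_significant_dose(c(250, 125),
                                      c("activated", "inhibited")),
               "ascending")
  expect_error(first_significant_dose(125, "maybe"), "unknown label")
})

test_that("a dose-threshold neuron is classified from its first effective dose", {
  # no response at the low dose, inhibition at the high dose
  spec <- neuron_sim_spec(modulation_amplitude_pct = c(0, -45), seed = 61)
  st <- simulate_neuron(spec, epoch = c(0, 1090),
                        injection_times = c(300, 900))
  low <- classify_drug_response(st, 300, n_shuffles = 500, seed = 62)
  high <- classify_drug_response(st, 900, n_shuffles = 500, seed = 63)
  expect_equal(low$label, "nonresponsive")
  expect_equal(high$label, "inhibited")
  expect_equal(first_significant_dose(c(125, 250),
                                      c(low$label, high$label)),
               "inhibited")
})
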