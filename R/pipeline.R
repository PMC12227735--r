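# End-to-end orchestration: one configuration object, per-population
# classification and the two-drug concordance stage.

#' Analysis configuration
#'
#' Bundles every tunable of the pipeline with its default: 60 s rate
#' windows every 15 s, a 180 s response period, a 300 s baseline, 1000 ISI
#' shuffles, the (0.05, 0.95) percentile rule, 10000 concordance
#' surrogates, alpha 0.05.
#'
#' @param window_length,step Rate-window parameters (s).
#' @param response_period Response period (s).
#' @param baseline_duration Baseline length before each injection (s).
#' @param n_shuffles Number of ISI shuffles per neuron.
#' @param percentile_bounds Numeric `c(lower, upper)` percentile rule.
#' @param n_surrogates Surrogates for the concordance test.
#' @param alpha Significance level.
#' @param seed Root seed; per-neuron streams are derived from it by stable
#'   hashing of the neuron id, so results are order-independent.
#' @return An object of class `run_config`.
#' @export
run_config <- function(window_length = 60, step = 15, response_period = 180,
                       baseline_duration = 300, n_shuffles = 1000,
                       percentile_bounds = c(0.05, 0.95),
                       n_surrogates = 10000, alpha = 0.05, seed = NULL) {
  for (nm in c("window_length", "step", "response_period",
               "baseline_duration", "n_shuffles", "n_surrogates", "alpha"))
    stopifnot_scalar_number(get(nm), nm, positive = TRUE)
  if (length(percentile_bounds) != 2L ||
      percentile_bounds[1L] >= percentile_bounds[2L])
    stop("`percentile_bounds` must be an ordered pair", call. = FALSE)
  structure(list(window_length = window_length, step = step,
                 response_period = response_period,
                 baseline_duration = baseline_duration,
                 n_shuffles = n_shuffles,
                 percentile_bounds = percentile_bounds,
                 n_surrogates = n_surrogates, alpha = alpha, seed = seed),
            class = "run_config")
}

#' Classify every neuron of a population
#'
#' Runs the ISI-shuffle bootstrap classification for each neuron and each
#' requested injection. Neurons whose baseline is insufficient (too few
#' spikes, silent, or truncated by the epoch) are skipped with a logged
#' reason rather than failing the run.
#'
#' @param records List of [neuron_record()]s, or list of [spike_train()]s
#'   together with `injections`.
#' @param config A [run_config()].
#' @param injections Optional list of [injection_event()]s applied to every
#'   train when `records` are bare spike trains.
#' @param substance Optional filter: classify only injections of this
#'   substance.
#' @return A data.frame (class `classification_report`) with one row per
#'   neuron x injection: `neuron_id`, `substance`, `dose`, `t_inject`,
#'   `projection`, `baseline_hz`, `delta_f_pct`, `percentile`, `label`,
#'   `conflict`. Skipped neurons appear in attribute `skipped`.
#' @export
run_classify <- function(records, config = run_config(), injections = NULL,
                         substance = NULL) {
  stopifnot(inherits(config, "run_config"))
  rows <- list()
  skipped <- list()
  for (rec in records) {
    if (inherits(rec, "spike_train"))
      rec <- neuron_record(rec$neuron_id, rec,
                           injections = if (is.null(injections)) list()
                                        else injections)
    stopifnot(inherits(rec, "neuron_record"))
    inj_list <- rec$injections
    if (!is.null(substance))
      inj_list <- Filter(function(j) j$substance == substance, inj_list)
    for (inj in inj_list) {
      res <- tryCatch(
        classify_drug_response(
          rec$train, t_inject = inj$time,
          window_length = config$window_length, step = config$step,
          response_period = config$response_period,
          baseline_duration = config$baseline_duration,
          n_shuffles = config$n_shuffles,
          bounds = config$percentile_bounds,
          seed = child_seed(config$seed,
                            paste(rec$neuron_id, inj$substance, inj$time))),
        error = function(e) e)
      if (inherits(res, "error")) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          neuron_id = rec$neuron_id, substance = inj$substance,
          t_inject = inj$time, reason = conditionMessage(res))
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        neuron_id = rec$neuron_id, substance = inj$substance,
        dose = inj$dose, t_inject = inj$time,
        projection = rec$projection,
        baseline_hz = res$baseline_mean_hz,
        delta_f_pct = res$delta_f_pct, percentile = res$percentile,
        label = res$label, conflict = res$conflict)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(neuron_id = character(0), substance = character(0),
               dose = numeric(0), t_inject = numeric(0),
               projection = character(0), baseline_hz = numeric(0),
               delta_f_pct = numeric(0), percentile = numeric(0),
               label = character(0), conflict = logical(0))
  rownames(out) <- NULL
  if (!nrow(out)) warning("no neuron could be classified")
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped)
                          else NULL
  attr(out, "config") <- config
  class(out) <- c("classification_report", class(out))
  out
}

#' Two-drug concordance from two classification reports
#'
#' Joins two [run_classify()] reports on `neuron_id`, keeps neurons
#' responsive to both drugs (exclusions are logged in the result), and
#' computes the polarity concordance together with the pooled-surrogate
#' permutation test.
#'
#' @param report1,report2 Classification reports (one drug each).
#' @param config A [run_config()]; supplies `n_surrogates` and the
#'   concordance-test seed.
#' @return A list with `concordance` ([polarity_concordance()] result),
#'   `surrogate_test` ([surrogate_concordance_test()] result), `pairs`
#'   (joined data.frame of responsive neurons) and `n_excluded`.
#' @export
run_concordance <- function(report1, report2, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  shared <- intersect(report1$neuron_id, report2$neuron_id)
  if (!length(shared))
    stop("the two reports share no neuron ids", call. = FALSE)
  r1 <- report1[match(shared, report1$neuron_id), ]
  r2 <- report2[match(shared, report2$neuron_id), ]
  responsive <- r1$label != "nonresponsive" & r2$label != "nonresponsive"
  if (!any(responsive))
    stop("no neuron is responsive to both drugs", call. = FALSE)
  pairs <- data.frame(neuron_id = shared,
                      polarity_drug1 = r1$label,
                      polarity_drug2 = r2$label)[responsive, ]
  conc <- polarity_concordance(pairs$polarity_drug1, pairs$polarity_drug2)
  surr <- surrogate_concordance_test(
    pairs$polarity_drug1, pairs$polarity_drug2,
    n_surrogates = config$n_surrogates,
    seed = child_seed(config$seed, "concordance"))
  list(concordance = conc, surrogate_test = surr, pairs = pairs,
       n_excluded = sum(!responsive))
}
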