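---
title: "Classifying drug-evoked dopamine responses with an ISI-shuffle bootstrap"
author: "spikeboot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying drug-evoked dopamine responses with an ISI-shuffle bootstrap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikeboot)
```

## The problem

Midbrain dopamine neurons respond heterogeneously to drugs of abuse:
within the ventral tegmental area, an intravenous injection of nicotine or
ethanol increases the firing rate of some neurons and decreases that of
others, and the polarity of the response tracks the neuron's projection
target (accumbens-projecting neurons are mostly activated,
amygdala-projecting neurons mostly inhibited). Deciding, neuron by neuron,
whether a modest rate change within a few minutes of an injection is a
genuine response — rather than ordinary rate drift of an irregularly
firing cell — requires a null model for spontaneous rate variability.
`spikeboot` implements that decision as a bootstrap built from the
neuron's own baseline, together with the population-level statistics that
follow from it: cross-drug polarity concordance and its permutation test,
rule-based unit screening, and template-based synaptic event detection for
the accompanying slice experiments.

## The response statistic

Firing frequency is estimated on sliding windows (60 s long, stepped every
15 s by default; windows are half-open so a spike on a shared boundary is
counted once). Windowed rates are expressed as percent change from the
baseline mean,

$$v_k = 100\,\frac{r_k - \bar r_B}{\bar r_B},$$

where $\bar r_B$ is the mean of the windows fully contained in the
baseline interval (by default the 300 s preceding the injection). The
response statistic $\Delta f$ is the *signed extremal variation*: the
maximum and minimum of $v_k$ over windows whose centers fall in the
response period (the 180 s following the injection, interval open at the
left and closed at the right), keeping whichever has the larger magnitude.
On an exact non-zero tie the maximum is kept and a tie flag is set. A
window belongs to the response period if and only if its *center* does;
this center rule is simple, symmetric, and avoids ad hoc treatment of
windows straddling the injection.

## The ISI-shuffle bootstrap

The null asks: how large an extremal variation would this neuron show in a
response-period-length stretch of data that has the baseline's interspike
interval (ISI) statistics but no injection-locked structure? Each
surrogate is a pure permutation of the baseline ISI multiset
(`shuffle_isis()`): spike count, total span and the ISI multiset are
conserved exactly. On each of 1000 surrogates (default) the same windowed
statistic is computed over a stretch matching the observed response
period's window count, and the observed $\Delta f$ is located in the
resulting null by its mid-rank percentile (ties count half). A neuron is
*responsive* when the percentile is at least 0.95 or at most 0.05;
responsive neurons are labelled *activated* ($\Delta f > 0$) or
*inhibited* ($\Delta f < 0$). When an extreme percentile and the sign of
$\Delta f$ disagree the neuron is flagged and left non-responsive rather
than silently relabelled.

### Why the null needs a variance-matched reference

A subtlety matters here. The observed statistic compares *fresh*
response-period windows against a baseline mean estimated from a
*separate* stretch of data. A permuted surrogate, in contrast, conserves
the baseline's total rate exactly, so comparing its stretch windows
against that conserved mean omits two sources of variance that the
observed comparison has: the sampling error of the baseline mean and the
unconstrained fluctuation of a fresh stretch's local mean (a
finite-population effect of permuting a fixed multiset). Left uncorrected,
the null is too narrow and the test rejects stationary neurons at roughly
twice its nominal rate.

`build_null_distribution()` therefore re-references each surrogate: the
reference rate is $\hat m + \alpha\,(\bar r^{\text{rest}}_b - \bar r)$,
where $\bar r^{\text{rest}}_b$ is surrogate $b$'s mean rate *outside* the
evaluation stretch (empirically centred across surrogates) and the weight
$\alpha$ is fixed by matching first-order variances. With window length
$W$, stretch span $S$, out-of-stretch span $R = T - S$, baseline span $T$
and baseline-estimation span $B$,

$$\alpha = \frac{cT - R}{S}, \qquad
  c = \sqrt{\frac{W/S + W/B}{\,W/S + W/R\,}}.$$

The weight is a closed-form function of the window geometry — nothing is
fitted — and the surrogates remain pure ISI permutations. With the
correction, the fraction of simulated stationary gamma-renewal neurons
(5 Hz, shape 2, 300 s baseline) called responsive is within Monte-Carlo
error of the nominal 0.10 (two 5% tails); without it, about 0.21. The
acceptance suite re-measures this on 500 neurons. Setting
`variance_correction = FALSE` reproduces the plain conserved-mean null.

## Drug-versus-saline contrasts and dose series

Population contrasts of drug- versus saline-evoked extremal variations use
a normality screen on the paired differences (Shapiro-Wilk at p > 0.05)
to choose between a paired t-test and a paired Wilcoxon signed-rank test,
with Holm's step-down correction available across multiple contrasts
(`adjust_contrasts()`). For dose series, a neuron's overall polarity is
the polarity at the lowest dose whose bootstrap classification is
responsive (`first_significant_dose()`).

## Cross-drug concordance and its surrogate test

For neurons responsive to both drugs, concordance is the fraction of
neurons with the same response polarity for both
(`polarity_concordance()`); response magnitudes can additionally be
correlated with a product-moment coefficient
(`response_correlation()`). Whether the observed concordance exceeds
chance is tested by pooling and re-pairing: each of 10,000 surrogates
(default) pairs the drug-1 polarities with an independent random
permutation of the drug-2 polarities, preserving each drug's response
composition while destroying the pairing — the only exchangeable null
consistent with per-neuron pairing. The p-value is the add-one upper-tail
proportion with exact ties counted half,
$p = (1 + \#\{>\} + \tfrac12\#\{=\})/(B+1)$. The mid-tie count matters:
the concordance percentage of $n$ pairs takes at most $n+1$ values, and
counting ties fully makes null p-values markedly super-uniform (median
near 0.65 for $n = 30$); with ties at half weight the null p-values are
indistinguishable from uniform (Kolmogorov-Smirnov check in the
acceptance suite) while the add-one term still bounds p away from zero.
When every surrogate ties the observed value (e.g. both polarity lists
constant) the test is degenerate and reports p = 1 with a warning.

## Unit screening

`is_putative_da()` applies the four in vivo identification criteria for
putative dopamine neurons — triphasic action potential with a marked
negative deflection, total duration above 2.0 ms, start-to-trough width
above 1.1 ms, and a firing rate strictly between 1 and 10 Hz — as strict
inequalities exactly as stated, reporting every failed criterion.
`opto_tag_test()` assesses direct optogenetic activation: the fraction of
light pulses followed by a spike within 10 ms is compared against a null
built by circularly shifting the pulse train by uniform random offsets,
which preserves the spike train's autostructure. The choice of a
circular-shift permutation test is this package's construction; the
criterion itself (no significant increase in firing probability within
10 ms of light onset) fixes only the window and the question.

## Synaptic event detection

Postsynaptic currents are extracted with the classical scaled-template
criterion: a template averaged from at least 15 example currents
(baseline-subtracted, unit peak) is fitted at every offset by least
squares in scale and offset, and the detection statistic is the fitted
scale over its standard error. Local maxima above the criterion threshold
(default 4) become candidates; candidates are kept only when the fitted
peak amplitude reaches 3 times the noise standard deviation, and overlaps
are resolved greedily by score with a refractory span of one template
length. The noise SD is the scaled median absolute deviation of first
differences outside detected events — a one-lag high-pass that removes
drift and most event energy and is robust to residual events. The
detection threshold and noise estimator are configurable because the
source analyses name only vendor software; the 15-example and
3-standard-deviation rules are applied as stated. At these defaults the
3-sigma amplitude rule dominates: sub-threshold events are rejected
outright and false positives on pure noise are practically absent, while
5-sigma events are recovered essentially completely with amplitude errors
of a few percent (re-measured in the acceptance suite).

## What the generators emulate — and what they do not

The synthetic module exists so that every stage can be scored against
planted truth:

* `simulate_neuron()` draws a time-rescaled gamma-renewal process with
  intensity $\lambda(t) = \lambda_0 \max\{0, 1 + (m/100)\,g(t-t_{inj})\}$.
  The default ISI shape $\kappa = 2$ reflects that dopamine-neuron firing
  is more regular than Poisson — and the ISI-shuffle null is only
  informative for irregular trains; $\kappa = 1$ recovers Poisson. The
  default kernel $g$ is a plateau with 10 s linear ramps spanning the
  3-minute response period: a deliberately simple shape that matches the
  duration of drug responses without claiming their exact kinetics. A
  difference-of-exponentials kernel is available. Inhibition floors the
  intensity at zero rather than allowing negative rates.
* `simulate_population()` plants a composition of activated / inhibited /
  non-responsive neurons (defaults mirror the reported two-drug
  composition: about 57% / 39% / 4%), a cross-drug concordance
  probability $\rho$ (default 0.8, the reported concordance level), a
  planted magnitude of 40%, and a deterministic polarity-to-projection
  map. Ground truth is emitted alongside the records.
* `simulate_current_trace()` adds biexponential events (1 ms rise, 8 ms
  decay by default, inward) at Poisson or listed times to Gaussian noise
  at 10 kHz.

These generators reproduce the statistical structure the analysis
*assumes*: stationary renewal baselines, step-like rate modulations,
independent neurons, Gaussian recording noise. Real recordings violate
each of these in places — slow drift, bursting, correlated state changes
under anesthesia, seal instabilities — so passing tests demonstrate
correctness of the statistical machinery under its stated model, not
robustness to every pathology of real data. The baseline duration for the
single-cell recordings is not fixed by the source description (5 min is
stated for the tetrode protocol); 300 s is adopted as the default
throughout and is configurable.

## Numerical choices and degenerate inputs

* Windows are placed from the analysis interval's start at multiples of
  the step; only fully contained windows are evaluated.
* The bootstrap uses one root seed; per-neuron streams are derived by a
  stable string hash of the neuron id, so results are independent of
  processing order and reproducible for a fixed seed and configuration.
* A silent baseline (0 Hz) is an error; in `run_classify()` such neurons
  are skipped with a logged reason. Fewer than 3 baseline spikes cannot be
  shuffled and are likewise skipped.
* A perfectly regular baseline yields a degenerate (single-valued) null;
  the mid-rank percentile then places any tying observation at 0.5, i.e.
  non-responsive.
* The SEM of a single-profile aggregate is defined as 0, with a warning.
* Spike tables are serialised at 17 significant digits so a write/read
  round trip is bit-exact; reports are written deterministically and
  carry a JSON manifest (configuration, seed, package version).

## Problem sizes used in validation

The shipped validation suite simulates 500 stationary neurons for the
type-I check, 200 neurons with planted ±40% responses for polarity
recovery, 200 replicate 30-pair populations each for the calibration and
power of the concordance test (2000 surrogates per replicate), and 100
planted events each for the detector's recall, rejection and amplitude
checks. These sizes put Monte-Carlo error comfortably inside the margins
being asserted while keeping a full run on one CPU within a few minutes.

## Known limitations

* The bootstrap assumes a stationary baseline; rate drift inflates the
  null spread and makes the test conservative for real responses, or can
  masquerade as a response if the drift is injection-locked.
* The variance-matched reference is a first-order (Gaussian) correction;
  it is exact neither for very short baselines nor for extremely regular
  trains, though the degenerate-regular case is handled by the mid-rank
  percentile.
* The concordance test conditions on each drug's composition; it does not
  model classification uncertainty in the polarity labels themselves.
* The event detector fits amplitude only; rise/decay kinetics are out of
  scope, as are vendor acquisition formats and spike sorting.
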