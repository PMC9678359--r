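---
title: "Intensity coding in insular broadband activity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intensity coding in insular broadband activity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(insulacoder)
```

## The scientific question and the measurement model

When people watch someone else in pain, populations of neurons in the
insula change their firing with the *perceived intensity* of that pain.
Intracranial EEG gives access to this signal through the **broadband
power (BBP)** of the local field potential — the baseline-normalized
spectral power averaged over 20–190 Hz — which tracks aggregate neuronal
spiking far better than any narrow oscillatory band. The package
implements the full statistical pipeline for asking, channel by channel
and millisecond by millisecond, whether BBP carries information about a
participant's ordinal intensity rating (options coded 1–4), and whether
that information is stimulus-specific (a hand being slapped vs. a
painful facial expression) or shared.

The measurement chain is:

1. **Bipolar re-referencing** of adjacent depth-electrode contacts
   (`bipolar_rereference()`), localizing the signal and rejecting common
   noise; a bipolar channel's coordinate is the midpoint of its
   contacts.
2. **Epoching** into 4 s trials (1 s pre-movie baseline, 2 s movie, 1 s
   post-movie), per-trial linear detrending, and decimation to 400 Hz
   (`epoch_and_detrend()`).
3. **Time–frequency decomposition** with a frequency-adaptive Hanning
   taper: at frequency $f$ the window spans $8/f$ seconds, clipped to
   $[0.1, 1]$ s (`tfr_hanning()`). Power is expressed per trial,
   channel and frequency as a baseline fraction
   $y(t) = (P(t) - P_0)/P_0$ with $P_0$ the mean over $[-1, 0)$ s
   (`baseline_percent_change()`); figures conventionally show
   $100\,y(t)$ %.
4. **Outlier-point rejection**: a time–frequency point of one trial is
   masked when it is more than 10 leave-one-out SDs from the mean of
   the other trials (`reject_outlier_points()`). Only points are
   dropped, never trials.
5. **Band averaging** over 20–190 Hz honoring the mask
   (`band_power()`).

## Intensity-coding statistics

Because ratings are ordinal, association is measured by **Spearman rank
correlation** with average-rank ties (`spearman_coding()`); one-tailed
p-values use the t approximation
$t = r\sqrt{(n-2)/(1-r^2)}$, $df = n-2$, with no Fisher transform
(coefficients stay well inside $\pm 0.5$ where $r$ and $z$ are
indistinguishable). `critical_r(60, 0.05)` reproduces the reference
significance bound $r = 0.214$ analytically. Partial rank correlations
are Pearson correlations of rank residuals (`partial_spearman()`),
identical to the classical partial-correlation recursion applied to the
Spearman coefficients.

**Multiple comparisons.** Across large time(–frequency) grids the
package uses cluster-based permutation
(`circular_shift_cluster_test()`): the observed statistic is the
per-point one-sample t of channel coefficients against zero; points
with two-tailed $p <$ `cluster_alpha` (default 0.05; configurable, the
choice is a cluster-*forming* threshold, not an inference level) form
4-connected clusters scored by summed t. The null circularly rotates
each channel's coefficient map along time — one uniform offset per
channel per iteration, shared across that channel's frequencies — which
preserves autocorrelation while destroying alignment. Cluster
$p_1 = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_{iter})$, so no
p-value is ever exactly zero. Condition differences (Hand vs. Face
coding) replace the rotation with random trial-to-condition
reassignment (`condition_shuffle_cluster_test()`). Across small sets of
adjacent bins or lags, Benjamini–Hochberg FDR at $q = 0.05$ is used
instead. Anatomical specificity is tested by a patient-stratified
resampling null (`whole_brain_resampling_null()`): each iteration draws
from every patient's whole-brain pool exactly as many coefficients as
that patient has insular channels.

**Bayesian complements.** Site-count enrichment uses the exact
one-sided binomial test and a directional Bayes factor with a
Beta(1,1) prior truncated to $(\alpha_0, 1]$
(`binomial_bf_plus()`) — this prior reproduces the reference values
17.09 and 27 analytically and is evaluated through the regularized
incomplete beta in log space. Paired contrasts use the default JZS
Bayes factor, i.e. a Cauchy(0, 0.707) prior on the standardized effect
integrated against the noncentral-t likelihood (`jzs_ttest_bf()`).
Evidence *against* a positive correlation uses a stretched-beta prior
folded to $\rho > 0$ with the classical approximate likelihood of a
correlation coefficient (`correlation_bf_plus()`). The reference
evidence-of-absence bound 0.085 at $n = 60$ originated from a
nonparametric (Kendall-tau) Bayes factor whose exact kernel is not
reproducible from its description; the constant is therefore shipped
verbatim as the default (`coding_thresholds()`), and in-package
recomputation (`correlation_bf_bound()`) is documented as approximate
(it lands near 0.10). Bayes factors attached to Kendall coefficients in
the spike module reuse the same parametric kernel and are flagged
`bf_approx`.

**Quadrant classification.** Each channel's $(r_{Hand}, r_{Face})$
pair is labeled `dual` (both $\ge r_{sig}$), `hand_pref` /
`face_pref` (one $\ge r_{sig}$, the other $< r_{absent}$),
`inconclusive` (one significant, the other between bounds) or `none`
(`classify_channels()`); `quadrant_enrichment()` tests whether the
dual and preference quadrants hold more channels than the per-site
error rates alone would produce, including the pessimistic
$\alpha = 0.25$ sensitivity re-run and the $\alpha^2$
double-false-positive variant.

**Decoding.** Pattern decoding of mean movie ratings from the channel
vector of period-averaged BBP uses partial least squares regression
(PLS1, SIMPLS deflation, column mean-centering, no variance scaling;
`plsr_fit()`), two components by default, inside a 1000-iteration
random 3-fold cross-validation over movies where the per-fold Pearson
correlation of predicted and actual ratings is the accuracy
(`cv_decode()`). Significance comes from re-running the whole scheme on
permuted ratings (`shuffle_null()`; default 1000 shuffles with a
scaled-down inner iteration count, flags reach the full 10,000 / 1000
scheme). Cross-stimulus generalization trains on two thirds of one
type's movies and predicts one third of the other's
(`cross_decode()`), optionally excluding channels (e.g. the dual-coding
sites).

**Stimulus information.** Motion energy is the mean Euclidean RGB
distance between corresponding pixels of consecutive frames
(`motion_energy()`); facial shape is the mean of action units 4 and 7
(brow lowering, lid tightening) with linear interpolation of missing
frames (`shape_signal()`). Single-component PLSR betas over frames
localize *when* a signal predicts ratings
(`plsr_beta_timecourse()`), and `lagged_information_correlation()`
correlates each channel's coding time course $r(t)$ with the
information profile $B(t + \text{lag})$ for lags 0–1000 ms in 40 ms
steps — positive lag meaning the information *precedes* the neural
coding — with optional partialling of a competing profile at the same
lag and an FDR-corrected group t-test per lag.

## The synthetic cohort

`cohort_spec()` fixes the emulated study conditions: 7 patients, 85
insular bipolar channels (5–19 per patient), 60 Hand and 60 Face
trials per patient covering 30 movies per type shown twice, and rating
probabilities equal to the printed patient means (Hand
13.6/26.4/36.9/23.1 %, Face 39.8/32.6/20.0/7.6 %). Ratings are sampled
independently per trial (the randomized presentation order justifies
ignoring serial structure); a movie's *intensity* is defined as the
empirical mean rating of its trials, which keeps the marginal rating
distribution exact at any cohort size while still giving movies a
stable identity for feature generation and decoding.

Each LFP trial is $1/f$-spectrum background noise (spectral shaping by
FFT, default exponent 1) plus a 20–190 Hz band-limited component whose
baseline variance equals the background's in-band variance. For coding
channels the band component's power is multiplied by
$1 + g\,(\text{rating}-1)$ inside the stimulus-matched window only
(Hand: 1.01–1.44 s; Face: 1.75–1.86 s and 1.91–1.98 s; 25 ms cosine
ramps at the edges). The in-band signal-to-background ratio of one was
chosen once as a realistic magnitude for insular broadband effects;
with it, gain 0.5 yields per-channel coding around $r \approx 0.7$ and
gain 0.12 around $r \approx 0.35$ in the early window. Because the
late window is only 0.18 s long, the same gain produces somewhat
weaker measured coding for Face than for Hand — a faithful consequence
of the window definitions, worth keeping in mind when interpreting
recovery experiments.

Stimulus features mirror the videos' structure: Hand movies get a
rating-independent lift bump near 0.5 s and a slap bump near 1.0 s
whose amplitude grows with intensity; Face movies get a motion bump
after 1 s and logistic AU4/AU7 ramps from about 1.1 s whose plateaus
grow with intensity; 50 frames per 2 s movie. Spike trains are
inhomogeneous Poisson with the pain-period (1–2 s) rate scaled by
$1 + g\,(\text{rating}-1)$.

What the generator does *not* emulate: volume conduction and electrode
geometry, line noise, artifacts beyond the ±10 SD rule,
patient-specific rating styles (all patients share the mean
probability table), serial trial dependencies, and realistic facial
rendering. Passing tests therefore demonstrate the *statistical
machinery* — calibration under the null, recovery of injected effects,
correct bookkeeping — not robustness to every pathology of clinical
recordings.

## Numerical choices and edge cases

* **Taper edges**: power at times whose window would cross the epoch
  boundary is `NA`, never zero-padded, so baselines cannot be
  contaminated; downstream period averages drop a trial from a
  correlation only when more than half of its in-period points are
  masked.
* **Resampling**: trials are fixed-length 4 s segments, so decimation
  is done by exact Fourier resampling (dropping bins above the target
  Nyquist). A polyphase FIR resampler was measured to leave ~7%
  passband ripple on a 30 Hz tone and was rejected; spectral
  truncation is exact for band-limited content, and its edge
  sensitivity is removed by the per-trial detrend plus the taper-edge
  invalidation above.
* **Percent change** is stored as a fraction; rendering as % is a
  display convention.
* **Cluster bookkeeping**: connected components are labeled by a
  sparse union-find over supra-threshold points (4-connectivity;
  diagonal neighbors are separate clusters); permutation iterations
  use a fast path that computes only the extreme cluster sums.
* **Degenerate inputs**: constant ratings or power flag a result as
  undefined rather than erroring mid-cohort; folds whose held-out
  ratings are constant, or whose training cross-covariance is exactly
  null on rank-deficient predictors, are skipped and excluded from the
  accuracy average; an exactly collinear covariate makes a partial
  correlation `NA` (undefined), not zero.
* **Perfect rank agreement** (tau = 1) is mapped just inside the open
  interval before the parametric correlation BF kernel is applied.

## Problem sizes in the shipped tests

The test-suite experiments run at desk scale, chosen so the full suite
completes in minutes on one core while keeping every Monte-Carlo
assertion's standard error well inside its tolerance: cluster
calibration uses 400 simulated experiments of 10 channels × 12
frequencies × 60 time points with 200 shift iterations; pipeline-level
recovery uses 15 replicate cohorts of 10 channels at full 60-trial
design; quadrant and decoding cohorts use 40 and 18 channels with the
time–frequency grid restricted to the baseline and analysis windows
(the `out_times` argument exists for exactly this purpose); shuffle
nulls use hundreds rather than thousands of shuffles. All scheme sizes
are arguments, and the full-scale settings (1000 cluster iterations,
10,000 shuffles, 100,000 resampling draws) are the documented
defaults of the corresponding functions where the reference analysis
used them.

## Known limitations

* The quadrant labels inherit the error rates of their two thresholds:
  at a true effect of $\rho \approx 0.35$ and 60 trials, the
  probability that a preference channel receives exactly the right
  label is only ~0.65 (significance is reached with probability ~0.87
  and evidence-of-absence on the other axis with ~0.76), so
  label-recovery experiments at that effect size plateau around 70% —
  a property of the criteria at this sample size, not of the
  implementation.
* The correlation Bayes factor is parametric; it stands in for the
  nonparametric Kendall-tau Bayes factor wherever tau is the
  coefficient, and is labeled as such in results.
* The whole-brain resampling treats extra-insular pools as given;
  no anatomical screening of those channels is modeled.
* Spike sorting, electrode localization, action-unit estimation from
  images, and all fMRI analyses are upstream/downstream of this
  package and out of its scope.
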