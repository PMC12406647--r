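---
title: "Action-timing control and auditory sensory attenuation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Action-timing control and auditory sensory attenuation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fracatten)
```

This vignette documents the models, numerical conventions and design choices
behind `fracatten`. The package analyses the self-stimulation paradigm: long
blocks of paced keypresses (every 0.8, 1.6 or 3.2 s) that either trigger a
tone (MA), trigger nothing (MO), or are replaced by passive listening (AV).
Two derived measures are joined: the fractal scaling exponent α of the
inter-keypress-interval (IKI) series, read as an index of implicit
action-timing control, and the windowed mean amplitudes of the auditory N1
and P2 ERP components, whose attenuation for self-generated sounds is the
sensory-attenuation effect.

## Detrended fluctuation analysis

`dfa()` implements the standard first-order procedure: centre the series,
integrate it by cumulative summation, tile the profile into non-overlapping
windows of `n` samples (one pass from the start, discarding the tail
remainder shorter than `n`), detrend each window by an OLS line on the
within-window index, form the fluctuation `F(n)` from the residuals, and
estimate α as the slope of `log F(n)` on `log n`. Natural logarithms are
used; the slope is invariant to the base.

Numerical conventions that deserve a sentence each:

- **Window ladder.** `generate_window_sizes()` starts at 4 and repeatedly
  multiplies the *unrounded* value by 1.2, flooring each value to an integer
  and deduplicating. A value is admitted while the unrounded value is at
  most 10% of the series length. For 512 samples this yields the 13 sizes
  4, 5, 6, 8, 9, 11, 14, 17, 20, 24, 29, 35, 42. Rounding instead of
  flooring, or filtering on the floored value, produces a different ladder;
  the rule here is pinned to the flooring dialect and covered by an exact
  test.
- **Fluctuation definition.** `F(n)` is the RMS residual pooled across all
  windows of size `n` (the square root of the mean squared residual). The
  alternative — averaging each window's RMS — introduces a Jensen bias that
  is material at 4-sample windows (a per-window RMS on ~2 residual degrees
  of freedom is markedly downward-biased), steepens the low-`n` end of the
  log–log plot, and inflates α by ≈ +0.03 to +0.04 across the persistence
  range. The pooled definition is also what the widely used DFA
  implementations compute, and it is the convention under which the
  package's recovery suite (mean |α̂ − H| ≤ 0.08 at 512 samples) holds.
- **Tiling.** One forward pass, no reversed second pass, no overlap. The
  choice is recorded in `dfa_result$meta`.
- **Classification.** α < 0.5 anti-persistent; 0.5 ≤ α ≤ 1 persistent;
  1 < α ≤ 1.2 "elevated" but treated as stationary (small-sample DFA is
  biased upward, so only exponents above 1.2 are called nonstationary);
  boundary values go to the higher-persistence bin. These cutpoints are
  conventions, not estimates.

Small-sample DFA is biased even with these choices: at 512 samples the mean
estimate overshoots low Hurst targets by up to ≈ 0.06 and high ones by
≈ 0.03. The test suite asserts the bias envelope rather than pretending the
estimator is unbiased.

## The fractional Gaussian noise oracle

DFA is validated against data with known scaling: `simulate_fgn()` draws
exact fractional Gaussian noise by circulant embedding of the theoretical
autocovariance `γ(k) = ½(|k+1|^{2H} − 2|k|^{2H} + |k−1|^{2H})`. The
embedding eigenvalues are checked and a materially negative eigenvalue is an
error, never a silent truncation — the generator must be trustworthy because
the DFA acceptance rests on it. For fGn the DFA exponent equals `H`, giving
a closed-form round trip.

`simulate_iki_series()` maps a target α one-to-one to `H` on (0, 1);
exponents ≥ 1 (fractional-Brownian-type series) are not supported as
generation targets and raise an error — observed exponents above 1 are
treated as estimation outcomes, not as something the generator should
produce. The realised draw is standardised to exact zero mean and unit SD
before affine scaling to the requested interval mean and SD. This makes each
block's marginal statistics exact (convenient for the shuffle control, whose
whole point is that mean and SD are held fixed) and costs nothing
downstream: DFA centres the series and α is scale-invariant. Long-range
dependence is the reason this matters — for persistent series the standard
error of the sample mean decays as `n^{H−1}`, not `n^{−1/2}`, so without
standardisation a 512-sample block at α = 0.7 would routinely sit several
"iid standard errors" away from its nominal mean. Values below 1 ms after
scaling are clipped to 1 ms with the count logged; at paradigm-typical
parameters (mean 0.85 s, SD 0.16 s) the clipping rate is zero. The marginal
distribution (Gaussian before clipping) is a modelling choice: only the mean
and SD of real IKI distributions are constrained by the study design.

## The shuffle-surrogate control

Differences in α between cells could in principle be artifacts of different
interval means or SDs rather than of sequential order.
`surrogate_anova_test()` rules this out: each of the 6 per-participant
series is independently permuted (preserving its multiset of values, hence
mean and SD, exactly), DFA is recomputed, and the 2 × 3 within-subject ANOVA
is re-run; 500 iterations (100 at desk scale) yield surrogate F
distributions for both main effects. Conventions:

- **Equivalent p** is `count(surrogate F ≥ observed F) / n_shuffles`, with
  ties counting against the observed effect. The `(k+1)/(n+1)` permutation
  convention is deliberately not used, so 1 exceedance in 500 gives exactly
  0.002 and 19 give 0.038.
- The loop compares **uncorrected F values**: since F, not p, is ranked, a
  sphericity correction would cancel out of the comparison.
- One master seed spawns an independent stream per iteration × series
  (Lehmer-step derivation), so runs are reproducible and the iteration
  order is immaterial.

Under an iid null (α target 0.5 everywhere) the equivalent p is
approximately uniform; the suite checks a false-positive rate of
0.05 ± 0.04 over 200 synthetic datasets at desk scale (8 participants, 100
shuffles). With 100 shuffles the attainable p values are the multiples of
0.01 and the ≥-tie convention makes the test marginally conservative-to-
liberal at the grid edges; the ± 0.04 band absorbs this granularity.

## The ERP chain

The processing order is fixed: filter → re-reference → epoch → baseline →
reject → drop-initial → average → motor-correct → localize → measure.
Baseline correction must precede peak-to-peak rejection (a DC-offset epoch
is not an artifact once baselined); permuting those stages changes results
and is not supported by the API.

- **Filtering.** `filter_continuous()` applies a zero-phase (forward–
  backward) Butterworth band-pass, 0.1–30 Hz, with a one-pass asymptotic
  slope of 12 dB/octave per edge (second-order sections), plus a zero-phase
  50 Hz Butterworth notch. The two band edges are cascaded as separate
  high-pass and low-pass stages because a single band-pass prototype with a
  0.1 Hz corner at EEG sampling rates is numerically fragile. The contract
  is stated as attenuation, and tested that way: an in-band 10 Hz sinusoid
  passes within 5%, a 50 Hz sinusoid is reduced below 10%, and a 100 μV DC
  offset is removed to below 1% outside edge transients.
- **Epoching.** Epochs span the half-open window [−200, 400) ms around
  sound onset, `round(0.6 · fs)` samples; events without a full window are
  dropped and counted. In MA/MO cells the keypress marker sits at −100 ms
  (the tone follows the press by 100 ms).
- **Rejection.** An epoch is removed iff any channel's peak-to-peak range
  *strictly* exceeds 200 μV ("exceeding" read literally); an epoch at
  exactly 200 μV is retained. Independent-component artifact correction is
  out of scope: threshold rejection is the only cleaning implemented, which
  is sufficient for synthetic data with no ocular activity.
- **Bookkeeping.** The first 13 epochs are dropped to mirror the removal of
  the first 12 intervals (plus the one lost to differencing) from the
  keypress series: 525 recorded → 512 analysed on both sides.
- **Motor correction.** C-MA = MA − MO pointwise, defensible because the
  motor potential is additively present in both and the subtraction is
  exact for the simulated ground truth.
- **Collapsed localizer.** All analysed condition ERPs are averaged with
  equal weight, pooled over the component's electrode set (pool first, then
  find the peak — the authors' ordering is unstated; pool-first is the
  documented choice), and the extremum (minimum for N1, maximum for P2)
  inside the search range centres a 30-ms window. Search ranges are not
  fixed by the study design; the defaults, N1 [50, 150] ms and P2
  [120, 220] ms, are artifact parameters. Ties break to the earliest
  latency on the sampled grid; a boundary extremum warns about truncation.
- **Measurement.** Mean amplitude = average over pooled electrodes, then
  over samples in the half-open window on the sampling grid (order
  irrelevant on a fixed grid); stable under refinement of the sampling rate
  for smooth inputs (tested at 512 vs 1024 Hz).

## The simulated epochs

Components are Gaussian bumps in time (peak latency, FWHM width, signed
amplitude, per-channel topography), summed and superposed on independent
per-channel 1/f noise. Windowed means are shape-insensitive near the window
centre, which is exactly what mean-amplitude measurement assumes; for the
default widths the 30-ms windowed mean sits within 5% of the peak
amplitude. Defaults: N1 −3 μV at 90 ms (FWHM 60 ms, fronto-central), P2
+4 μV at 160 ms (FWHM 80 ms, centro-parietal), and a +2 μV slow motor
potential at −80 ms present only when a keypress is made (MA, MO) — so the
MA − MO subtraction is meaningfully exercised. Condition effects are
additive amplitude offsets per component × production × SOA; the pipeline
default injects −1 μV on the MA N1 and P2 at the two longer SOAs, mirroring
the SOA-graded attenuation pattern at the conventional 1 μV effect
magnitude. Noise is pink (spectral exponent 1) at 2.5 μV RMS, a plausible
scale for filtered, baselined scalp EEG at ERP level.

What the simulation does *not* emulate: ocular and muscle artifacts,
latency jitter of components across trials, inter-trial overlap from short
SOAs, electrode drift, or any feedback between keypress timing and the EEG.
Passing tests therefore validate the *arithmetic* of the chain and its
statistical calibration, not its robustness to real-world artifact
structure.

## The statistical layer

- **Within-subject ANOVA.** `rm_anova_2x3()` computes the classical
  univariate decomposition for the balanced 2 × 3 design, each effect
  tested against its own subject-by-effect stratum; it is verified against
  `stats::aov()` error strata to 1e-8 and collapses exactly to the squared
  paired t for 2-level factors. Mauchly's W (verified against
  `stats::mauchly.test()`) and the Greenhouse–Geisser ε (from the
  orthonormal-contrast covariance, bounded to [1/(k−1), 1]) are computed
  for every within factor with more than two levels; both uncorrected and
  corrected p are always reported, and the headline p applies the
  correction only when Mauchly's test is significant at 0.05. When an
  effect has literally zero contrast variance (a degenerate but legal
  input), sphericity is vacuous and ε = 1 is reported.
- **Contrasts.** Paired t with Cohen's d = mean difference / SD of
  differences (so d = t/√n, consistent with how paired designs are
  conventionally reported); Benjamini–Hochberg adjustment within each
  contrast family via `stats::p.adjust`. BH is monotone and
  order-preserving but *not* idempotent — re-adjusting adjusted values can
  inflate sub-maximal ties — so the suite asserts the properties that
  actually hold.
- **Mixed models.** `fit_random_intercept_lmm()` wraps `lme4::lmer` with
  `REML = FALSE`: the Bayes-factor approximation compares BICs across
  models with different fixed effects, and only ML BICs are comparable
  that way. Fixed-effect inference is Wald (normal approximation);
  Satterthwaite degrees of freedom are not implemented, and at the design
  scale of 63 observations / 21 groups the difference is small but makes
  the intervals mildly anticonservative — the recovery suite measures
  ≈ 93% empirical coverage for nominal 95% intervals. A singular fit
  (intercept variance estimated at zero) is returned with a boundary flag,
  not an error, and then equals OLS exactly. ICC =
  var(intercept) / (var(intercept) + var(residual)).
- **Bayes factor.** `BF10 = exp((BIC_without − BIC_with)/2)` for the α
  term, from the two ML BICs.

## Pipeline scale and determinism

`run_full()` composes all stages on synthetic data. Reduced-scale defaults
keep a full run near ten seconds on a laptop-class core: 8 participants, 64
epochs per cell, 100 shuffles, with 512 analysed intervals per block
(paradigm-faithful, since the DFA ladder depends on series length);
`run_config(paper_scale = TRUE)` restores 21 participants, 525 epochs per
cell and 500 shuffles. The test suite's problem sizes follow the same
logic: DFA recovery at 100 seeds per Hurst value, surrogate calibration at
200 datasets × 100 shuffles, LMM coverage at 500 replicates of the 63-obs
design. Every stochastic stage derives its stream from the master seed via
a fixed integer map, and the generator restores the caller's RNG state, so
an identical configuration reproduces every reported number bit-for-bit on
one platform.

Generator condition targets are fixed once, to the observed scale of the
paradigm: per-SOA mean intervals near the instructed rate with SD growing
with SOA (MA 0.85/1.71/3.18 s, MO 0.75/1.45/3.06 s), α targets rising with
SOA (cell means 0.68/0.75/0.82) and 0.04 higher with sound feedback than
without, and between-participant exponent jitter of SD 0.05 (clamped to the
generator's supported range) — a value chosen to sit slightly below the
observed between-participant spread, since part of that spread is
estimation noise that the DFA step adds back.

## Known limitations

- Epoch containers are serialised as plain text (wide CSV + JSON sidecar),
  not a binary array format; this is auditable but not compact, and reading
  large recordings through it is slow by design.
- No multifractal DFA, no unbiased-DFA variant, no higher-order detrending;
  no phase-randomisation or AAFT surrogates (plain shuffling only); no
  Huynh–Feldt correction or multivariate sphericity alternative; no
  Bayesian estimation beyond the BIC approximation.
- The command-line surface is a single acceptance script; the package API
  (`run_config()` / `run_full()` and the per-stage functions) is the
  intended interface for composing analyses.
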