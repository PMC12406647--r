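# fracatten

Linking implicit action-timing control to auditory sensory attenuation.

In the self-stimulation paradigm, participants press a key once every 0.8,
1.6 or 3.2 s (the stimulus onset asynchrony, SOA); in the motor-auditory (MA)
condition each press triggers a tone 100 ms later, in the motor-only (MO)
condition it does not, and in a passive condition (AV) the same tone sequence
is replayed without movement. Two quantities are extracted per participant
and condition:

- **The DFA α exponent** of the inter-keypress-interval (IKI) series.
  Detrended fluctuation analysis regresses `log F(n)` on `log n`, where
  `F(n)` is the RMS residual of the linearly detrended, integrated series in
  non-overlapping windows of `n` samples; the slope α indexes long-range
  autocorrelation (α < 0.5 anti-persistent, 0.5–1 persistent, > 1.2 treated
  as nonstationary). Persistence in timing behaviour is read as the
  signature of implicit action-timing control.
- **N1 and P2 mean amplitudes** of the auditory ERP, measured as average
  voltage in 30-ms windows centred by a collapsed localizer, over Fz/FCz/Cz
  (N1) and FCz/Cz/CPz (P2), after band-pass + notch filtering, epoching
  (−200 to 400 ms), baseline correction, 200 μV peak-to-peak rejection and
  motor correction (C-MA = MA − MO).

The statistical layer ties them together: 2 × 3 within-subject ANOVAs with
Mauchly's test and Greenhouse–Geisser correction, a shuffle-surrogate control
establishing that α effects are sequence-order effects (shuffling each series
preserves its mean and SD exactly but destroys order), Benjamini–Hochberg
adjusted paired contrasts, and random-intercept mixed models
`C-MA ~ 1 + α-MA + AV + IKI-MA + (1 | participant)` with a BIC-approximated
Bayes factor `BF10 = exp(ΔBIC / 2)` for the α term.

A synthetic-data module generates both inputs with known ground truth:
IKI series as exactly standardised fractional Gaussian noise (circulant
embedding, so the DFA exponent equals the Hurst parameter in expectation) and
multichannel epochs with Gaussian-bump N1/P2/motor components over 1/f noise.

## Worked example

```r
library(fracatten)

# one block: 512 intervals around 0.85 s with target exponent 0.77
s <- simulate_iki_series(0.77, mean_iki = 0.85, sd_iki = 0.16, n = 512,
                         seed = 1, production = "MA", soa = 0.8)
s
#> <iki_series> participant P01, MA, SOA 0.8 s: 512 intervals (mean 0.850 s, SD 0.160 s)

dfa(s)
#> <dfa_result> alpha = 0.781 (persistent), R^2 = 0.9942, 13 window sizes [4..42], N = 512
```

The estimated exponent (0.781) recovers the generating target (0.77) within
single-draw sampling error, and the series is classified persistent: long
intervals tend to follow long intervals, as expected when timing is actively
controlled. The 13 window sizes run from 4 to 42 samples (at most 10% of the
series length).

A full reduced-scale run (8 participants, 64 epochs per cell, 100 shuffles):

```r
report <- run_full(run_config(seed = 1))
report
#> <pipeline_report> schema 1.0: 8 participants, 100 shuffles, 64 epochs/cell
#>   alpha ANOVA: production F = 0.03 (p = 0.8771), soa F = 27.90 (p = 0.0000)
#>   surrogate equivalent p: production 0.930, soa 0.000
#>   windows: N1 72.1-102.1 ms, P2 147.3-177.3 ms
#>   BF10 (alpha term): N1 0.237, P2 0.208
```

The generator's α targets rise with SOA, and the ANOVA on estimated
exponents detects that SOA effect (F = 27.9); the surrogate control confirms
it is carried by sequence order (equivalent p ≈ 0 for SOA: no shuffled
dataset produced as large an F). The small production effect (0.04 in the
generator) is not detectable at 8 participants. The collapsed localizer
placed the N1 and P2 windows around the simulated 90-ms and 160-ms peaks.

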