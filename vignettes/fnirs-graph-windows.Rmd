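---
title: "Graph metrics of DLPFC resting-state fNIRS across cumulative time windows"
author: "fnirsgraph authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph metrics of DLPFC resting-state fNIRS across cumulative time windows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

Resting-state functional near-infrared spectroscopy (rs-fNIRS) over the
dorsolateral prefrontal cortex (DLPFC) yields, for each subject, an
18-channel hemodynamic recording from which a functional-connectivity (FC)
network can be built. Two graph statistics summarize that network: the
**average degree** (AD), the mean Fisher-z connectivity over all distinct
channel pairs — a weighted network-density measure — and the **global
efficiency** (Eglob) of the binarized graph, the mean inverse shortest-path
length, swept over binarization thresholds 0.1–0.5. Both have been related
(negatively) to fluid-intelligence scores measured with Raven's Advanced
Progressive Matrices (RAPM, set II, 0–36). Because scan length affects the
reliability of connectivity estimates, the analysis is repeated over eleven
cumulative windows, [0, k] minutes for
k ∈ {1, 2, 3, 5, 8, 10, 12, 15, 20, 25, 30}, asking (i) when the metrics
stabilize, (ii) how consistent each window is with the full 30-min
recording, and (iii) how the brain–behavior association evolves with window
length.

`fnirsgraph` implements this pipeline end to end, together with a
synthetic-cohort generator that plants a known connectivity–behavior
coupling so that every stage — and the whole design — is testable without
access to human recordings.

## Pipeline and model

### Preprocessing

The stage order is fixed and logged:

1. **Saturation repair.** Saturated samples arrive as `NA` and are filled
   by natural cubic splines over neighboring valid samples (nearest-value
   extension at recording edges). Interpolated intensity is floored at
   half the channel's minimum valid value: detected light cannot be
   non-positive, and spline overshoot next to steep transients must not
   make it so.
2. **Optical density.** ΔOD(t) = −log(I(t)/mean I) per channel-wavelength.
3. **Motion detection** (on OD, per channel, both wavelengths OR-ed): a
   sample is flagged when the excursion within any sliding window of
   `tMotion` = 0.5 s exceeds `STDEVthresh` = 15 times the SD of the
   channel's first differences, or `AMPthresh` = 0.5 OD in amplitude;
   flagged samples are dilated ±`tMask` = 5 s.
4. **Motion correction**, two stages. First, inside masked segments the
   artifact is reconstructed in the temporal-derivative domain: first
   differences beyond 6 robust SDs are grouped into events; events with
   near-zero net (spikes) have their artifact integrated back to baseline,
   events with substantial net (baseline shifts) keep their jump, and the
   cumulative artifact is subtracted. This removes steps exactly, keeps
   the series continuous by construction, and — unlike subtracting a
   smoothing-spline fit inside the (tMask-dilated, hence long) mask —
   leaves the slow in-band signal untouched. Second, the whole series is
   decomposed with a periodized orthogonal Daubechies-5 wavelet
   (4 levels) and detail coefficients beyond 1.5 interquartile ranges
   from the quartiles are zeroed; this suppresses residual spike wings.
   The transform reconstructs to machine precision, so with an empty mask
   and no outlying coefficients the stage is an identity.
5. **Band-pass 0.01–0.08 Hz** (zero-phase): cascaded forward–backward
   Butterworth sections, high-pass order 3 at 0.01 Hz and low-pass order 5
   at 0.08 Hz, with reflection padding sized for the low edge. The
   steeper low-pass is deliberate: Mayer waves sit at ~0.1 Hz, just above
   the band edge, and a 3rd-order section leaks ~23% of their amplitude
   where the 5th-order section leaks ~14%. Measured response: 99.5% at
   0.04 Hz, within 1 dB across 0.02–0.06 Hz, 2.2% at 0.3 Hz, 0.6% at
   1.1 Hz.
6. **Modified Beer–Lambert inversion.** Per sample the 2×2 system
   ΔOD_λ = d · DPF_λ · Σ_c ε_{c,λ} ΔC_c is solved for ΔHbO and ΔHbR
   (ΔHbT = ΔHbO + ΔHbR), with a fixed extinction table at 760/850 nm,
   source–detector distance d = 3 cm and DPF = 6 at both wavelengths.
   Neither constant is reported by typical acquisition setups with
   certainty; both scale concentrations linearly and cancel exactly in
   correlation-based FC, which the tests assert. Filtering before or
   after this inversion commutes (both are linear); the default filters
   the OD, and an equivalence test covers the alternative order.

Channel quality is judged on raw intensity: CV = 100·SD/mean per
channel-wavelength, exclusion above 15%, with zero-mean or fully missing
channels excluded with a reason.

### Connectivity and graph metrics

HbO (the most SNR-favorable chromophore) is correlated across all channel
pairs within each cumulative window, giving a symmetric 18×18 Pearson
matrix with unit diagonal; the Fisher transform z = atanh(r) is applied
off-diagonal (|r| ≥ 1 is clipped at 1 − 1e−7 with a warning). The diagonal
is excluded — not zeroed — everywhere downstream.

AD is the mean off-diagonal z (equivalently the mean node strength).
Binarization places an edge where r ≥ τ, τ ∈ {0.1, …, 0.5}; negative
correlations simply yield no edge (|r| thresholding is available behind a
flag). Eglob is computed by breadth-first search with the convention
1/d = 0 for unreachable pairs, so the empty graph scores 0 and the
complete graph 1. Whether the study thresholded r or z, and whether AD
used r or z, is not documented; the defaults (threshold on r, AD on z) are
config switches, and the outputs record which was used.

### Stability and association statistics

Per metric (AD, and Eglob per threshold): the cohort mean trajectory
across windows; the partial correlation (controlling age and sex,
female = 0/male = 1 — the statistic is invariant to affine recoding, which
a test asserts) between each window's value and the 30-min value; and the
brain–behavior table of partial correlations between each metric cell and
the RAPM score — 11 AD cells plus 55 Eglob cells. Partial correlation is
implemented by residualizing both variables on [1, covariates] and
correlating the residuals; p-values are two-sided from
t = r√((n−k−2)/(1−r²)) on n−k−2 degrees of freedom. An independent
precision-matrix formulation serves as a test oracle. No multiple-testing
correction is applied; all 66 raw p-values are reported. A metric that is
constant across the cohort (e.g. Eglob pinned at 1 below the lowest
informative threshold) has no defined correlation and is reported as an
`NA` row rather than dropped or faked.

## The synthetic cohort

`cohort_spec()` fixes the emulated study conditions: 116 subjects, 30-min
scans (sampling rate carried per file; synthetic default 10 Hz), behavior
scores rounded and clipped to 0–36 from a Gaussian with mean 25.24 and
SD 4.00, ages ~N(20.05, 2.01²) clipped at 18, P(female) = 88/152, and a
planted correlation of −0.33 between behavior and each subject's
connectivity *density*.

Per subject the generator draws a density level u ~ U(0.5, 0.9), then an
18×18 correlation matrix whose pairwise couplings scatter around u with
SD 0.15 (projected to the nearest PSD correlation matrix). The realized
density — the mean off-diagonal correlation — is exactly the quantity AD
estimates, so parameter-recovery tests have a sharp target. The pair-level
spread matters: exactly uniform coupling at these density levels would
make every low-threshold graph complete and Eglob degenerate across the
cohort.

The time series stack, per channel:

* a **neural component**: correlated Gaussian noise colored by the planted
  covariance and band-limited to the analysis band, SD 0.3 µM HbO, with
  HbR = −0.4·HbO plus independent slow noise (activation-like inverse
  coupling);
* **physiological oscillations**: cardiac 1.1 Hz (3× neural SD),
  respiratory 0.3 Hz (1.5×), Mayer 0.1 Hz (1×), phase-jittered per
  channel, and co-oscillating in HbO and HbR with ratio +0.3 — pulsatile
  components are blood-volume driven, so both chromophores rise together.
  (An earlier draft reused the neural −0.4 ratio here; that made the HbO
  and HbR contributions cancel almost exactly at 760 nm — ε₇₆₀ is
  1486.6/3843.7 for HbO/HbR — leaving one wavelength noise-dominated and
  physically wrong.);
* the **forward Beer–Lambert map** to dual-wavelength OD with the same
  constants the pipeline inverts, making the pair round-trip testable;
* **linear drift** (±0.02 OD over the scan) and white measurement noise
  (0.005 OD) in the OD domain, then intensity I = I₀·exp(−OD);
* **motion events** at 0.5/min (70% spikes of 20× channel-OD-SD,
  duration < 1 s; 30% baseline shifts of 0.6 OD — an optode-displacement
  coupling change is multiplicative in intensity, so its OD magnitude is
  a property of the displacement, not of the signal scale) and
  **saturation dropouts** (~1 NA segment per scan, mean 2 s). The exact
  injected masks are returned for detector-sensitivity tests.

All randomness flows from one master seed through per-subject substreams
under a pinned generator (Mersenne-Twister/Inversion/Rejection), so a
fixed seed fixes every output bit.

### The cohort-level simulator

Monte-Carlo studies of the full design (hundreds of 116-subject cohorts,
11 windows) cannot afford to synthesize and preprocess ~10⁵ half-hour
recordings. A 0.01–0.08 Hz band-limited process carries about
2·bandwidth ≈ 8.4 independent samples per minute, so
`simulate_metric_cohort()` draws i.i.d. Gaussian vectors from each
subject's planted covariance at that effective rate and accumulates their
scatter over window segments — cumulative windows share data exactly as
real anchored windows do — then feeds the per-window sample correlation
matrices through the package's real Fisher/graph/statistics code. The
full time-series generator remains the vehicle for everything upstream of
connectivity (Beer–Lambert round trips, filter measurements, motion
injection/detection/correction, end-to-end determinism).

### What the generator does not emulate

* **Nonstationarity.** Real cohorts drift over 30 minutes (settling,
  drowsiness). On strictly stationary synthetic data the cohort-mean FC
  *decreases* slightly with window length, because low-frequency leakage
  inflates short-window correlation estimates (at ~8 effective samples a
  shared slow fluctuation looks like a trend correlation); reported
  rising mean-FC trends on real data are therefore not a pattern the
  generator reproduces, and passing tests say nothing about it. The
  stability properties that *are* asserted — trajectories stabilizing,
  window-vs-30-min consistency rising monotonically to exactly 1 — hold
  on stationary data and are tested over seeds.
* **Scalp physiology.** No short-channel or superficial-layer model, and
  hence no systemic confound correlated across channels beyond the
  sinusoidal components; the study itself had no short channels.
* **Sub-threshold baseline drifts.** Coupling changes smaller than
  `AMPthresh` are indistinguishable from neural drift for any
  detector of this family and are not injected.

## Numerical choices

* Filter: Butterworth cascade as above; padding = 3/low-edge seconds.
* Wavelet: Daubechies-5, 4 levels, periodized with reflection padding to
  a multiple of 2⁴; perfect reconstruction < 1e−10 is a test. Deeper
  decompositions reach into the analysis band and measurably distort the
  neural signal (recovery correlation drops from ~0.97 to ~0.76 at
  8 levels), so the despike deliberately stays above the band.
* Derivative-domain artifact threshold: 6 robust SDs (MAD) of the
  unmasked first differences; spike/step classification at |net| < 0.3 ×
  Σ|increments|.
* Degenerate inputs: zero-variance channels abort FC with the channel
  named; rank-deficient covariates, n ≤ k+2, and constant residuals are
  explicit errors in `partial_correlation()`; the association and
  consistency tables convert only the constant-metric case to NA rows.
* Window/threshold lists are validated against the canonical design with
  a 1e−9 tolerance (floating-point `seq()` artifacts).

## Problem sizes used in tests

Unit and acceptance tests run the full time-series pipeline on 2–12
subject cohorts of 2–30 minutes at 5–10 Hz, and the cohort-level
simulator at the study's full size (n = 116; 500 null cohorts for test
calibration, 200 cohorts for parameter recovery, 20 for the consistency
trend). These sizes were chosen so the whole suite certifies study-scale
statistical behavior while the expensive physics (filtering,
wavelets, Beer–Lambert) is exercised at realistic sampling rates on
smaller cohorts.

## Known limitations

* The on-disk scan format is the package's documented plain-text dialect
  (header + CSV matrix), not HDF5-backed SNIRF; it carries the same
  minimal payload (probe, sampling rate, raw intensity, NaN markers) and
  round-trips bit-exactly.
* HbR/HbT are computed and carried but not analyzed downstream, matching
  the HbO-only analysis scope.
* Eglob at low thresholds saturates at 1 for densely connected cohorts;
  the association table reports such cells as NA. Interpreting the
  threshold sweep requires checking which cells were informative.
* Partial correlations are associations; nothing here supports causal
  claims about connectivity and fluid intelligence.
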