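---
title: "Detecting myocardial ischemia from minute-long ECG spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting myocardial ischemia from minute-long ECG spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Myocardial ischemia — insufficient blood supply to the heart muscle — shows
on the ECG as a deviation of the ST segment relative to the PR segment,
which acts as the voltage reference level. Rather than detecting these
segments beat by beat (which requires fragile morphological delineation),
this package observes their *spectral* footprint over whole minutes of
signal: ST-segment changes concentrate around 11–14 Hz and PR-segment
changes around 5–8.5 Hz. Each one-minute slot of each lead is decomposed
with the discrete Choi-Williams distribution (CWD), a Cohen's-class
bilinear time-frequency distribution

$$\mathrm{CWD}(n,\omega) \;=\; 2\sum_k e^{-i2\omega k}\sum_m
  g_\sigma(m-n;k)\, x(m+k)\,x^*(m-k),
  \qquad g_\sigma(m;k)\propto e^{-\sigma m^2/4k^2},$$

whose exponential kernel suppresses the oscillatory cross-terms that plain
Wigner–Ville analysis places between genuine components. The matrix is
truncated to its positive part (the negative part of a Cohen's-class
matrix carries cross-term residue, not signal energy), and two numbers are
read off per minute per lead: the mean positive power in 11–14 Hz
(`p_st`) and in 5–8.5 Hz (`p_pr`), each expressed as a percentage of the
0–35 Hz total. These `(p_st, p_pr)` pairs feed a per-lead one-vs-one
multi-class SVM with a Gaussian kernel (three classes: normal, ischemia,
infarction); per-lead decisions are fused by majority vote across leads.

The classification unit is the minute, not the beat: a minute aggregates
60–100 beats, which is what makes the band-power statistics stable and the
scheme independent of QRS detection.

## The processing chain and its parameters

1. **Resampling** to a common 250 Hz (`target_fs`), by rational polyphase
   resampling. All downstream settings assume this rate.
2. **Baseline removal**: linear-phase FIR high-pass, cutoff 0.5 Hz, order
   1500. The long filter is needed to put 30 dB of attenuation at 0.1 Hz
   while staying within 1 dB at 10 Hz. The impulse response is adjusted to
   an exact DC null.
3. **Muscle/mains suppression**: linear-phase FIR band-pass, 2–35 Hz,
   order 400. The source description of this filter ("bandwidth of 2 Hz
   and 35 Hz centre frequency") is ambiguous; a literal 2 Hz-wide filter
   centred at 35 Hz would destroy the 5–14 Hz feature bands, so the 2–35 Hz
   passband reading is implemented (configurable via `passband`). Both
   filters are applied with their group delay compensated, so filtering
   introduces no time shift (verified by cross-correlation in the tests).
4. **Scaling**: per-lead z-score over the whole record, removing
   inter-device gain so heterogeneous sources are comparable. Combined with
   the percentage normalisation of the features, the whole chain is exactly
   invariant to any positive input gain.
5. **Segmentation**: consecutive non-overlapping 60 s windows; a trailing
   remainder is dropped (the band means are length-sensitive, so partial
   windows are not padded).
6. **CWD**: `sigma = 1` (no canonical value exists for this application;
   1 is the common general-purpose compromise between resolution and
   cross-term suppression, and the cross-term tests exercise
   `sigma` from 10 down to 0.01), lag window 127 samples with a Hamming
   taper, 256 frequency bins on `[0, fs/2)` (0.49 Hz spacing, comfortably
   resolving the 5–8.5 and 11–14 Hz bands), time decimation 4 (one slice
   per 16 ms; the features are time means, so they are insensitive to this
   stride for quasi-stationary minutes).
7. **SVM**: RBF width `sigma_rbf = 0.1` with features mapped from
   percentages to `[0, 1]`, so the width is meaningful on the feature
   scale; soft-margin cost 10 (no value is canonical; 10 keeps the box
   constraint loose enough for clean synthetic data while bounding dual
   coefficients). Dual solutions come from libsvm; the package owns the
   decision function, pairwise voting with margin tie-breaks, and lead
   fusion.

## Numerical conventions of the discrete CWD

Several choices pin down the discrete distribution; they are shared by the
fast FFT implementation (`cwd()`) and the literal nested-loop reference
(`cwd_reference()`), which agree to machine precision on every battery
signal:

* **Analytic signal first.** Real inputs would interfere with their own
  negative-frequency image; the frequency-domain Hilbert construction
  removes that, and makes the integer-lag frequency sampling on
  `[0, fs/2)` alias-free.
* **Frequency axis.** The integer-lag discrete form samples frequency with
  period `fs/2`, so the axis holds `n_freq` uniform bins from 0 up to one
  bin-width below `fs/2` (an inclusive endpoint would duplicate the 0 Hz
  bin).
* **Zero-lag window.** The Gaussian kernel degenerates at `k = 0`; its
  limit, a Kronecker delta, is used. A consequence worth knowing: the time
  marginal is then *exactly* instantaneous power at every sample.
* **Window truncation.** The lag-`k` Gaussian is cut at
  `±ceil(4|k|/sqrt(sigma))` samples (below 3e-7 of its peak) and
  renormalised to unit sum; samples beyond the record are treated as zero,
  so the first/last `lag_window` samples carry shrinking-window bias
  (`edge_samples`), and marginal tests use the central half.
* **Normalisation.** The overall `2/fs` scale is fixed by requiring the
  Riemann-sum marginals to reproduce instantaneous power, the energy
  spectrum shape, and total analytic-signal energy. Marginals are only
  meaningful *before* positive-part truncation, and the accessors enforce
  that contract.

## Feature normalisation

The band features are defined as a *power share*: the truncated CWD total
inside the band divided by the 0–35 Hz total, times 100. A per-bin mean
ratio was considered and rejected because it can exceed 100 % for narrowband
signals, breaking the natural invariants `0 ≤ p ≤ 100` and
`p_st + p_pr ≤ 100`; the two readings differ only by the fixed ratio of bin
counts, so group separations (standardised mean differences) are identical
under either. Normalisation is per segment, making every minute
self-contained.

## What the synthetic generator does and does not emulate

The generator exists so that every stage is exercisable end to end without
clinical recordings. Beats are sums of five Gaussians (P, Q, R, S, T) with
explicit piecewise-constant ST and PR pedestals — chosen over a dynamical
ODE heart model precisely because the pedestals give direct, auditable
control over the quantities the features measure. Conditions map to
presets: ST elevation +0.15 mV, ST depression −0.15 mV, infarction
+0.30 mV with T-wave inversion — magnitudes in the clinically meaningful
0.1–0.3 mV range, chosen once as generator conventions. RR intervals jitter
by a truncated Gaussian (sd 3 % of the mean, capped at ±10 %), keeping
per-minute beat counts stable; leads differ by random gains in 0.7–1.3.
Noise adds the three artifact classes the conditioning stage targets:
0.25 Hz baseline wander (default 0.10 mV), 50 Hz mains (0.02 mV), and
20–100 Hz band-limited Gaussian muscle noise (0.03 mV).

What this deliberately does **not** contain: genuine inter-patient
morphology variability, arrhythmia, electrode motion transients,
non-stationary drift of the ST level within a record, or physiologically
coupled 12-lead projections. Consequently, a high held-out accuracy on
synthetic corpora demonstrates that the chain *recovers the class structure
it is pointed at* — pedestal shifts of ±0.15 mV and larger under realistic
stationary noise — not that it attains any particular accuracy on clinical
databases.

## Evaluation design

Splits and cross-validation are stratified **by record**, never by
segment: minutes of one record are highly correlated, and letting them
straddle a train/test boundary would leak. The test corpus is 3 classes ×
10 records × 6 minutes × 2 leads at 250 Hz (the held-out split leaves 2
records per class out; 10-fold cross-validation is run record-wise on the
same corpus). Sensitivity and specificity are reported in the binary
screening sense, pooling ischemia and infarction as "positive".

The label-permutation control deserves a note: with training labels
shuffled, held-out accuracy per *single* permutation is cluster-quantised
(all minutes of a test record move together), so the control is asserted on
the mean over 15 permutations against chance (1/3), with an interval
derived from the permutation spread itself rather than a per-minute
binomial formula.

## Known limitations

* The 16-bit WFDB writer clips above ±16.38 mV at its fixed gain of 2000
  adu/mV (ample for ECG, not for arbitrary signals).
* `cwd()` memory grows with `n_freq × n_samples/time_decimation`; minute
  segments at the defaults are ~4 MB, but decimation 1 on long records is
  costly.
* The detector is intentionally blind to rhythm disorders: a record that is
  arrhythmic but isoelectric in ST/PR will read as normal.
* Condition presets are conventions of this package's generator; clinical
  deployment would require training on real labelled data through the same
  interface (`read_record()` accepts WFDB and CSV).
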