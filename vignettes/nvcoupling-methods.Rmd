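---
title: "Estimating global neurovascular coupling from resting-state EEG-fNIRS"
author: "nvcoupling"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Estimating global neurovascular coupling from resting-state EEG-fNIRS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nvcoupling)
```

## The measurement problem

Neural activity and the hemodynamic response it triggers are measured by
two different instruments: high-density EEG captures band-limited voltage
fluctuations at 250 Hz, while continuous-wave fNIRS captures slow
(≲ 0.4 Hz) changes in oxy- and deoxy-hemoglobin concentration at 10.42 Hz
through dual-wavelength (690/830 nm) attenuation. Neurovascular coupling
(NC) is the *statistical* link between the two: how strongly the slow
envelope of band-limited electrical activity, delayed and smeared by the
hemodynamic response function, predicts the hemoglobin signal. This package
quantifies that link as six standardized regression weights per subject —
three EEG bands (theta 3.5–8.2 Hz, alpha 7.4–13 Hz, beta 13–30 Hz; the
theta/alpha overlap is kept exactly as defined) crossed with two hemoglobin
species — and feeds them into group statistics and a cross-validated
classifier.

## Per-subject model

**EEG chain.** Raw voltages are band-passed 1–80 Hz and notch-filtered at
50 Hz with zero-phase (forward–backward) 2nd-order Butterworth filters.
Stereotyped artifacts can be removed by a seeded symmetric FastICA
(`remove_artifacts_ica()`): components are flagged automatically when their
excess kurtosis magnitude exceeds 5 (spiky, non-neural sources) or when
they correlate above 0.7 with a frontal 1–4 Hz reference (ocular activity);
both thresholds are arguments. Per band, the power envelope is the
magnitude of the analytic signal of the band-passed data. Channel
envelopes are z-scored and reduced by a temporal PCA; the first principal
component — a variance-weighted global envelope that is robust to
channel-wise noise, unlike a plain average — is retained per band, with its
sign fixed so the mean channel loading is positive (β signs are then
comparable across subjects).

**fNIRS chain.** Intensities become optical densities
`OD(t) = −ln I(t)/I_m`, with `I_m` the mean over the whole (all-rest)
recording. Motion artifacts are corrected by a kurtosis-based wavelet
filter (below), the ODs are band-passed 0.01–0.4 Hz (zero-phase 4th-order
Butterworth), and hemoglobin follows from the modified Beer–Lambert law
with a per-channel interoptode distance ρ (35 mm for the 16 long channels,
15 mm for the 4 short ones) and the general age- and wavelength-dependent
differential-pathlength-factor polynomial (690 nm path lengths are longer
than 830 nm, and both grow with age — for an 73-year-old,
`dpf(690, 73) = ` `r round(dpf(690, 73), 2)` vs `dpf(830, 73) = `
`r round(dpf(830, 73), 2)`). The 2×2 extinction/DPF system is assembled
with each wavelength's own coefficients; the shipped extinction table (in
mM⁻¹ mm⁻¹) is a compiled literature table, and all quantitative claims
about the conversion are made through round-trip properties rather than
absolute concentrations.

**GLM.** Each global envelope is convolved at the EEG rate with a
canonical double-gamma HRF (response gamma shape 6, undershoot shape 16,
peak:undershoot ratio 6, 32 s support, peak-normalized; the peak sits near
5 s), block-averaged to 1 Hz, and z-scored. The four short-separation
channels of the matching chromophore — scalp-only measurements — join the
design as nuisance regressors (matching-species is standard practice), plus
an intercept. The first 30 s are discarded (convolution transient), and
the first/last 5 s of envelopes and hemoglobin are trimmed before anything
else (filter and Hilbert transients). Ordinary least squares of each
z-scored long-channel series on this design yields standardized β-weights;
a perfectly coupled noise-free channel gives β = 1 exactly. The six
subject metrics are the β's averaged over long channels. Unimodal
reference metrics are also computed: mean squared band envelope (EEG) and
the per-channel SD of HbO/HbR averaged over long channels (fNIRS).

Fixed order of operations: convolve at the native rate → block-average to
1 Hz (anti-aliasing by construction) → z-score last, which is what makes
the coefficients standardized.

## Kurtosis-based wavelet motion correction

Each OD series is decomposed to depth `round(log2(fs/0.1)) − 1` (coarsest
detail band near 0.1 Hz) with a periodized orthogonal Symlet-8 transform.
A detail level is cleaned only while its coefficient kurtosis exceeds 3.3
(Gaussian = 3); cleaning zeroes coefficients farther than 3 robust SDs
(1.4826 × MAD) from the level median and repeats. Two numerical safeguards
matter in practice and are part of the package's definition of the filter:

* the trigger adds two standard errors of the kurtosis estimator
  (`sqrt(24/n)` under Gaussianity) to the threshold, so a coarse level with
  only a few dozen coefficients is not "cleaned" on sampling noise;
* kurtosis and MAD are evaluated over the surviving coefficients only —
  zeroed coefficients would otherwise inflate the kurtosis and cascade the
  iteration into removing genuine signal.

On artifact-free near-Gaussian series the filter changes essentially
nothing (< 2% RMS); a 10-SD spike on a band-limited hemodynamic carrier is
suppressed by ~90%. On a *white* carrier the same spike loses only ~70% of
its amplitude: its coarse-level coefficients sit at 2–3 robust SDs, which
no kurtosis criterion can distinguish from noise. That boundary is a
property of the method, not of this implementation.

## The synthetic cohort generator

`simulate_subject()` inverts the analysis chain to produce raw data with
known ground truth. Three unit-variance band-limited Gaussian latents
(theta/alpha/beta) are mixed into `n_channels` EEG channels through smooth,
all-positive spatial lobes (a Gaussian bump per latent over the channel
axis plus a positive floor) imitating volume conduction, at 20 µV per
unit latent, plus sensor noise (default SD 5 µV). The latents' Hilbert
envelopes, resampled to the fNIRS rate, HRF-convolved, band-limited to
0.03–0.2 Hz (safely inside the 0.01–0.4 Hz analysis band, which is what
makes exact forward/inverse checks meaningful) and scaled to unit variance,
drive the long channels' ΔHbO/ΔHbR with the signed couplings of the
`coupling_spec` (in µM per unit drive). A systemic scalp signal — a
0.08–0.12 Hz oscillation plus a 0.2–0.3 Hz respiration component, with a
fixed HbO:HbR amplitude ratio of 1:0.4 — enters the short channels at unit
gain and the long channels at `scalp_gain_long` (default 0.3). Hemoglobin
is pushed forward through the same Beer–Lambert matrices the analysis
inverts, optional motion spikes (exponentially decaying steps of random
sign, default 1 s decay) and white noise (default SD 0.01) are added in OD
space, and intensities are `I_m · exp(−OD)` with random per-channel `I_m`.
Everything is deterministic given the seed, with per-subject seeds derived
from the cohort seed; ages are drawn from N(73, 7.5²) truncated to
[50, 95].

The reference study conditions are 17 AD-like subjects with all couplings
zero versus 18 HC-like subjects with theta→HbO and alpha→HbR at +0.4
(`default_coupling_specs()`). The HbR coupling is *positive* by default:
the generator exposes signed couplings rather than fixing a physiological
sign convention, because the direction of the alpha–HbR association is
itself a modelling question.

**What the generator does not emulate.** Within a group all subjects share
the same true couplings, so between-subject spread comes from estimation
noise alone; real cohorts add biological heterogeneity, and group
separation here is correspondingly sharper than any real-data effect.
Planted couplings also add hemodynamic variance, so the *unimodal* fNIRS
power metric separates the synthetic groups even though the emulated study
found unimodal metrics uninformative — tests of the multimodal pipeline
should not read that as a property of real data. There is no anatomical
head model, no photon-transport simulation, and EEG mixing is a smooth
positive lobe rather than a conductivity model.

## Numerical choices

* **Filtering.** All filters are designed with `signal::butter` and applied
  forward–backward with zero initial conditions (compiled inner loop).
  Band envelopes are computed spectrally: one FFT per recording, the exact
  squared Butterworth magnitude response (the zero-phase gain) times the
  analytic-signal mask per band, one inverse FFT per band. This is the
  same zero-phase filter expressed in the frequency domain and shares the
  FFT the Hilbert transform needs anyway.
* **Resampling** to the 1 Hz GLM rate is non-overlapping block averaging,
  which handles the non-integer 10.42 Hz ratio and anti-aliases by
  construction.
* **Degenerate inputs.** Zero-variance envelope channels are excluded from
  the PCA with a warning; a zero- or near-zero-variance design column
  (relative SD below 1e−8) is an error naming the column, as is a
  rank-deficient design; fits require at least `columns + 2` rows and by
  default 3× as many rows as columns.
* **Sweeps.** The recording-time sweep keeps the full-length trims (5 s
  edges, 30 s HRF transient) whenever the window affords them and shrinks
  them smoothly below ~60 s, down to untrimmed 15 s windows where the GLM
  is as over-parameterized as the record allows. At the full window and
  the full channel count the sweep reproduces the full analysis exactly —
  an identity the tests assert.
* **ROC.** The AUC is the normalized Mann–Whitney statistic with ties
  counted one half; its significance uses the closed-form null-SE at
  AUC = 0.5, `SE₀² = [1/4 + (n₁+n₂−2)/12]/(n₁n₂)`, with a one-sided normal
  p. Reported loadings are means over leave-one-out folds; their
  variability comes from refitting on bootstrap resamples (default
  10,000), redrawing resamples that lose a class or the full design rank.
* **Bands and defaults** follow the acquisition they model: 250 Hz EEG,
  10.42 Hz fNIRS, 0.01–0.4 Hz hemodynamic band, 35/15 mm geometry, 1 Hz
  GLM rate, 15 s and 4-channel sweep steps. `nc_config()` validates the
  whole set before any computation.

## Validation scale

The test-suite recovery study runs the complete pipeline on 20 replicate
cohorts of 35 subjects at 16 EEG channels × 120 s — the package's chosen
validation scale, which keeps a full replicate under half a minute while
leaving the two planted couplings' p-values around 1e−20 against > 0.1 for
the four null couplings, and the cross-validated AUC at 1.0. The
acceptance script repeats a 10-replicate version of the same study.
Recovery saturates: because β's are standardized, the estimate is
`b/√(b² + σ²)` for true coupling `b` and residual SD σ, so estimated
couplings grow monotonically but sublinearly with the truth — the
monotonicity and regression-slope tests account for this.

## Known limitations

LOO-CV regression scores are pessimistically biased under the null (each
held-out label pulls the training fit away from itself), so permuted-label
AUCs average slightly below 0.5 (~0.43 at n = 35 with six features); null
calibration of the *final* AUC should therefore use permutation, not the
normal z, when effects are marginal. The ICA stage is fully automatic and
seeded, which trades operator insight for reproducibility; its two flagging
criteria are exposed for tuning. The interchange format is plain CSV/JSON
bundles; device formats (EDF, SNIRF) are out of scope for I/O. No
multiple-comparison correction is applied to the six univariate tests —
the multivariate analysis is the intended guard against false positives —
and the package deliberately offers no regularized or nonlinear
classifiers: with six features and 35 subjects, the closed-form linear
regressor's small effective degrees of freedom are the overfitting control.
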