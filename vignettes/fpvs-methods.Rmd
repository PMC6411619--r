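---
title: "Frequency-tagged EEG analysis for FPVS oddball paradigms: models and methods"
author: "fpvs package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-tagged EEG analysis for FPVS oddball paradigms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpvs)
```

## The paradigm and the signal model

In fast periodic visual stimulation (FPVS), images are presented by
sinusoidal contrast modulation at a fixed base rate (6 Hz here), and a
category or identity of interest appears as every fifth stimulus, i.e. at
an oddball rate of 1.2 Hz (= 6/5 Hz). Because presentation is strictly
periodic, the brain's responses are confined to known frequencies: a
general visual response at 6 Hz and its harmonics (12, 18 Hz), and a
discrimination response at 1.2 Hz and its harmonics (2.4, 3.6, 4.8,
7.2, 8.4 Hz, ...). Harmonics of 1.2 Hz that coincide with multiples of
6 Hz carry the base response and are therefore never counted towards the
oddball response. This frequency separation is the whole trick: the
response of interest lives in a handful of narrow FFT bins, and everything
else in those bins is noise whose level can be estimated from the
immediately surrounding bins.

The package implements the complete analysis for a two-group study
(a typically developing control group versus a patient-like group with
reduced upright face individuation), and, because no recordings from such
cohorts are distributed with it, also a synthetic cohort generator whose
ground truth is known exactly.

## The synthetic generator

`simulate_subject()` builds each recording as a sum of:

* a base-rate response: sinusoids at 6, 12, 18 Hz with geometric
  amplitude decay (`harmonic_decay`, default 0.7 per harmonic), a
  medial-occipital topography peaking at Oz/Iz, and first-harmonic
  amplitude `base_amp` (default 1 µV);
* an oddball response: sinusoids at the first `n_harmonics` multiples of
  1.2 Hz that are not multiples of 6 Hz (default six: 1.2-8.4 Hz), with
  the same decay, an occipito-temporal right-lateralized topography
  peaking at PO8, and a first-harmonic amplitude set per group and
  orientation (defaults: control upright 0.9 µV; control inverted and
  both patient-like conditions 0.6 µV — a 1.5x upright advantage for
  controls and no inversion effect in the patient-like group);
* 1/f-shaped Gaussian background noise (`noise_1f_exponent` 1.0,
  `noise_scale` 5 µV RMS per channel, independent across channels),
  synthesized by frequency-domain shaping of a Hermitian random spectrum;
* an alpha sinusoid (10 Hz, 3 µV, parieto-occipital topography, random
  phase per sequence);
* optionally, stereotyped blinks: frontal-dominant half-cosine
  transients (0.35 s, 100 µV) at Poisson times, matching the ~0.43
  events/s regime reported for child cohorts.

Between-subject variability enters through a log-normal response gain
(`subject_sd` 0.3 on the log scale) shared by all conditions of a
subject, which is what makes subjects with large upright responses also
have large inverted responses — the structure that the repeated-measures
analysis exploits. All injected harmonics have zero phase at sequence
onset; every downstream statistic uses only FFT amplitudes, so phase
conventions are immaterial. Sequences follow the canonical timing:
2 s sinusoidal fade-in, 40 s full contrast, 2 s fade-out, epoched from
2 s before to 45 s after onset (the 47 s epoch).

The defaults were calibrated once, against the qualitative outcomes the
generator is meant to emulate: with them, nearly all simulated control
subjects reach individual significance for upright sequences,
first-harmonic SNR at the occipito-temporal maximum falls in the 2-5
range, and group-level cohorts reproduce the Group x Orientation
interaction. The generator does **not** model: spatially correlated
noise (channels are independent), volume conduction or any head model
(topographies are abstract per-channel gains), eye movements beyond
blinks, non-stationarity within a sequence, or line noise. Passing tests
therefore demonstrate the correctness and calibration of the analysis
given this idealized signal structure, not robustness to every artifact
of real recordings.

## Preprocessing

`preprocess_recording()` enforces the canonical order: segmentation
(47 s epochs), band-pass, decimation, channel interpolation, common
average reference. Numerical choices:

* **Zero-phase filtering.** The 0.1-100 Hz 4th-order Butterworth is
  applied forwards and backwards (`signal::filtfilt`), so the effective
  magnitude response is the square of the one-pass design and the phase
  response is identically zero. Group delay would otherwise shift epochs
  relative to their onset markers; since all statistics are amplitude
  based, zero-phase filtering is the safe choice.
* **Decimation** (512 to 256 Hz) uses an eighth-order Chebyshev type-I
  anti-aliasing low-pass (`signal::decimate`), again zero-phase.
* **Interpolation** replaces a bad channel by the unweighted mean of its
  3 spatially nearest neighbours on an idealized unit-sphere 10-10
  montage constructed geometrically (18-degree inclination rings,
  great-circle interpolation for intermediate electrodes). At most 5% of
  channels (3 of 64) may be interpolated; distance ties are broken by
  alphabetical label order.
* **Blink handling.** Blink rate is estimated from a frontal channel by
  peak detection on a 5 Hz low-passed signal with a 0.2 s refractory
  period; `blink_screen()` flags subjects above the cohort mean + 2 SD.
  Because FPVS responses occupy narrow bins while blinks are broadband,
  no systematic blink correction is applied; an optional regression-based
  subtraction (`regress_eog()`) is available instead of ICA, which would
  add a heavy dependency to handle what is typically a single subject.

## Spectral statistics

Epochs are cropped from the end of the fade-in to 39.1992 s — 10035
samples at 256 Hz, the published analysis window. Note a subtlety we
preserve deliberately: 39.1992 s corresponds to 47.04 cycles of 1.2 Hz,
not an exact integer, so oddball harmonics sit 0.04 bins off the FFT
grid and a fraction of a percent of their energy leaks into neighbouring
bins (more for higher harmonics, ~3% amplitude at 8.4 Hz). Harmonic
frequencies are mapped to the nearest bin; `freq_to_bin()` reports the
residual offset. No taper is applied — integer-cycle cropping is the
leakage control.

Per-bin statistics use the 20-bin noise window: 12 bins on each side of
the target, minus the bin directly adjacent on each side, minus the
single highest- and single lowest-amplitude bins of the remaining 22.
Then

* SNR = amplitude / window mean,
* baseline-corrected amplitude = amplitude - window mean (µV, may be
  negative),
* z = (amplitude - window mean) / window SD.

The SD uses the population (n) denominator; this is configurable but
pinned for reproducibility (at n = 20 the difference is ~2.6%).
Degenerate inputs are handled explicitly: flat spectra give SNR 1 and
z 0; a zero noise mean (noiseless input) gives SNR `Inf` with a warning.

### A calibration caveat on the z threshold

The z > 2.33 rule is nominally p < .01 one-tailed, but two properties of
the procedure make it anticonservative under pure noise. First, FFT
amplitude noise is Rayleigh distributed (right-skewed), so the upper
tail is heavier than Gaussian. Second — quantitatively more important —
excluding the two extreme bins shrinks the noise SD estimate by roughly
12%, inflating every z. Monte-Carlo calibration (the package's
acceptance suite runs 500 null cohorts) puts the long-run
P(z > 2.33) at a signal-free bin near 5%, not 1%; even for Gaussian
noise the exclusion rule alone yields ~4%. Users should read individual
z values as a ranking device with a lenient implicit alpha, not as
calibrated p-values. The group-level inferential results (ANOVA,
permutation tests) are unaffected: their calibration is verified
separately and is nominal.

## Harmonic selection and quantification

Group-level selection walks the harmonics of 1.2 Hz upward on the grand
average spectrum (all subjects, all electrodes, groups pooled — so
selection cannot induce group bias, which a label-permutation test
verifies) and keeps them while z > 1.64 (p < .05 one-tailed). Base-rate
multiples are skipped without breaking the "consecutive" chain, matching
the published harmonic ranges (harmonics 1-14 of 1.2 Hz minus 6 and
12 Hz give 12 summed harmonics; 1-7 minus 6 Hz give 6). The base
response is selected the same way over multiples of 6 Hz.

Responses are sums of baseline-corrected amplitudes over the selected
harmonics, averaged within ROIs (medial occipital Oz/Iz/O1/O2;
left and right occipito-temporal P7/P9/PO7 and P8/P10/PO8 — electrode
labels normalized to the PO7/PO8 spelling). ROI-averaging and harmonic
summation commute; both are linear in the spectrum.

Individual significance follows the summed-window procedure: the raw
ROI-averaged spectrum is cut into 41-bin windows (±20) centred on each
selected harmonic, windows are summed element-wise across harmonics, and
the centre of the summed window is z-scored against its own 20-bin noise
window; z > 2.33 marks a significant subject. The ±20 window width and
the ±12 statistic window are independently configurable because they are
genuinely different parameters of the published procedure. For the
per-subject input we use each subject's raw condition-averaged spectrum —
the only reading that yields per-subject output.

## Group statistics

`mixed_anova()` fits the classical split-plot decomposition (between:
Group; within: Orientation and/or ROI) via `aov()` Error strata on the
enforced-balanced design, where Type I/II/III sums of squares coincide.
Partial eta squared is SS_effect / (SS_effect + SS_error-of-stratum).
For within effects with more than two levels, Mauchly's test
(`stats::mauchly.test`) and the Greenhouse-Geisser epsilon (computed
from orthonormal effect contrasts of the residual covariance, verified
against `anova.mlm`'s spherical tests) are reported; the corrected
p-value is the headline whenever Mauchly's p < .05. Two-level within
factors trivially satisfy sphericity and carry no correction. A constant
dependent variable is reported as F = 0, p = 1 rather than NaN.
Assumption checks (Shapiro-Wilk on the dependent variable, Levene across
groups on subject means) are attached to every fit.

Post-hoc pairwise contrasts use paired t-tests within groups and
pooled-variance two-sample t-tests between groups, Bonferroni-scaled by
the number of contrasts. The electrode-wise analysis fits Group x
Electrode and masks per-electrode group contrasts at alpha / n_electrodes
(0.05/64 ≈ 0.00078). The severity-score correlation uses the upright
individuation amplitude averaged over LOT + ROT by default (the
electrode set is a flag, since published analyses do not pin it), pooled
and within groups — the pooled-versus-within contrast is what
distinguishes a between-group offset from a within-group association.

## Classification

Feature vectors are the per-harmonic baseline-corrected amplitudes of
the first five oddball harmonics (1.2, 2.4, 3.6, 4.8, 7.2 Hz — the 6 Hz
bin belongs to the base response, and 8.4 Hz is the optional sixth
feature) for LOT and ROT: 10 columns, ROI-major. Three linear models are
fitted: LDA with pooled covariance (`MASS::lda`, with a
shrinkage-towards-diagonal fallback if the covariance is singular),
L2-penalized logistic regression with C = 1 in the sum-loss convention
(`glmnet`, the default parametrization of the reference scikit-learn
implementation, whose per-fold predictions all three models reproduce
exactly), and a linear-kernel SVM with C = 1 (`e1071::svm`). Features
are standardized inside each
training fold only — the held-out subject never contributes to the
scaling — and the harmonic plan itself is computed without reference to
group labels, so leave-one-out estimates are leakage-free. Significance
uses label permutations with the full LOO re-run per permutation and the
add-one estimator (1 + #{perm ≥ observed}) / (n_perm + 1), which is
super-uniform under the null by construction.

## Problem sizes and reproducibility

Everything is deterministic given the configuration: subject seeds
derive from the master seed, and identical configurations yield
bit-identical cohorts. The test and calibration suites exploit one
scaling fact: the spectral bin width depends only on the crop duration,
not the sampling rate, so simulating at 64 Hz with the full 40-s
sequences reproduces the canonical 0.0255 Hz frequency grid at a quarter
of the sample count. The package's calibration suites use 500 null
cohorts (10 per group, 8 channels, 4 sequences, simulated at 32 Hz) for
type-I calibration and 100 effect cohorts (15 per group, 16 channels,
64 Hz) for power and classifier recovery; band-pass filtering and decimation are skipped
there (they are linear, have no effect under the null, and carry their
own dedicated tests). The full 512-to-256 Hz path is exercised
end-to-end on single subjects. Stage artifacts are held in memory within
`run_pipeline()` — the permutation stage re-enters only the classifier
with the already-computed features — rather than cached on disk.

## Known limitations

* Electrode positions are idealized spherical 10-10 coordinates, not
  digitized locations; interpolation quality inherits this approximation.
* The generator's noise is spatially white across channels; real EEG
  noise is strongly correlated, which mainly affects how much the common
  average reference can help or hurt.
* The individual z statistic is anticonservative (see above); this is a
  property of the published procedure that the package reproduces
  faithfully rather than corrects.
* The split-plot ANOVA is the classical fixed-design decomposition; no
  random-slope mixed modelling is attempted.
* EDF/BDF import/export is not provided; recordings interchange through
  the package's plain-text fixture container (`write_recording()` /
  `read_recording()`).

## A worked micro-example

```{r example, eval = FALSE}
cfg <- pipeline_config(
  sim = sim_config(n_per_group = 8, sampling_rate = 64,
                   full_duration = 40,
                   channel_labels = c("Fp1", "Fp2", "Fz", "Cz", "Pz",
                                      "POz", "P7", "P9", "PO7", "O1",
                                      "Oz", "Iz", "O2", "PO8", "P10",
                                      "P8"),
                   seed = 42),
  low = NULL, resample = NULL)
res <- run_pipeline(cfg)
print(res)
summary(res)
```

The printed bundle reports the selected harmonic plan (six oddball
harmonics through 8.4 Hz at default effect sizes), the split-plot ANOVA
with the Group x Orientation interaction, and the three leave-one-out
classifier accuracies.
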