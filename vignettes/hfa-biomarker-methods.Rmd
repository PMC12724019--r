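---
title: "Interictal high-frequency activity biomarkers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interictal high-frequency activity biomarkers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

In drug-resistant focal epilepsy, resective surgery aims to remove the
epileptogenic zone, for which the clinician-defined seizure onset zone
(SOZ) is the practical proxy. Waiting for habitual seizures during
intracranial EEG (iEEG) monitoring is burdensome, so short interictal
recordings are attractive if a biomarker measured from them can localize
the SOZ. Interictal high-frequency activity (HFA) — brief events above
80 Hz that stand out from background — is such a candidate. HFA is
heterogeneous: narrow-band oscillatory bursts (HFOs), interictal spikes
with broadband high-frequency augmentation, and spike–oscillation
complexes. This package implements a pipeline that (i) detects HFA with
four established automatic detectors, (ii) quantifies per-event
morphology, (iii) trains a gradient-boosted model mapping seven
electrode-level features to an SOZ probability, and (iv) relates
resection-completeness summaries of those scores to postoperative
outcome (ILAE class 1 vs class 2 or worse), together with a synthetic
cohort generator so that every stage is testable without patient data.

## Montage and preprocessing

Subdural channels are re-referenced to the common average of the
*included* subdural channels (artifact, white-matter and out-of-brain
channels are excluded first, so they contaminate neither the reference
nor any downstream statistic). Depth shafts use a bipolar montage: pair
*k* is contact *k* minus contact *k+1* along the shaft. Detection and
feature extraction run on these montaged signals; pair-level statistics
are mapped back to contacts as the mean of the two adjacent pair values,
with shaft-end contacts inheriting their single adjacent pair's value —
the end-contact rule is our choice (only the interior two-pair case is
standard), made to avoid discarding shaft ends.

## Detectors

All four detectors first band-pass 80–500 Hz. Filtering is zero-phase so
event latencies agree across detectors; the default implementation
applies the squared magnitude response of a 128-tap FIR in the frequency
domain (the exact spectral equivalent of a forward–backward pass, and
much faster on 5–20-minute epochs). Intervals are half-open and 0-based;
detections closer than 10 ms are merged.

* **STE** (short-time energy): 3-ms moving RMS above mean + 5 SD, at
  least 6 ms long, with at least 6 rectified peaks above mean + 3 SD in
  a ±20 ms context window around the detection. The context window is
  needed because the suprathreshold RMS core of a tapered event is
  shorter than the event.
* **SLL** (short line length): 40-ms moving line length over the
  97.5th empirical percentile, at least 12 ms. A fixed-percentile
  anomaly detector flags its design fraction of any recording, so SLL is
  by far the most prolific detector; this matches its published
  behavior and we do not re-tune it.
* **HIL** (Hilbert envelope): envelope above mean + 5 SD within sliding
  10-s threshold-estimation epochs, at least 10 ms.
* **MNI** (baseline method): 125-ms candidate baseline segments with no
  transient above mean + 2 SD of the rectified signal; when at least 5 s
  of baseline exists, a gamma distribution (method of moments) is fitted
  to baseline 10-ms energies and the 99.99th-percentile gamma quantile
  is the threshold; otherwise an iterative empirical-percentile fallback
  re-estimates the threshold after removing suprathreshold samples.

Every numeric default lives in `inst/extdata/detector_defaults.yaml`.
SD-relative detectors (STE, HIL) are invariant to rescaling the signal,
and raising any detector's primary threshold cannot increase its event
count on the synthetic test signals; both properties are tested.

## Event morphology

Each event gets a multitaper time–frequency map: 200-ms windows sliding
in 1-ms steps, 5-Hz frequency bins spanning 80–500 Hz. At 1000 Hz a
200-sample window has exactly 5-Hz FFT resolution, so the bins are the
natural FFT bins starting at 80 Hz (85 bins); no zero-padding. We use 3
Slepian tapers at time–bandwidth product 2 — a modest smoothing choice
that respects the 200 ms x 5 Hz grid; taper count is configurable
(`tf_config()`). Reported features:

* duration (ms) from the detector bounds;
* maximum spectral power (uV^2) over cells inside the event, ties in
  frequency broken toward the lower bin;
* frequency of the maximum-power bin (Hz);
* normalized spectral entropy of the time-averaged spectrum
  `P(f_i)` over the `N = 85` bins:

  `H = -sum_i P(f_i) log2(P(f_i) + eps)`, `H_norm = H / log2(N)`,

  with `eps = 1e-12` guarding the zero logarithm. `H_norm` is 0 for a
  one-bin spectrum and 1 for a flat one; narrow-band oscillations score
  low (~0.5 on pure synthetic bursts) and broadband spikes high (~0.9).
  Using the time-averaged spectrum rather than the peak-time slice is a
  robustness choice and is configurable.

Per electrode, the model row is the event rate (events/min) plus the
median of each morphology feature (mean optional), the anatomical region
(fixed 12-level vocabulary: frontal, central, parietal, occipital,
temporal, insular x hemisphere), and patient age. Zero-event electrodes
keep rate 0 with missing morphology — the tree model handles missingness
natively, and dropping them would bias the sample toward high-rate
sites.

## The SOZ probability model

A gradient-boosted tree ensemble (xgboost, binary logistic objective)
maps the seven features to an SOZ probability. Evaluation uses nested
10-fold cross-validation: outer folds are grouped by patient (no patient
spans folds; grouping prevents within-patient leakage — the stratification
scheme is our choice since electrode- vs patient-level splitting is
genuinely open) and approximately stratified by per-patient SOZ counts;
the inner loop tunes a small versioned grid (depth 2/4, learning rate
0.1/0.3, 60 rounds, 0.8 row/column subsampling, imbalance-weighted
positives) on the outer-training portion only. Every electrode is scored
exactly once by a model that never saw it. Determinism is guaranteed by
single-threaded fits with derived seeds.

Robustness is checked with a pseudo-label null: labels are redrawn at
16.8% prevalence (the SOZ-site prevalence the pipeline emulates), the
nested CV is rerun per replicate, and the permutation p-value uses the
add-one rule `p = (1 + #{null >= observed}) / (n_models + 1)`; with 100
replicates all below the observed AUROC this floors at 1/101 = 0.0099.
The default replicate count is 20 (100 for the full experiment); test
runs use 10 — a runtime choice, the statistic is a mean over replicates
either way.

Feature attributions use exact tree-SHAP (`predcontrib`); per-row
contributions plus the bias reconstruct the model margin to
single-precision accuracy (tested at 1e-5 — xgboost margins are
float32, so the textbook 1e-6 bound is not representable), and the
global ranking orders features by mean absolute attribution with the 12
region indicators pooled into one feature.

## Outcome analysis

For each patient the *biomarker difference* is the mean biomarker value
(SOZ probability or HFA rate) over resected electrodes minus the mean
over preserved ones; higher values mean high-biomarker tissue was
preferentially removed. Four alternative summaries are provided:
difference index `(R - P)/(R + P)`, resection ratio
`sum(resected)/sum(all)`, critical resection percentage (% of
electrodes above a critical value that were resected; default critical
value is the cohort's 90th percentile — our choice, no standard default
exists), and the distinguishability statistic (rank probability that a
resected electrode outranks a preserved one, i.e. the AUROC of the
resection mask). Patients with an undefined measure (e.g. no resected
contacts) are excluded listwise with a warning.

The standard-care logistic model regresses ILAE class 1 on the 10
routine covariates (age, sex, daily seizures, ASM count, hemisphere, MRI
lesion, habitual-seizure capture, incomplete SOZ removal, extratemporal
resection, resection extent), optionally plus one summary measure; the
odds ratio for the measure is reported per unit (standardization is left
to the caller). Discrimination with and without the measure is compared
by leave-one-patient-out prediction and a paired DeLong test. Subgroup
evaluation (e.g. by MRI etiology) recomputes AUROCs within groups
without refitting.

## Evaluation statistics

AUROC is the Mann–Whitney pair probability with half credit for ties
(equal to exhaustive pair counting; tested on all instances up to
n = 12), with DeLong confidence intervals and paired DeLong tests via
pROC. AUPRC is the interpolation-free step summation, whose expectation
under random scoring is the positive prevalence. The bootstrap paired
test resamples rows with replacement and reads a two-sided p from the
replicate distribution of metric differences (2000 replicates by
default; single-class replicates are redrawn). Paired SOZ vs
non-epileptic contrasts use the Wilcoxon signed-rank test with effect
size `r = Z / sqrt(N)` signed by the median difference
(small ~0.1 / medium ~0.3 / large >= 0.5); the signed-rank (not
rank-sum) form matches the per-patient pairing of the contrast tables.
Detector-family comparisons apply a Bonferroni gate at p < 0.0125
(alpha = 0.05 over the four detectors, strict inequality). DeLong and
bootstrap tests are calibration-tested (type-I error within
[0.02, 0.09] at alpha = 0.05 over 200 simulated nulls).

## The synthetic cohort generator

The generator defines the study conditions every test runs under:
1000 Hz sampling, 5-minute non-REM epochs (20 minutes available),
16.8% SOZ-site prevalence, subdural grids plus one depth shaft of >= 4
contacts, and three event classes whose rates, amplitudes and class
mixes differ between site classes in the configured directions (SOZ
sites: higher rate, higher amplitude, more spike–oscillation complexes).

Background is pink noise (PSD ~ 1/f, floored below 0.5 Hz) plus a single
0.5–4 Hz slow-wave component — the recordings emulate non-REM sleep but
no background statistic is standard, so this is a deliberate minimal
model. Defaults: 5 uV broadband pink RMS (~2.3 uV within 80–500 Hz) and
20 uV slow wave. Oscillations are Hann-windowed sinusoids (20–80 ms,
center frequency 90–250 Hz); spikes are a sharp biphasic transient plus
a Hann-enveloped broadband 80–500 Hz noise burst spanning the event
(40–80 ms) — a bare millisecond transient would carry no sustained
in-band energy and would be undetectable by any energy criterion,
contradicting how spike-related HFA behaves; complexes superimpose
both. The spike burst is RMS-matched to the oscillation so `amplitude`
means the same in-band energy for every kind. Default site-class event
rates are 3.0 / 1.5 / 0.8 / 0.6 events/min (SOZ / spiking /
resected-other / non-epileptic) with mean amplitudes 24 / 19 / 17 /
16 uV — SNR such that SOZ events sit around 4–5x the in-band background
RMS at their core, the regime where the four detectors operate reliably.
Throughout, event SNR is quantified as the event's core in-band RMS
relative to the background's in-band RMS.

Outcomes follow a logistic link on the true biomarker difference
computed from ground-truth rates and the resection mask:
`P(ILAE 1) = plogis(intercept + beta * d)`, intercept 0 and beta 1.5 by
default, with per-patient resection quality drawn from a Beta(2.5, 1.5)
so the difference varies across patients. `beta = 0` degenerates to a
fair coin; negative `beta` produces the inverted regime where resecting
high-biomarker tissue predicts a worse outcome.

What the generator does *not* emulate: volume conduction and
inter-channel correlation, ictal dynamics, artifacts beyond exclusion
flags, realistic electrode geometry, and any coupling between anatomy
and epileptogenicity. Passing tests therefore demonstrate that the
pipeline recovers known structure under idealized signals; they say
nothing about detector sensitivity on real recordings, where background
spectra, artifacts and non-stationarity dominate the error budget.

Signals can be synthesized lazily per patient (`signals = FALSE` plus
`patient_signals()`), so metadata-scale experiments (hundreds of
patients for outcome-model recovery) never materialize the ~2.4e9
samples a fully rendered cohort of that size would need; outcome
analyses operate on per-electrode values, for which ground-truth rates
serve directly.

## Problem sizes and numerical choices

Test and acceptance runs use: a 79-patient x 16-channel cohort (1264
electrodes) for model recovery and the pseudo-label null (>= 1000
electrodes, 10 label redraws); 400 metadata-only patients for outcome
recovery; 120-s two-channel signals with ~56 injected events per
detector check; 200 simulated nulls for test calibration with 300
bootstrap replicates each. These sizes were chosen so the full suite
exercises every stage at statistically meaningful scale on a single
CPU. Other numerical choices: EDF samples quantize to 16 bits over the
per-channel range (round-trip error below one quantization step);
frequency-tie peaks report the lower bin; zero-difference pairs are
dropped from the signed-rank test with tie-corrected normal
approximation; degenerate inputs (single-class labels, empty resection
sides, all-zero spectra) raise errors or return flagged missing values
rather than silent defaults.

## Known limitations

Detector parameters follow the original publications' defaults where
printed; exact numerical replication of the MATLAB reference
implementations is out of scope (filter realizations differ), so
equivalence is at the level of detection behavior on ground-truth
events. The outcome model's probability calibration is not asserted —
only rank-based discrimination is used. Cross-channel network features
of HFA are deliberately absent. Real-cohort effect sizes (e.g. published
AUROC ranges) are not reproduction targets; they depend on patient data
this package does not ship.
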