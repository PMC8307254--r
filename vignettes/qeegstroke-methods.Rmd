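---
title: "Task-induced qEEG stroke biomarkers: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Task-induced qEEG stroke biomarkers: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

An ischemic lesion disturbs the cortical rhythms that scalp EEG records:
slow-wave (delta, theta) power rises over the affected tissue while
faster alpha activity weakens, and the power balance between homologous
left/right electrode sites degrades. Quantitative EEG (qEEG) turns these
observations into numbers — band powers, slow-to-fast power ratios and
interhemispheric symmetry indices — that can be compared between a stroke
group and a control group, tracked across task states of increasing mental
workload, and fed to classifiers.

`qeegstroke` implements that analysis end to end for a six-channel montage
(Fz, C1, C2, T7, T8, Oz, plus VEOG and chin-EMG reference channels,
nominally sampled at 1000 Hz) and four task states with ordinal workload
levels: resting (0), walking (1), working (2), reading (3). Because no
public recording set exists for this protocol, the package ships a
first-class synthetic cohort generator with the statistical structure the
analysis assumes, so every downstream stage is testable.

## The synthetic signal model

Each scalp channel is a sum of five independent band-limited Gaussian
processes, one per canonical band (delta 0.5–4, theta 4–8, alpha 8–13,
beta 13–30, gamma 30–44 Hz), generated by FFT-masking white Gaussian noise
to the band — an ideal band-pass — and rescaling to the target variance
exactly. The band variances come from a per-(group, task) profile, so the
generator reproduces group-by-task spectral differences with an analytic
oracle: the four-band relative power of a channel is simply
$v_b / \sum_{b'} v_{b'}$ over the profile variances.

Design choices worth knowing:

* **Independent channels.** Scalp channels are generated independently
  apart from deterministic asymmetry scaling and artifact leakage. The
  downstream biomarkers consume only power ratios, not cross-spectra, so
  inter-channel coherence would add realism without adding testability.
* **Lesioned hemisphere fixed to the right.** Stroke subjects have C2 and
  T8 amplitude-scaled by $1 + a$ (power by $(1+a)^2$), where `asymmetry_factor`
  $a$ defaults to 0.3. With $a = 0.3$ the signed right-minus-left power
  asymmetry has the analytic value $(1.69 - 1)/(1.69 + 1) \approx 0.2565$.
  A fixed side keeps the sign of the asymmetry features interpretable.
* **Default cohort effect.** Stroke profiles are the control profiles with
  delta × 1.5 and alpha × 0.7 — the canonical post-stroke slow-wave shift.
  Control profiles are alpha-dominant at rest (delta 20, theta 10,
  alpha 30, beta 12, gamma 4 µV²) with task modulations that push power
  toward theta and away from alpha/beta during motor tasks; magnitudes sit
  in the tens-of-µV² range typical of scalp band power.
* **Artifacts.** VEOG carries biphasic raised-cosine blink pulses (400 ms,
  100 µV) at a Poisson rate (default 12/min) and leaks into Fz with gain
  0.1; EMG carries Hann-enveloped broadband (> 20 Hz) bursts (default
  6/min) leaking into T7/T8 with gain 0.1. The leakage is exactly linear,
  which is what the regression-based artifact removal assumes; amplitudes
  were chosen to be clearly visible in delta-band power yet fully
  removable.
* **Protocol defaults.** Four tasks of 180 s each in protocol order
  (resting, walking, working, reading), 1000 Hz, 10 stroke + 10 control
  subjects. Per-subject RNG substreams are derived from the master seed,
  so cohorts are byte-reproducible and individual subjects can be
  regenerated in isolation.

What the generator deliberately does **not** emulate: volume conduction or
any forward model, 1/f background, nonstationarity within a task,
per-subject severity strata, or lesion-side variability. Passing tests on
this cohort demonstrate that the estimators recover the generative
structure they target — not that the pipeline's clinical effect sizes
transfer to real recordings.

## Preprocessing

The cleaning chain follows standard clinical qEEG practice:

1. **Notch** at the 60 Hz line frequency: order-2 Butterworth band-reject
   with quality ≈ 30 (2 Hz stop width), applied forward–backward
   (`filtfilt`) for zero phase.
2. **Band-pass** 0.5–44 Hz: a cascade of an order-4 Butterworth high-pass
   and an order-6 low-pass, each zero-phase. A single 4th-order band-pass
   was rejected because its measured double-pass attenuation at
   `high + 10` Hz (≈ 16 dB) misses the ≥ 20 dB stop-band contract that the
   cascade meets; the pass-band stays flat within 1 dB.
3. **Artifact removal** by per-interval least-squares regression of every
   scalp channel on [VEOG, EMG] (with intercept). This removes exactly the
   reference-correlated component, deterministically — the behaviour an
   ICA-based cleanup aims for when it uses reference channels to pick
   components, without ICA's rotation ambiguity. Component-based methods
   remain an extension point; they are not implemented.
4. **Epoching** into fixed 10-s windows cut inside annotated task
   intervals only; trailing partial windows are discarded. No
   peak-to-peak epoch rejection is applied by default (a configurable
   threshold exists in `reject_epochs()`).

## Spectral features

PSDs are estimated per epoch by Welch's method: 2-s Hamming segments, 50%
overlap, one-sided density scaling in µV²/Hz. The 2-s segment gives a
0.5 Hz grid whose bins align exactly with every band edge. The historical
phrase "10% hamming window" for this analysis is ambiguous (10% of the
epoch would be 1-s segments and a 1 Hz grid that cannot represent the
0.5 Hz delta edge; a 10% Tukey taper is not a Hamming window), so the
2-s/50% configuration is the package default and both parameters are
exposed.

Band powers integrate the PSD over half-open `[low, high)` bins (gamma
closes at 44 Hz) so adjacent bands never double count. Relative power
divides by the four-band denominator delta + theta + alpha + beta; gamma
is excluded from the denominator but its relative power is reported
against the same denominator, so the four denominator bands always sum
to 1. Undefined features (zero denominators) become `NA` markers and
propagate pairwise.

Spectral summaries (power-weighted mean frequency, median frequency, peak
frequency, 95% spectral edge) are computed over 0.5–44 Hz; 95% is the
dominant spectral-edge convention. Task-induced change is expressed as
$\Delta p = 100\,(p - \bar{rp}_r)/\bar{rp}_r$ percent against the
subject's mean resting relative power.

**Known estimator bias.** A Hamming-windowed 2-s segment leaks power
roughly ±1 Hz around sharp spectral edges. For the narrow delta band this
is material: part of its power smears below 0.5 Hz, outside every band,
giving delta relative power a systematic bias of about −7% *relative* (−2
to −3 points of a typical delta fraction) at 10-minute averaging, with
neighbouring sparse bands gaining correspondingly. Absolute recovery
errors stay well under 0.05; slow-to-fast ratios (DAR/DTR) inherit up to
≈ 15% relative bias when the numerator and denominator bands have very
different spectral densities. Left/right asymmetry indices are unaffected
because the bias cancels in same-band ratios between channels. Tests and
tolerances reflect these measured properties.

## Biomarkers

* **DAR** = delta/alpha and **DTR** = delta/theta power per channel
  (computed on relative powers; the denominator cancels, so these equal
  the absolute-power ratios).
* **DTABR** = (delta + theta)/(alpha + beta) on absolute powers. Under the
  four-band relative normalization DTABR is not denominator-invariant, so
  absolute powers are the defined basis.
* **pdBSI**: mean over homologous pairs (C1–C2, T7–T8) and 0.5 Hz bins in
  0.5–30 Hz of $|R - L| / (R + L)$; 0 = symmetric, 1 = totally
  asymmetric. The frequency index is interpreted as individual PSD bins
  (not four band aggregates); band-restricted components are also
  computed for workload-profile summaries. The absolute value is required
  for the stated [0, 1] range.
* **Band power asymmetry**: mean over pairs of $(R - L)/(R + L)$ on
  band-integrated power, kept *signed* (right minus left) so lateralized
  effects retain direction; range [−1, 1].
* Ratios are computed per channel and also usable as channel means; the
  feature table keeps per-channel columns (named `channel__feature__band`)
  plus pair-level columns.

Feature tables come in two aggregations: per-epoch rows (default for
classification — more rows for the 70/30 split) and per-(subject, task)
means (default for group statistics). Both are exposed.

## Group statistics and feature ranking

Each feature is compared stroke-versus-control with the classical
two-stage test: Levene's test (mean-centered) at α = 0.05 gates between
the pooled-variance and Welch t-tests; two-sided p-values are reported
with significance at p < 0.05, uncorrected. No multiple-testing
correction is applied by default, matching standard practice in this
analysis style; `p.adjust` can be applied to the output by the user.

Feature importance is `1 − p` from Pearson's chi-square test of
independence between the discretized feature and the group label.
Continuous features are discretized into 10 equal-frequency bins (fewer
under ties), which makes the importance invariant to monotone transforms.
Screening first removes constant columns and columns with more than 20%
missing values; selection keeps features with importance > 0.95. The
equal-frequency binning with adequate samples keeps the null distribution
of importances approximately uniform — with small cells (expected counts
below ~10) the chi-square approximation visibly distorts it, which is why
calibration checks use a few hundred rows per group.

## Classification harness

70/30 train/test split, stratified by group and *subject-disjoint* by
default (all epochs of a subject land on one side), preventing
within-subject leakage — whether the original analysis split at subject
or epoch level is unknowable, so both modes exist. Four model families:

* an entropy-criterion decision tree (`rpart`, `split = "information"`) —
  the open substitute for the proprietary C5.0 engine;
* an RBF-kernel SVM with cost/gamma chosen by 10-fold cross-validation on
  the training set (`e1071`);
* logistic regression (binomial GLM);
* a random forest (`randomForest`) for the "random trees" family.

Scores are positive-class probabilities in [0, 1] with the stroke group
as positive class and hard labels at 0.5. The metric panel is computed
from the confusion matrix (accuracy, sensitivity, specificity, precision,
NPV, with `NA` markers on zero denominators); AUC uses the rank
(Mann–Whitney) estimator with midrank tie handling, and Gini = 2·AUC − 1.
The phrase "double of (AUC − 1)" sometimes attached to the Gini would
give a negative value for any AUC < 1 and contradicts every published
AUC/Gini pairing; 2·AUC − 1 is the standard definition and what the
package computes. The experiment grid runs each task-specific dataset
plus the task-independent pooled dataset, and a resting-versus-active
variant (label = workload level > 0, groups pooled).

Feature selection inside the harness is performed on the training side
only. This is deliberately stricter than selecting on the full dataset
before splitting (which leaks test information into the selection); with
the strong default synthetic effect the distinction is immaterial, on
real data it is not.

## Numerical and interface choices

* All signal amplitudes are µV, times are seconds from recording start,
  annotation intervals are half-open `[start, end)`.
* EDF (16-bit) is the on-disk recording format, written and read by a
  minimal base-R implementation; channels are scaled to per-channel
  physical ranges, so round-trips are exact up to one quantization step.
  Annotations travel in a sidecar CSV (`<file>.annotations.csv`) rather
  than an EDF+ annotation channel. Wide CSV input (one column per
  channel, labels in the header, 10–20 aliases accepted case-insensitively)
  is also supported.
* Pipeline configuration serializes to a single YAML document; unknown
  keys are rejected. Every run writes a JSON manifest (config hash, seed,
  package version), and a rerun from the same config and seed regenerates
  every output byte-identically (all stochastic steps draw from seeded,
  per-subject or per-stage substreams).
* Degenerate inputs produce `NA` markers, not errors, wherever the
  quantity is genuinely undefined (zero spectra, zero-power pairs,
  all-constant bins); structural problems (missing channels, overlapping
  annotations, single-class training data) raise errors naming the
  offender.

## Problem sizes used in the shipped checks

The package's own verification runs at deliberately chosen scales: unit
tests use 250 Hz cohorts with 20–60 s tasks (seconds per test); the
end-to-end checks use the full default conditions — 1000 Hz, four 180-s
tasks, 10 + 10 subjects — for estimator recovery and discriminability,
and a 3 + 3 subject cohort for byte-level determinism. Statistical
calibration uses 1000 null feature draws at 250 rows per group. These
sizes make the Monte-Carlo tolerances in the tests (±0.05 absolute on
relative-power recovery, ±0.03 on asymmetry recovery, 0.03–0.07 on the
null false-positive rate) comfortably attainable without being trivial.

## Limitations

* The synthetic cohort is a band-variance model; none of the pipeline's
  claims about real post-stroke EEG are tested here, only the estimators'
  fidelity to a known generative truth.
* The regression-based artifact removal only removes reference-correlated
  activity; artifacts invisible to VEOG/EMG pass through.
* Delta-band features carry the edge-leakage bias described above; if
  absolute delta accuracy matters, use longer Welch segments via the
  exposed configuration.
* The feature importance, selection threshold and classifier settings
  reproduce a particular analysis workflow; they are not tuned
  recommendations for new studies.
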