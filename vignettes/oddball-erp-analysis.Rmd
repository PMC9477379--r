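---
title: "Simulating and decoding name-stimulus oddball ERPs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and decoding name-stimulus oddball ERPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The experiment and the analysis problem

In the auditory oddball paradigm studied here, a subject hears five spoken
names over headphones: their own name (the target, "SON") and four
unfamiliar names (non-targets, "ONs").  A session has 5 blocks of 20
repetitions; each repetition presents all five names once in pseudo-random
order with the constraint that the same name never plays twice in a row.
Stimuli last 600 ms and are separated by a uniform 500–800 ms silent
interval, giving 500 stimuli per session (100 targets, 400 non-targets).
Sessions are run in four conditions crossing attention mode (*active* =
silently counting the target, *passive* = just listening) with non-target
name length (*3CC* = three syllables, *2CC* = two syllables).

Targets in an attended oddball stream evoke a parietal P300 (a positive
deflection roughly 300–600 ms after onset, largest around Pz); the spoken
non-target names evoke an earlier frontal P200 (~200–270 ms, largest around
Fz) and targets also show a modest fronto-central N2 negativity.  The
analysis question is how reliably the target name can be detected from
single trials, and how that reliability depends on condition.

The package implements the full pipeline — synthetic data generation,
preprocessing, discriminability mapping, window feature selection, SVM
classification with repetition aggregation, and condition statistics — with
`aerp_fit()` as the core estimator.

## The synthetic generator

Because no public recordings accompany this paradigm, the generator is a
first-class, tested component: every downstream stage is validated against
data whose ground truth is known.

Each ERP component is a Gaussian temporal envelope
$a \, \exp(-(t-\mu)^2 / 2w^2)$ projected through a smooth scalp topography
(Gaussian fall-off with electrode distance on a unit-disc 10-10 montage of
60 channels).  Per trial, the amplitude $a$ is drawn
$\mathcal N(\bar a, \sigma_a)$ and the latency $\mu$ is jittered.  The
background is band-limited (0.5–40 Hz) Gaussian noise with a $1/f$ power
spectrum, independent across channels.

Defaults encode the study conditions:

* target P300 mean amplitudes per condition: passive-3CC 3.02, active-3CC
  5.40, passive-2CC 1.87, active-2CC 4.43 µV, with condition-wise peak
  latencies in 395–535 ms; non-target P200 amplitudes and 220–275 ms
  latencies follow the per-condition measurement table at Fz.  Envelope
  widths (P300 60 ms, P200 25 ms, N2 35 ms), trial-level amplitude SDs and
  latency jitters are assumptions, chosen as typical single-subject ERP
  variability.
* between-subject spread of the P300 mean is $\sqrt{12}\times$ the reported
  group standard errors (printed for $n = 12$), so simulated cohorts
  reproduce the printed Mean ± SE scale.
* the noise level is **not** reported for the original recordings.  We fix
  `noise_sd = 8` µV by calibration: it is the level at which the active-3CC
  condition's single-trial accuracy falls in the 80–90 % band, matching the
  reported group mean of 85 %.  This is a modelling assumption, not a
  measured value.
* the target N2 amplitude (−2 µV) is likewise an assumption; the source
  figures show the component but print no number for it.

Seeding is hierarchical: a master seed plus the documented counter scheme
`child = (master + 1000003 k) mod (2^31 - 1)` gives every subject/session
its own seed, so any single session of a cohort can be regenerated in
isolation.

What the generator does **not** emulate: volume-conducted correlated noise
across channels, eye-blink and muscle artifacts (beyond what the amplitude
rejection test plants explicitly), non-Gaussian trial-to-trial component
shape changes, and habituation across blocks.  Passing tests therefore show
that the *analysis machinery* is correct and calibrated, not that it will
reach the same numbers on real recordings.

## Preprocessing

The chain is fixed: band-pass filter → decimation → (optional) ICA
artifact removal → epoching → baseline correction → amplitude rejection.

* **Filter**: linear-phase Hamming-window FIR, 0.5–40 Hz, applied forward
  with group-delay compensation so there is no net shift.  The order follows
  the window-method rule $N = 3.3 f_s / \Delta f$ with the transition width
  set by the 0.5 Hz lower edge; at 1 kHz that is 6601 taps, which is why the
  generator leaves 5 s of lead-in before the first stimulus.
* **Decimation** to 200 Hz with an internal anti-alias low-pass (cut-off at
  80 % of the new Nyquist); the original sampling rate of the source
  recordings is not documented, so the generator's 1 kHz default is an
  assumption.
* **ICA stage**: the original analysis removed ocular components by manual
  inspection, which cannot be reproduced.  We provide an automated rule
  instead — FastICA (symmetric, tanh contrast), zeroing components whose
  absolute correlation with designated frontal proxy channels exceeds 0.8 —
  and keep it off by default for synthetic data, which plants no ocular
  source.
* **Epochs** span the half-open window [−200, 800) ms so a 200 Hz epoch has
  exactly 200 samples; endpoint inclusion is not specified by the source
  description, and the half-open choice avoids double-counting the boundary
  sample.  Baseline is the mean over [−200, 0) ms per epoch and channel.
* **Rejection** flags a whole epoch when any channel sample exceeds
  ±100 µV.  Channel scope was unstated; any-channel is the conservative
  reading.

## Discriminability and feature selection

At every channel and time point the target/non-target separation is the
signed squared quantity

$$ r^2(t) = \pm \left[ \frac{\sqrt{M_T M_N}\,
  (\overline{X_T} - \overline{X_N})}{(M_T + M_N)\,
  \mathrm{std}(X_T \cup X_N)} \right]^2 $$

with the sign of the mean difference.  `std` is read as the *sample*
standard deviation ($n-1$) of the pooled trials; under that convention the
quantity is the signed squared point-biserial correlation between amplitude
and class label (the test suite checks agreement to $10^{-12}$).  Constant
channels (zero pooled variance) propagate as flagged missing values —
a constant carries no discriminative information.

Feature selection works inside two constraint windows, T1 = [100, 300) ms
and T2 = [300, 600) ms.  The early window is defined as 100–300 ms in the
source methods but appears as 200–300 ms in its results; which one produced
the published accuracies is unknowable, so the methods definition is the
default and the narrower window is available as an ordinary
`constraint_window("T1", 200, 300)` override.  Within a window:

1. `score(t)` = mean over channels of $|r^2|$ + max over channels of
   $|r^2|$.  The aggregation dimension was unstated; aggregating over
   channels at fixed time is the reading under which the subsequent "select
   a time range" step is well-defined.  Magnitudes are used because
   discriminability is sign-agnostic for selection.
2. Adjacent time points are linked by the plain cosine similarity
   $\langle x(t), x(t{+}\Delta t)\rangle / (|x(t)||x(t{+}\Delta t)|)$ of the
   across-trial amplitude vectors, exactly as the inner-product formula is
   written (no mean-centering).  The vector dimension was unstated; we use
   one channel's across-trial vector and aggregate channel cosines by
   median before thresholding.
3. The selected range is the longest contiguous run of points with
   `score(t) > 0.5 × max score` whose interior links all have cosine
   > 0.7; ties break toward the run containing the score maximum, and if no
   point qualifies the single maximal point is used with a warning.
   "More than half of the score value" is read as half the window maximum —
   the only scale-free interpretation of "half".

Averaging amplitudes over the selected range per channel gives one feature
per (window, channel): a 500 × 120 matrix for a default session, labelled
+1/−1.

## Classification and evaluation

Classes are unbalanced 100:400, so classification is four balanced binary
problems — the target name against each non-target name — each evaluated by
stratified 10-fold cross-validation of a linear SVM (cost 1, untuned;
the source describes the classifier only generically).  Features are
standardised per fold with training-set statistics, since SVM margins are
scale-sensitive.  The headline single-trial accuracy is the mean of the
four pairing accuracies.

Held-out decision values drive name identification: within each block,
every name's values over its first $k$ presentations are averaged and the
arg-max name is called the target.  Decision values come from held-out
folds only — using training-set values would leak — and target trials,
which appear in all four pairings, use the mean of their four values.
Exact ties resolve to the lowest name index and are flagged.  ROC curves
and AUC (trapezoidal; equal to the normalised Mann–Whitney U) are computed
on the pooled held-out values; per-pairing ROC can be derived from the
stored decision table.

ERP measurement follows the group-figure conventions: window mean
amplitude, and the signed extremum matching component polarity (positive
for P200/P300, negative for N2) with its latency, measured on across-trial
averages (targets at Pz, non-targets at Fz).  Condition contrasts are
paired two-sided t-tests across subjects — the design-consistent choice for
a within-subject 2 × 2 design — reported with raw p-values (the source
reports uncorrected values; `p.adjust` can be applied by the caller).
Whether the original t-tests were across subjects or across trials is
unstated; across-subject is implemented.

## Numerical choices and degenerate inputs

* Half-open windows everywhere (epochs, baselines, constraint windows) keep
  sample counts exact and prevent double-assigning boundary points.
* Zero pooled variance → flagged missing `r²`, excluded from scores; zero
  norm vectors → flagged missing cosine, treated as a broken link.
* All-equal decision values → flagged tie, lowest-index call.
* Degenerate rejection thresholds abort the pipeline at the analysis stage
  with the stage named.
* Identical paired samples in a contrast give $t = 0$, $p = 1$ rather than
  an error.

## Problem sizes used in the tests

The shipped test suite validates the pipeline at the design's native
session size (500 epochs × 60 channels × 200 samples) and uses: 50 seeded
null sessions for chance-level calibration, 100 seeded sessions for
planted-peak recovery and for repetition-aggregation monotonicity, and a
30-subject simulated cohort for the condition ordering check.  The
acceptance script reproduces the headline quantities on a 12-subject
cohort, the size of the study cohort it emulates.

## Known limitations

* The generator's spatial model is a distance kernel on a 2-D montage, not
  a volume-conduction head model; topographies are smooth and unimodal.
* Independent channel noise understates the spatial correlation of real
  EEG, which makes multichannel classifiers look better than they would on
  real data at the same SNR; the calibrated noise level absorbs this at the
  accuracy scale but not necessarily at the AUC or topography scale.
* Feature selection and classification share the session's trials (as in
  the published procedure), so null-data accuracies carry a small optimism
  from selection; the calibration tests quantify it (~2 % at Δ = 0)
  instead of removing it.
* The ICA artifact stage is validated on planted blink-like sources only.
* EDF support covers continuous 16-bit recordings with a uniform sampling
  rate, not the discontinuous (EDF+D) or annotated variants.
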