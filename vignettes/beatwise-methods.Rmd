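---
title: "Locating the ECG signal behind reduced ejection fraction: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating the ECG signal behind reduced ejection fraction: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question

Convolutional networks can detect reduced left ventricular ejection
fraction (LVEF below 50%) from a resting 12-lead ECG, but *where* in the
signal the discriminative information lives is much harder to establish.
`beatwise` frames that localisation question as a set of controlled
experiments over three axes:

* **representation** — a 3 s multi-beat strip (12 x 1500 samples at 500 Hz)
  versus a single fixed-length beat (12 x 375) versus a channel-wise stack
  of two consecutive beats (24 x 375);
* **leads** — classifiers trained on subsets of the 12 standard leads, with
  a per-lead *contribution* statistic (mean metric of models whose lead set
  contains the lead minus the mean of those lacking it);
* **intra-beat segments** — the P, PQRS, QRS, QRST and PQRST portions of a
  beat, all masked back to the common 12 x 375 shape.

Real ECG/echocardiography pairs are hospital data and cannot ship with a
package. `beatwise` therefore includes a synthetic cohort generator whose
discriminative signal is *planted at a known location*: recovery of that
location by the pipeline is the testable claim, not any particular AUC on
clinical data.

## The synthetic cohort generator

Each record is 10 s of 12-lead ECG at 500 Hz (a 12 x 5000 matrix in mV).
Beats are sums of five Gaussian wavelets — P, Q, R, S, T — each with an
amplitude, width (sigma, ms) and latency relative to the R peak. The
defaults (P: 0.12 mV / 22 ms / -170 ms; Q: -0.10 / 9 / -28;
R: 1.0 / 11 / 0; S: -0.22 / 10 / 28; T: 0.30 / 60 / 310) give a plausible
adult sinus beat whose fiducials are *analytic*: QRS onset is taken at the
Q latency minus 2.5 sigma, the ST junction at the S latency plus 2.5 sigma,
the T end at the T latency plus 2.5 sigma. Exact ground truth is what makes
delineation and segment-recovery tests meaningful; the sum-of-Gaussians
model was chosen over dynamical-system ECG simulators precisely because its
fiducials need no numerical root-finding.

Waves live on three dipole source channels and are mapped to the 12 leads
by a fixed 12 x 3 projection whose limb-lead rows satisfy the Einthoven and
Goldberger identities exactly (III = II - I, aVR = -(I+II)/2, ...).
Baseline wander (default 0.05 mV at 0.25 Hz) is added *in source space* —
physically, respiration moves the dipole — so the limb-lead algebra
survives wander and is only broken by per-lead measurement noise (default
0.02 mV white) and by deliberately lead-restricted effects.

Heart rate is drawn per record (default 70 +/- 8 bpm), RR intervals jitter
by 10 ms (sd) in sinus rhythm; atrial fibrillation (per-class fraction,
default 5/10/20% for pEF/mrEF/rEF) zeroes the P wave and draws i.i.d. RR
intervals with 15% coefficient of variation. LVEF is uniform within the
class interval (pEF 50–70, mrEF 40–50, rEF 20–40) since only the class
thresholds are clinically defined. Only complete beats — those whose whole
P-to-T wavelet support fits inside the 10 s window — are placed, so the
truth table enumerates exactly the beats present.

The planted signal is an `EffectSpec`: for records of chosen reduced-EF
classes, the amplitude and/or width of one wave group (P, QRS or ST–T) is
multiplied on chosen leads. A multiplier of ~0.4–0.5 on the T wave is a
strong, easily learnable effect used by the recovery experiments; the
mechanism is an explicit stand-in for whatever physiology the clinical
signal has — which waveform features actually encode LVEF in patients is
exactly the open question, and nothing here claims to answer it.

## Preprocessing

* **Delineation.** A Pan–Tompkins-style detector on lead II (band-pass
  5–15 Hz, derivative, squaring, 150 ms moving-window integration,
  thresholding with a 200 ms refractory period), refined to the argmax of
  the mean squared band-passed signal across all 12 leads. QRS onset and
  the ST junction come from smoothed-energy threshold crossings around the
  refined R peak; the T-wave end from the tangent method on the
  12 Hz-low-passed T wave. On noise-free synthetic cohorts the detector
  recovers 100% of truth R peaks within one sample; the test suite asserts
  the 99%/95% recovery contracts (clean / 0.02 mV noise) at +/- 20 ms.
* **3 s strips.** Start offsets are evenly spaced over the admissible
  0..3500-sample range, endpoint-inclusive, rounded to integer samples
  (four strips: 0, 1167, 2333, 3500). The number of strips per record is
  class- and split-dependent: x4 (pEF), x7 (mrEF), x6 (rEF) for training
  data and x4/x16/x11 for development and test data — oversampling the rare
  reduced-EF classes.
* **Single beats.** A window from 250 ms before to 500 ms after the R peak
  (375 samples); all samples after the delineated T end are replaced by the
  value at the T end, so inter-beat content does not leak into the
  "single beat" representation. Beats whose window crosses the record
  boundary are dropped and counted.
* **Partial segments.** With b = QRS onset - 100 ms, j = ST junction,
  t = T end (window coordinates), the five segments are P = [0, b),
  QRS = [b, j), QRST = [b, t), PQRS = [0, j), PQRST = the full window.
  Samples outside a segment's span are replaced by the span's nearest
  boundary value (constant continuation) so all five kinds share one CNN
  input shape; the set of unmasked samples is monotone
  (P ⊂ PQRS ⊂ PQRST, QRS ⊂ QRST ⊂ PQRST). Note that defining the P/QRS
  boundary 100 ms before QRS onset deliberately places a short stretch of
  pre-onset signal inside the "QRS" segment.
* **Two-beat stacks.** Beat i and beat i+1 concatenated channel-wise into
  24 x 375; the final beat wraps around to the first, so the output count
  equals the beat count.
* **Standardisation.** One scalar mean and one scalar sd over every sample
  of the training tensors; dev/test/external data reuse the train
  statistics unchanged. This is asserted at run time by the no-leakage
  checks.

Sample indexing is 1-based inside the package (R convention); strip start
offsets are reported 0-based so the offset arithmetic above reads naturally.

## The classifier

A 1D CNN: `nBlocks` blocks of convolution ("same" padding, no bias), batch
normalisation, ReLU and max pooling, then a flattening fully connected
softmax layer — ten weighted layers in the default configuration (nine conv
blocks, filters 16→128, kernels 7/5/3, pool 2). The same code path serves
1–24 input channels and 375- or 1500-sample inputs; an optional hidden
dense layer (`fcWidth`) is available but off by default. Because no deep
learning framework is available to R in this toolchain, the forward pass,
analytic gradients (im2col convolutions as single BLAS products, standard
batch-norm and max-pool backward rules) and Adam are implemented in the
package and verified against finite differences to ~1e-8 relative error.

Training minimises class-weighted cross-entropy (pEF : reduced = 1 : 2 by
default, matching the roughly 2:1 class imbalance the weighting is meant to
counter), with MixUp augmentation (Beta(0.2, 0.2), one lambda per batch,
labels mixed identically; disabled for reduced-lead runs). Checkpoint
selection keeps the epoch with the best development AUC. Batch-norm running
statistics are primed with the first batch's moments and then updated with
momentum 0.1. Divergent (NaN) loss aborts the fold with a diagnostic rather
than returning a silent garbage model.

## Splitting and evaluation

Cases are stratified by EF class and dealt round-robin into five subsets:
subsets 1–4 rotate as development sets over four folds (the remaining three
train), subset 5 is the *fixed* test set shared by every fold. Splits are at
case level — all strips/beats of a case stay together — and disjointness is
asserted at run time. Case-level scores are the mean predicted reduced-EF
probability over the case's tensors (median/majority available); the
reduced-lead analysis is evaluated at data level instead, one score per
tensor. AUC is the Mann–Whitney concordance probability computed by
midranks (ties count one half), checked in the tests against a brute-force
O(n^2) oracle at 1e-12. Accuracy/sensitivity/specificity use a 0.5
operating threshold by default. Two configurations are compared by
Student's t-test on per-fold AUCs; three or more by one-way ANOVA with
Tukey's HSD at 0.05.

## Experiments and desk-scale defaults

The three runners (`runRepresentationExperiment`, `runSegmentExperiment`,
`runLeadExperiment`) generate EvalResult tables, comparison statistics and
rankings, all reproducible bit-for-bit from (configuration, seed). The
package's own validation runs use desk-scale sizes chosen to keep each
experiment in the minutes range on one CPU: 60-case cohorts
(30 pEF / 15 mrEF / 15 rEF), three-block compact model configurations,
5–6 epochs, one or two folds, and a 12-singleton lead ensemble; chance-level
(null) controls are evaluated case-level on a fresh 300-case cohort so the
chance band is tight, and the label-permutation control averages ten seeded
runs. The full 2^12 - 1 = 4095 lead subsets remain available via
`enumerateLeadSets("all")`, but a full sweep times folds is cluster-scale
by construction, which is why the default ensemble is singles +
leave-one-out + a seeded sample of subsets. (One printed figure in the
field for the subset count, 40,955, is simply the mis-typed closed form;
the package uses 4095.)

With a T-wave amplitude effect planted on all leads, the expected pattern —
and what the acceptance checks assert — is QRST ≈ PQRST well above QRS-only
and P-only models, every representation recovering the signal, a
lead-I-restricted effect putting lead I at the top of the contribution
ranking, null cohorts at chance, and label-permutation controls averaging
AUC ≈ 0.5. Because the planted effect multiplies every beat identically,
all three representations see the same per-beat signal, so the
representation experiment asserts recovery rather than a strict
two-beat > single-beat ordering; beat-to-beat dynamics that would
specifically favour the two-beat stack (e.g. alternans) are outside the
generator's effect model.

## What passing tests do and do not show

The generator emulates the statistical *structure* of a clinical cohort —
class imbalance, AF's missing P waves and irregular RR, noise and wander,
lead correlation through a dipole projection — but not real ECG morphology
variation, conduction disease, ischaemia, electrode placement or
population effects. A pipeline that recovers planted signals here is shown
to be correctly wired (shapes, splits, standardisation provenance, loss
weighting, contribution arithmetic) and capable of localising a known
signal; nothing about clinical AUCs follows. Degenerate inputs are handled
explicitly: flatlines delineate to empty annotation lists, out-of-bounds
beats are dropped and counted, constant training data rejects the
standardiser, single-class label vectors make AUC an error and the
threshold metrics `NA`, and zero-epoch budgets are refused.
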