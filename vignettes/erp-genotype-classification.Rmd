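---
title: "Spatio-temporal ERP characterization and genotype classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatio-temporal ERP characterization and genotype classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epierp)
```

## The analysis problem

Mouse models of psychiatric disease are commonly screened with auditory
event-related potentials (ERPs): click stimuli are presented every 2.5 s
while multi-channel epidural EEG is recorded at 1 kHz with 16-bit
precision, and the stimulus-locked responses are compared between a
wild-type group and a mutant group (here a *WT* vs *HYPO* two-class
labeling; the hypomorph plays the role of the disease model). `epierp`
implements the full chain from continuous recordings to a genotype
classifier and discriminant cortical maps:

1. **Epoching** — a (−500, 500) ms window around each click, half-open in
   samples so an epoch at 1 kHz has exactly 1000 samples with t = 0
   included.
2. **Artifact rejection** — epochs containing any sample with absolute
   value strictly greater than 1 mV are discarded (an excursion of
   exactly 1 mV is retained).
3. **Block averaging** — consecutive retained trials are averaged in
   non-overlapping blocks of k ∈ {1, 2, 4, 8, 16, 32}; the trailing
   remainder is discarded.
4. **Features** over the (0, 250) ms analysis window: either the
   latency/amplitude of the first three peak components (N1, P1, N2) per
   channel, or the scores of the leading principal components (PCs) of
   the concatenated five-channel waveform (FL, FR, PR, OL, OR; channel FR
   alone for the single-channel family).
5. **Classification** — a Fisher linear discriminant with a scanned
   decision threshold, evaluated by leave-one-animal-out cross-validation
   with nested selection of the number of PCs.
6. **Spatial maps** — the discriminant weight vector is mapped back to
   waveform space, factored by SVD into one temporal profile and
   per-channel spatial weights, and each animal's mean ERP is projected
   on the temporal profile to produce thin-plate-interpolated cortical
   maps.

No baseline correction is applied by default (the acquisition chain is
modeled as low-cut filtered at 0.1 Hz, and the procedure the package
mirrors does not baseline-correct); `extract_epochs(baseline = TRUE)`
subtracts the pre-stimulus mean per epoch if desired.

## The synthetic cohort generator

Animal recordings of this kind are rarely shareable, so the package
ships a forward model that generates cohorts with known ground truth;
every downstream stage is tested against it. `default_config()` fixes
the study conditions:

* 18 animals — 9 wild type, 9 hypomorphic, sexes alternating within
  group (5 female / 4 male per group);
* 1100 click trials per session at 2.5 s inter-stimulus interval
  (within the typical 1000–1200 range), 1 kHz sampling, signals
  quantized to the 0.1 µV step of a 16-bit ADC;
* per-channel evoked templates: sums of three Gaussian deflections.
  Frontal channels carry N1 (−30 µV at 25 ms, 8 ms SD), P1 (+40 µV at
  60 ms, 15 ms SD), N2 (−20 µV at 120 ms, 30 ms SD); parietal templates
  are frontal × 0.7 delayed 5 ms; occipital are frontal × 0.5 delayed
  10 ms; left/right templates are identical (bilateral symmetry);
* the planted hypomorph effect: occipital N1 amplitude scale −0.8 (a
  polarity flip), frontal P1 scale 0.7, frontal N1 latency +10 ms;
* background noise: 1/f pink noise, 20 µV SD per sample, spectrally
  shaped from white Gaussian noise with content below 0.1 Hz zeroed
  (emulating the amplifier low-cut);
* inter-animal variability: one multiplicative amplitude factor per
  animal, drawn from N(1, 0.1);
* artifacts: with probability 0.02 per trial a 1500 µV, 10-sample spike
  lands inside the epoch window on one random channel, so that the 1 mV
  rejection rule is exercised at the configured rate.

The template magnitudes and effect sizes are modeling assumptions — the
kind of amplitudes and latencies a practitioner would call typical for
epidural auditory ERPs in mice — not measured values; the analysis
pipeline never sees them except through the simulated signals.
`true_effect_pattern()` integrates the signed wild-type-minus-hypomorph
template difference per channel over (0, 250) ms and is the oracle the
spatial maps are validated against.

What the generator deliberately omits: sleep–wake state, locomotion,
EMG, stimulus acoustics, latency jitter across trials (available via
`trial_jitter_sd_ms`, off by default), and any non-stationarity beyond
pink noise. Passing tests therefore demonstrate correctness of the
analysis machinery under a plausible signal model, not robustness to
every pathology of real recordings.

## The classifier and the cross-validation protocol

For a feature matrix with per-row animal and genotype labels, the
Fisher discriminant is `w ∝ (Sw + λI)⁻¹ (μ_WT − μ_HYPO)` with pooled
within-class scatter `Sw` and ridge `λ = 1e-6 · trace(Sw)/d` for
conditioning when features outnumber samples. The decision threshold is
chosen by scanning the midpoints of consecutive sorted training
projections.

Two protocol details deserve their rationale, because both were chosen
to keep the procedure honest under *animal-level clustering* — samples
from one animal are correlated (shared amplitude factor, shared slow
noise), so the effective sample size of the cohort is closer to 18 than
to the number of trials:

* **The threshold minimizes the class-balanced training error** (the
  mean of the two per-class error rates, i.e. equal class priors). In
  leave-one-animal-out folds the training set is always imbalanced
  against the held-out class (8 vs 9 animals). A pooled-error threshold
  systematically drifts toward predicting the training majority — which
  is always the *wrong* class for the held-out animal — and on null
  cohorts this manifests as reproducible below-chance accuracy. The
  balanced objective is the standard equal-prior Fisher construction
  and removes that artifact without touching the data.
* **The number of PCs is selected by a nested leave-one-animal-out loop
  over the training animals with the one-standard-error rule**: the
  smallest candidate whose pooled inner error is within one SE of the
  minimum, the SE computed across inner animals (the cluster unit).
  With only 17 training animals, plain argmin selection is dominated by
  cluster noise and erratically picks large PC counts that overfit
  animal identity; the 1-SE rule is the usual guard against exactly
  this instability. Exact ties still resolve to the smallest count.

Everything fold-specific is fitted inside the fold: PCA (never fitted
globally), the PC count, the peak-imputation column means, the
classifier and its threshold. The aggregate error pools misclassified
held-out samples over all folds; per-animal majority votes are reported
alongside (vote ties resolve to WT, a fixed deterministic convention).

Invalid peak components (a slot with no matching extremum, or a raw
amplitude contradicting the slot's polarity) are imputed with the
training partition's valid-entry column means; rows are never dropped,
so sample counts stay comparable across feature families.

## Peak detection

The detector smooths the waveform with a centered 5 ms moving average,
lists local extrema in time order (plateaus collapse to their first
sample), and fills the canonical N1 → P1 → N2 slots with the first
extrema in alternating order: a leading minimum starts at N1, a leading
maximum starts at P1 (leaving N1 invalid). Amplitudes are read off the
*raw* waveform at the extremum sample, signed, in µV; latencies in ms
from stimulus onset. This rule is deterministic, equivariant to
amplitude scaling, and recovers planted component latencies within
±2 ms on noise-free data.

## Geometry products

`spanning_plane()` builds the 2-D subspace through the FR/PR/OR grand
averages (Gram–Schmidt on the mean-centered pair FR − centroid,
PR − centroid; the order is a convention that only rotates the 2-D
basis). `covariance_ellipse()` summarizes projected trial clouds at the
1σ contour. `extract_temporal_discriminant()` operationalizes
"projecting out the temporal component" as the rank-1 SVD factorization
of the channels × time discriminant weight matrix — unique up to a sign
that is fixed by making the temporal profile's largest-magnitude sample
positive. Interpolated maps use exact thin-plate RBF interpolation
(`r^2 log r` kernel with affine terms) through the six electrode
positions, evaluated on a 0.1 mm grid over AP [−6, 3] × ML [−4, 4] mm;
the surface passes through the electrode values exactly. The map
product is descriptive and is never fed back into cross-validation; it
is computed once on the full cohort at a fixed block size.

## Numerical choices

* PCA is computed from the covariance eigendecomposition, switching to
  the Gram-matrix (dual) route when samples are fewer than features;
  loadings are orthonormal rows, variance-ordered, each sign-fixed so
  its largest-magnitude coefficient is positive. Components with
  eigenvalues below `1e-12 ×` the leading eigenvalue are dropped.
* Threshold ties resolve to the widest flanking gap, then the smallest
  threshold; boundary points predict the orientation (above-threshold)
  class.
* Degenerate discriminants (coincident class means) predict the
  training majority, ties to WT.
* Event onsets are integer samples (1-based); seconds are always
  derived, never authoritative.
* The EDF writer uses a fixed physical range (−3276.8, 3276.7) µV so
  the 16-bit quantization step is exactly 0.1 µV; signals outside the
  range are an error, never clipped. The simulator quantizes to the
  same step, so simulated recordings round-trip bit-exactly.

## Problem sizes used in the shipped tests

The test suite and the acceptance script run the full pipeline on
scaled-down cohorts — 18 animals with 256 trials (null twin), 128 or
512 trials (planted-effect twin), and twenty 448-trial cohorts for the
feature-family ordering and map-sign studies. These sizes were chosen
once as the smallest cohorts at which the studied contrasts are stable
(in particular, the multi- versus single-channel peak-feature contrast
at 32-trial averaging needs a dozen blocks per animal); the generator's
scientific defaults (1100 trials) are unchanged.

## Known limitations

* The null-cohort chance-level check inherits genuine cluster-level
  variance: with 18 animals and correlated within-animal samples, the
  pooled error fluctuates several percentage points across cohort
  seeds even with the stabilized protocol.
* Peak features on single trials are often invalid at realistic noise
  (the first noise wiggle can claim a slot); this is a property of the
  classical peak-feature approach that the PC features are meant to
  fix, and it is visible in the error-versus-averaging comparison.
* The EDF layer is deliberately minimal: one sampling rate for all
  stored signals, 1-second records, microvolt units.
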