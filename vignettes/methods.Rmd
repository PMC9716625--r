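---
title: "Models and methods behind duosync"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind duosync}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duosync)
```

## What the package models

duosync analyses how an audience's continuously rated sense of
*togetherness* in a duo music performance relates to objective features of
that performance. Four feature families are computed:

* **Quantity of motion (QoM).** Marker positions (mm, 240 Hz in the
  motivating study design) are smoothed with a Savitzky–Golay filter
  (window 25 frames, local quadratic fit) and differentiated once; the
  per-marker speed is the Euclidean norm of the 3-D velocity. *Total* QoM
  sums speeds over markers per musician per timestamp and averages the two
  musicians; *local* QoM is the duo mean of one paired body part. Both are
  block-averaged down to 10 Hz, the rating rate.
* **Cross-wavelet coordination power.** Acceleration (second SG
  derivative) of each of six paired body parts (front head, chest,
  left/right shoulder, left/right arm; hands are excluded because hand
  motion is dictated by sound production) is reduced to its Euclidean
  norm, transformed with a complex Morlet continuous wavelet transform
  (centre frequency $\omega_0 = 6$), and the two musicians' coefficient
  matrices are
  multiplied element-wise (one conjugated). The modulus is the
  cross-wavelet power; the grid period (0.3–7 s, 20 suboctaves per octave)
  with the highest time-averaged power is the pair's *dominant period*,
  and the power row at that period, block-averaged to 10 Hz, is the
  coordination series.
* **Sound intensity.** RMS amplitude in rectangular 0.2 s windows hopping
  by 0.1 s (50 % overlap), i.e. a 10 Hz intensity envelope. A perceptual
  onset estimator reports the start of the first 10 ms window whose RMS
  reaches 70 % of the regional maximum.
* **Onset asynchrony.** At score-notated synchronization points, the
  signed asynchrony is onset(Secondo) − onset(Primo) in ms, positive when
  the Primo leads; for chords the latest onset within the chord per
  musician is used.

Sparse slider logs (a value is recorded only when the slider moves; the
handle starts at the scale center) are de-sparsified by previous-value
interpolation onto the same 10 Hz grid.

## The statistical models

The response model battery is a set of Gaussian linear mixed models fitted
by maximum likelihood via `nlme`: togetherness at time *t + lag* is
regressed on log-transformed predictors at *t*, with a participant random
intercept and first-order autoregressive (AR(1)) residual correlation
within every participant-by-stimulus time series. Predictors are
log-transformed because intensity, QoM and CWT power are strongly
right-skewed; the offset is `min(positive value) * 1e-3` per feature,
pooled across stimuli and recorded with the model table.

The response **lag** (candidates 1, 2, 3 s) is selected by 10-fold
cross-validation folded *by participants*: all trials of a held-out
participant group are predicted from the fixed effects of a model fitted
to the remaining participants (random intercepts of unseen participants
are set to their population mean of zero; the AR(1) structure does not
contribute to the marginal mean of an unseen series). The lag with the
lowest mean MAE and RMSE across folds wins; if the two measures disagree,
MAE decides, and exact ties break toward the shorter lag — a deterministic
rule is needed because the observed differences can be tiny.

The battery itself crosses presentation modality with listener group:
audio-only models use sound intensity; video-only models use total QoM
plus the six pair powers; audio-plus-video models use all of these. Each
is fitted separately for semi-professionals, novices, pianists and
clarinetists, and flagged at α = 0.0125 (Bonferroni over the four models
per modality). Local QoM per pair is *not* entered alongside the pair
powers: its variance inflation factors are high (the package's
`compute_vif()` reproduces this diagnosis), so total QoM is used, mirroring
the design the VIF analysis selects.

Synchronization models regress the rating observed at (sync reference +
selected lag) on the absolute asynchrony in ms, with a participant random
intercept, per modality with audible onsets (AO, AV) and per group. The
magnitude (not the signed value) is the default predictor: a single
negative slope then means "the smaller the asynchronies, the higher the
rated togetherness", which is the interpretable direction; a signed mode
is available (`predictor = "signed"`).

Mean-rating ANOVAs use type-II sums of squares on the (near-)balanced
participant × stimulus × modality design, with Tukey HSD contrasts.
Body-part comparisons fit series value ~ body part with a stimulus random
intercept and AR(1) residuals within each stimulus-by-part series, with
Tukey-adjusted pairwise contrasts via `emmeans`. Eye-gaze fixation
percentages (of tracked samples, per 1 s bin, averaged per
participant × stimulus × AOI with the final partial bin weighted by its
share of a full bin) feed a mixed model with crossed stimulus and
participant random intercepts via `lme4`.

## The synthetic-data generator

`sim_config()` defaults encode the study conditions the pipeline is
designed for: 30 participants (10 novices, 10 pianists, 10 clarinetists),
2 stimulus groups × 8 performances of ~47 s, mocap at 240 Hz, ratings at
10 Hz, 16 synchronization points per piece with points 11–14 realized as
chords, and a true response lag of 1 s.

**Motion.** Each body part oscillates at a part-specific base period
inside phrase-like episodes: a slow (12–18 s) smoothed gate switches the
movement on and off, emulating the alternation of vigorous coordinated
passages and near-still transitions in real performances. The coupling
parameter κ (default 0.7 per pair) controls duo alignment: at κ = 1 the
two musicians oscillate at the same period with synchronous phrases; as κ
falls their periods detune to opposite sides of the shared tempo (up to
~70 % apart) and their phrase gates shift apart in time. Position
amplitude is scaled by detune^1.5 so that the cross-wavelet response —
which sees acceleration (∝ 1/period²) with a √period analysis gain — is
period-invariant, keeping κ the only knob that moves coordination power.
Head amplitude and tempo are chosen so the head dominates both speed and
acceleration (head > arms > shoulders > chest), mirroring the body-part
profile the analysis is meant to resolve. Smooth low-pass noise (15 % of
part amplitude) is added. This generator makes no attempt at biomechanical
realism (no skeleton constraints, no posture), so passing tests speak to
the *signal-processing and statistical pipeline*, not to anatomical
validity.

**Onsets and intensity.** Primo onsets sit on a jittered expressive grid;
Secondo onsets add Normal(0, σ) noise, with σ set per stimulus group so
that the folded-normal mean |asynchrony| = σ√(2/π) matches the magnitudes
the pipeline should handle (piano σ = 159 ms → mean 127 ms; clarinet
σ = 172 ms → mean 137 ms). Because the generator is Normal, the implied SD
of |asynchrony| is σ√(1 − 2/π) ≈ 96–104 ms; real ensemble asynchronies are
heavier-tailed, so empirical SDs can exceed the mean — a known limitation
of the Normal model. The intensity envelope is a phrase-shaped dynamics
curve with exponentially decaying per-note pulses; an optional sine-tone
rendition supports audio round-trips.

**Ratings.** The latent togetherness trace is
`r(t) = 50 + b0_participant + Σ_j β_j (x_j(t − L) − mean(x_j)) + e(t)`,
where the x_j are the log features available in the trial's modality
(audio features in AO/AV, motion features in VO/AV), centering constants
are pooled across the whole study so between-stimulus differences carry
the effects too, b0 is a participant intercept (SD 5), and e is AR(1)
noise (ρ = 0.95, stationary SD 2.5 at 10 Hz). Group-specific β defaults
mirror the effect pattern the analysis should detect: novices weight
sound intensity (3.8 per log unit) and right-arm power (0.7);
semi-professionals weight chest power (0.5) and asynchrony (−0.005 per
ms). The trace is clipped to 0–100 and emitted as sparse events whenever
it drifts ≥ 2.5 rating units from the last emitted value. The triple
(ρ, noise SD, threshold) was calibrated once so that streams average
about one slider change per 1.1 s, the density continuous rating sliders
actually produce; `threshold = 0` emits a dense stream for estimator
studies. The slider dead-band attenuates small effects (by design — it is
a measurement model), so parameter-recovery checks that target the
*estimator* use the dense mode, while lag selection, significance patterns
and density checks run through the sparse slider.

## Numerical choices

* The Morlet CWT is computed in the frequency domain with the
  plain-Gaussian Morlet spectrum; the series mean is removed first, and
  zero-padding extends to the next power of two **beyond the widest
  wavelet's half-support (12 scales)** so the circular FFT correlation
  equals the linear one to machine precision (the test suite verifies
  < 1e-6 agreement against a direct time-domain convolution).
* The cone of influence is not masked; edge scales are therefore smoothed
  versions of interior values, consistent across stimuli.
* Dominant-period ties break toward the shorter period (periods ascend,
  the first maximum wins).
* `lme` fits use `niterEM = 10, tolerance = 1e-4`; against default
  tolerances the estimates agree to ~6 significant digits at half the
  cost, which matters in the cross-validation loops.
* Degenerate inputs fail loudly: constant predictors, single-level
  groups, all-zero cross matrices, and perfect collinearity (VIF = ∞) are
  reported, never silently dropped. Singular random-effect fits are
  flagged (`$singular`), not suppressed.
* Block-average resampling conserves the series mean exactly; a trailing
  partial block is dropped.

## Problem sizes used in validation

The validation suite runs the full design logic at reduced scale so every
stage executes in a desk-scale run: lag-selection checks use 10
participants × 2 stimuli × 15 s; fixed-effect recovery uses 100 replicates
of 6 participants × 4 stimuli × 20 s (with ρ = 0.5 and dense emission, the
estimator's own generative model); sign-recovery of the synchronization
slope uses 8 participants × 4 stimuli × 12 sync points; the qualitative
pattern study uses 16 participants × 4 stimuli × 25 s with mocap at 60 Hz.
These sizes were chosen once for adequate statistical power at the default
effect magnitudes; the generator defaults themselves stay at the
full-study conditions above.

## Known limitations

* Cross-wavelet **power** measures co-occurrence of amplitude at a common
  period; it is blind to relative phase. Coordination expressed purely as
  phase-locking at equal amplitude is invisible to this measure (wavelet
  coherence with significance testing, an explicit non-goal here, would be
  required).
* The Normal asynchrony model underestimates the tails of real ensemble
  timing.
* The AOI fixation module consumes already-labelled samples; fixation
  detection and AOI geometry are upstream concerns.
* The onset estimator assumes one attack per region and errors otherwise
  (`multiple = "earliest"` opts out).
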