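# duosync

Tools for analysing how an audience's continuous *togetherness* ratings of
duo music performances relate to objective coordination features of the
performers — for movement scientists, music psychologists and anyone
working with continuous-response paradigms over time-locked stimulus
features.

When two musicians play together, an audience can sense whether they are
"in the zone" with each other. duosync implements the full measurement
chain needed to study that judgement quantitatively:

* **Kinematics** — Savitzky–Golay smoothing/differentiation of
  motion-capture marker trajectories; total and local *quantity of motion*
  (QoM), the duo-averaged summed marker speed,
  `QoM(t) = mean_musician( sum_markers ||v_m(t)|| )`, resampled to 10 Hz.
* **Coordination** — complex Morlet cross-wavelet transform of paired
  body-part acceleration; for each pair the grid period in 0.3–7 s with
  maximal time-averaged cross power |W_xy| is its *dominant period*, and
  the power series at that period quantifies moment-to-moment coordination.
* **Audio features** — 10 Hz RMS intensity (rectangular window, 50 %
  overlap), perceptual onsets at 70 % of regional max RMS, and note/chord
  onset asynchronies, signed Secondo − Primo (positive = Primo leading).
* **Ratings** — de-sparsification of slider-event logs by previous-value
  interpolation, trial exclusion (partial loads, repeated presentations),
  and lag alignment of responses against features.
* **Statistics** — Gaussian linear mixed models with a participant random
  intercept and AR(1) residuals within each stimulus time series
  (`rating(t + L) ~ log features(t)`); response-lag selection by 10-fold
  cross-validation folded by participants (lowest MAE and RMSE); the
  modality × expertise model battery at Bonferroni α = 0.0125; VIF;
  synchronization models; type-II ANOVAs with Tukey HSD; body-part
  comparisons.
* **Eye-gaze** — AOI fixation percentages in 1 s bins and the fixation
  mixed model with crossed stimulus/participant random effects.
* **Synthetic data** — a generator producing complete studies (markers,
  note events, intensity, sparse slider logs, gaze samples) with known
  ground truth, so the entire pipeline is testable end to end.

## Worked example

Generate a miniature synthetic study, extract features, and fit the model
battery at the generator's true lag:

```r
library(duosync)

cfg <- sim_config(seed = 42, n_novices = 8, n_pianists = 4,
                  n_clarinetists = 4, n_stimuli = 2, duration = 25,
                  mocap_rate = 60, n_sync = 12, chord_sync = 9:12,
                  simulate_gaze = FALSE, include_repeats = FALSE)
generate_study(cfg, "study")
st <- read_study("study")

features <- lapply(st$recordings, extract_stimulus_features)
tables   <- build_model_tables(st, features, lag = 1)
battery  <- run_togetherness_models(tables, groups = c("a", "b"))

s <- battery$summary
s[s$significant & s$term != "(Intercept)",
  c("model", "group", "term", "estimate", "p")]
```

```
   model   group             term  estimate            p
2     1b  novice    log_intensity 3.0067060 0.000000e+00
8     2a semipro  log_power_chest 0.3073909 5.434583e-04
20    2b  novice  log_power_r_arm 0.4482350 3.575631e-26
31    3b  novice    log_intensity 2.9974378 0.000000e+00
38    3b  novice  log_power_r_arm 0.5654962 1.201243e-34
```

The generated ground truth gives novices a sound-intensity effect (3.8)
and a right-arm coordination effect (0.7), and semi-professionals a chest
coordination effect (0.5); the battery recovers exactly that pattern —
novices' ratings track loudness (models 1b, 3b) and right-arm cross-wavelet
power (2b, 3b), semi-professionals' track chest power (2a) — with estimates
attenuated somewhat by the slider's dead-band. The synchronization models
add the semi-professionals' sensitivity to onset asynchrony:

```r
sync <- run_sync_models(build_sync_table(st, 1), groups = "a")
sync$summary[sync$summary$term == "abs_ms",
             c("model", "group", "estimate", "p", "significant")]
```

```
  model   group     estimate           p significant
2    4a semipro -0.002281070 0.085443212       FALSE
4    5a semipro -0.003981469 0.003489940        TRUE
```

A slope of −0.004 per ms means a 100 ms larger absolute asynchrony costs
about 0.4 rating points on the 0–100 togetherness scale in the
audio-plus-video condition.

The response lag itself is selected, not assumed:

```r
res <- run_study_analysis(st, K = 5, seed = 1)
res$selected_lag   # 1 (the generator's true lag)
```

## Study bundle layout

`generate_study()` writes (and `read_study()` reads):

```
study/
  manifest.json                 # all true parameters + seed
  metadata/participants.csv     # participant, background, instrument
  metadata/stimuli.csv          # stimulus, stimulus_group, duration
  stimuli/<id>_markers.csv      # time + <marker>_{x,y,z} columns, mm
  stimuli/<id>_events.csv       # part, sync_index, onset_s, chord_group
  stimuli/<id>_intensity.csv    # t, rms at 10 Hz
  ratings/slider_events.csv     # sparse slider change log
  ratings/trials.csv            # full trial roster (incl. no-change trials)
  fixations/fixations.csv       # participant, stimulus, t, aoi
```

A thin command-line wrapper is installed at
`system.file("cli", "duosync.R", package = "duosync")` with subcommands
`simulate`, `features`, `lagcv` and `models`.

See the methods vignette (`vignettes/methods.Rmd`) for the models, the
generator's assumptions, and numerical choices.
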