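# Synthetic duo studies with known ground truth.
#
# The generator emulates the measured study design: 2 stimulus groups
# (piano, clarinet) x 8 performances x 3 presentation modalities x 30
# participants (10 novices, 10 pianists, 10 clarinetists). Duo motion is a
# mixture of a shared oscillation (coupling kappa per body-part pair) and
# idiosyncratic movement plus smooth noise; note onsets carry Normal
# asynchronies; ratings follow a lagged linear model on log features with
# AR(1) noise, emitted as sparse slider-change events.

#' Simulation configuration
#'
#' Defaults reproduce the measured study's conditions: sample sizes and
#' design (30 participants split 10/10/10, 2 x 8 stimuli, ~47 s at 240 Hz),
#' head-dominant movement amplitudes, asynchrony scale chosen so the mean
#' absolute asynchrony matches the reported values (piano 127 ms, clarinet
#' 137 ms: sigma = mean / sqrt(2/pi)), a 1-s true response lag, and
#' ground-truth effects mirroring the reported group-specific pattern
#' (novices weight sound intensity and right-arm coordination power;
#' semi-professionals weight chest power and asynchrony).
#'
#' @param seed master seed; a fixed seed reproduces the study bundle
#'   byte-identically.
#' @param n_novices,n_pianists,n_clarinetists participants per group.
#' @param n_stimuli stimuli per stimulus group.
#' @param duration stimulus length, s.
#' @param mocap_rate,rating_rate,audio_rate sampling rates, Hz.
#' @param modalities presentation modalities.
#' @param amplitude_mm movement amplitude per body part, mm (head largest).
#' @param base_period_s oscillation period per body part, s.
#' @param kappa coupling in \[0, 1\] per body part (scalar recycled).
#' @param noise_frac smooth-noise amplitude as a fraction of the part
#'   amplitude.
#' @param sigma_async_ms SD of note asynchronies per stimulus group, ms.
#' @param n_sync synchronization points per stimulus; `chord_sync` gives
#'   the indices realized as chords.
#' @param true_lag_s true response lag, s (one of 1, 2, 3).
#' @param rho,noise_sd AR(1) correlation and stationary SD of rating noise.
#' @param participant_sd SD of the participant random intercept on the
#'   latent rating level (rating units).
#' @param slider_threshold minimum rating change that moves the slider
#'   (rating units); 0 emits a dense stream.
#' @param beta named list of ground-truth effects per background
#'   (`novice`, `semipro`) on log-features (`intensity`, `qom`,
#'   `power_<part>`) and on `async` (per ms of absolute asynchrony).
#' @param include_repeats present 2 stimuli per group twice (second
#'   presentations are excluded from analysis, as in the study design).
#' @param simulate_gaze also generate AOI-labelled gaze samples for the
#'   video modalities.
#' @param gaze_rate,gaze_probs,gaze_dwell_s gaze sampling rate, AOI
#'   probabilities (S upper body most fixated) and mean fixation dwell.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_novices = 10, n_pianists = 10, n_clarinetists = 10,
                       n_stimuli = 8, duration = 47,
                       mocap_rate = 240, rating_rate = 10, audio_rate = 8000,
                       modalities = c("AO", "VO", "AV"),
                       amplitude_mm = c(head = 20, r_arm = 12, l_arm = 9,
                                        r_shoulder = 7, l_shoulder = 6,
                                        chest = 4, l_hand = 10, r_hand = 10,
                                        instrument = 5),
                       base_period_s = c(head = 0.9, chest = 2.8,
                                         l_shoulder = 1.8, r_shoulder = 1.6,
                                         l_arm = 1.3, r_arm = 1.1,
                                         l_hand = 0.5, r_hand = 0.45,
                                         instrument = 1.1),
                       kappa = 0.7, noise_frac = 0.15,
                       sigma_async_ms = c(piano = 159, clarinet = 172),
                       n_sync = 16, chord_sync = 11:14,
                       true_lag_s = 1, rho = 0.95, noise_sd = 2.5,
                       participant_sd = 5, slider_threshold = 2.5,
                       beta = list(novice = c(intensity = 3.8,
                                              power_r_arm = 0.7),
                                   semipro = c(power_chest = 0.5,
                                               async = -0.005)),
                       include_repeats = TRUE, simulate_gaze = TRUE,
                       gaze_rate = 60,
                       gaze_probs = c(S_UpperBody = 0.34, P_UpperBody = 0.28,
                                      Center = 0.16, S_Head = 0.10,
                                      P_Head = 0.07, none = 0.05),
                       gaze_dwell_s = 0.8) {
  parts <- coordination_parts()
  if (length(kappa) == 1L) kappa <- stats::setNames(rep(kappa, length(parts)), parts)
  stopifnot(all(kappa >= 0 & kappa <= 1), duration > max(base_period_s),
            true_lag_s %in% c(1, 2, 3))
  cfg <- list(seed = seed, n_novices = n_novices, n_pianists = n_pianists,
              n_clarinetists = n_clarinetists, n_stimuli = n_stimuli,
              duration = duration, mocap_rate = mocap_rate,
              rating_rate = rating_rate, audio_rate = audio_rate,
              modalities = modalities, amplitude_mm = amplitude_mm,
              base_period_s = base_period_s, kappa = kappa,
              noise_frac = noise_frac, sigma_async_ms = sigma_async_ms,
              n_sync = n_sync, chord_sync = chord_sync,
              true_lag_s = true_lag_s, rho = rho, noise_sd = noise_sd,
              participant_sd = participant_sd,
              slider_threshold = slider_threshold, beta = beta,
              include_repeats = include_repeats,
              simulate_gaze = simulate_gaze, gaze_rate = gaze_rate,
              gaze_probs = gaze_probs, gaze_dwell_s = gaze_dwell_s)
  structure(cfg, class = "sim_config")
}

#' Participant roster implied by a configuration
#'
#' @param cfg a [sim_config()].
#' @return data frame: `participant`, `background` (novice/semipro),
#'   `instrument` (pianist/clarinetist/none).
#' @export
sim_participants <- function(cfg) {
  n <- cfg$n_novices + cfg$n_pianists + cfg$n_clarinetists
  data.frame(
    participant = sprintf("p%02d", seq_len(n)),
    background = rep(c("novice", "semipro"),
                     c(cfg$n_novices, cfg$n_pianists + cfg$n_clarinetists)),
    instrument = rep(c("none", "pianist", "clarinetist"),
                     c(cfg$n_novices, cfg$n_pianists, cfg$n_clarinetists)))
}

smooth_noise <- function(n, rate, sd_target, cutoff_hz = 8) {
  k <- max(3L, round(rate / cutoff_hz))
  z <- stats::filter(stats::rnorm(n + 2L * k), rep(1 / k, k), sides = 2,
                     circular = TRUE)[(k + 1):(k + n)]
  z <- as.numeric(z)
  if (stats::sd(z) > 0) z <- z / stats::sd(z) * sd_target
  z
}

#' Simulate the motion of one duo performance
#'
#' Each body part oscillates at its base period inside episodic movement
#' bursts. The coupling `kappa` governs how much of this is shared across
#' the duo: at `kappa = 1` the partners oscillate at the same period with
#' synchronous bursts (identical motion up to amplitude scale when noise
#' is off); as `kappa` falls their periods detune and their bursts drift
#' apart, so common-period cross-wavelet power declines. Smooth low-pass
#' noise is added on top.
#'
#' @param cfg a [sim_config()].
#' @param stimulus_id identifier.
#' @param group `"piano"` or `"clarinet"` (clarinet recordings also carry
#'   instrument markers).
#' @param seed optional seed (defaults to continuing the current RNG
#'   stream).
#' @return a [duo_recording()].
#' @export
simulate_duo_motion <- function(cfg, stimulus_id, group = "piano", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rate <- cfg$mocap_rate
  n <- round(cfg$duration * rate)
  t <- (seq_len(n) - 1) / rate
  parts <- c(coordination_parts(), "l_hand", "r_hand",
             if (group == "clarinet") "instrument")
  rest <- list(P = c(-600, 0, 1200), S = c(600, 0, 1200))
  part_height <- c(head = 400, chest = 100, l_shoulder = 250, r_shoulder = 250,
                   l_arm = 0, r_arm = 0, l_hand = -150, r_hand = -150,
                   instrument = -100)
  trajectories <- list()
  # movement comes in phrase-like episodes: vigorous oscillation separated
  # by near-still gaps, gated by a smoothed slow square wave whose period
  # (12-18 s) lies below the coordination period grid. kappa controls duo
  # alignment: at kappa = 1 the partners oscillate at the same period with
  # synchronous phrases; as kappa falls their periods detune (up to ~70%)
  # and their phrase gates shift apart in time, so common-period
  # cross-wavelet power declines.
  phrase_gate <- function(T_phrase, offset, duty = 0.6, edge_s = 1.2,
                          floor = 0.08) {
    raw <- as.numeric(((t + offset) %% T_phrase) < duty * T_phrase)
    k <- max(3L, round(edge_s * rate))
    sm <- as.numeric(stats::filter(raw, rep(1 / k, k), sides = 2,
                                   circular = TRUE))
    floor + (1 - floor) * sm
  }
  for (p in parts) {
    A <- cfg$amplitude_mm[[p]]
    P0 <- cfg$base_period_s[[p]]
    kap <- if (p %in% names(cfg$kappa)) cfg$kappa[[p]] else 0
    T_phrase <- stats::runif(1, 12, 18)
    off0 <- stats::runif(1, 0, T_phrase)
    phi_osc <- stats::runif(1, 0, 2 * pi)
    dir3 <- c(1, 0.3, 0.2); dir3 <- dir3 / sqrt(sum(dir3^2))
    for (m in c("P", "S")) {
      amp <- A * ifelse(m == "P", 1, 0.9)
      # partners drift to opposite sides of the shared tempo as coupling
      # weakens (one rushes, one broadens)
      detune <- (1 + (1 - kap) * stats::runif(1, 0.25, 0.45))^
        (if (m == "P") 1 else -1)
      gate_lag <- (1 - kap) * stats::runif(1, 0.35, 0.5) * T_phrase
      osc_shift <- (1 - kap) * stats::runif(1, 0, 2 * pi)
      # position amplitude scales with detune^1.5: acceleration falls as
      # 1/period^2 while the wavelet response grows as sqrt(period), so
      # this keeps the cross-wavelet response period-invariant
      sig <- amp * detune^1.5 * phrase_gate(T_phrase, off0 + gate_lag) *
        sin(2 * pi * t / (P0 * detune) + phi_osc + osc_shift)
      if (cfg$noise_frac > 0) {
        sig <- sig + smooth_noise(n, rate, cfg$noise_frac * amp)
      }
      xyz <- outer(sig, dir3)
      base <- rest[[m]] + c(0, 0, part_height[[p]])
      xyz <- sweep(xyz, 2, base, `+`)
      id <- paste0(m, "_", p)
      trajectories[[id]] <- marker_trajectory(id, xyz, rate)
    }
  }
  duo_recording(stimulus_id, group, trajectories, duration = cfg$duration)
}

#' Simulate note events with Normal asynchronies
#'
#' Primo onsets fall on an expressive-timing grid (jittered intervals
#' spanning the stimulus); Secondo onsets equal Primo plus
#' `Normal(0, sigma_async)`. Sync points listed in `cfg$chord_sync` are
#' realized as chords of 2-3 near-simultaneous notes per part sharing a
#' `chord_group`.
#'
#' @param cfg a [sim_config()].
#' @param group stimulus group (selects `sigma_async_ms`).
#' @param seed optional seed.
#' @return note-event data frame (see [read_note_events()]).
#' @export
simulate_onsets <- function(cfg, group = "piano", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sigma <- cfg$sigma_async_ms[[group]] / 1000
  n <- cfg$n_sync
  gaps <- 0.35 + stats::rgamma(n, shape = 4, rate = 4)
  primo <- 1 + cumsum(gaps) / sum(gaps) * (cfg$duration - 3)
  # a performer's onsets at successive score events are ordered; redraw the
  # Secondo's timing jitter in the rare draws that would invert them
  for (try in 1:100) {
    rows <- list()
    for (i in seq_len(n)) {
      chord <- i %in% cfg$chord_sync
      cg <- if (chord) sprintf("c%02d", i) else NA_character_
      n_notes <- if (chord) sample(2:3, 1) else 1L
      p_on <- primo[i] - if (chord) c(sort(stats::runif(n_notes - 1, 0.01, 0.05),
                                           decreasing = TRUE), 0) else 0
      s_on <- p_on + stats::rnorm(n_notes, 0, sigma)
      rows[[i]] <- rbind(
        data.frame(part = "P", sync_index = i, onset_s = pmax(0, p_on),
                   chord_group = cg),
        data.frame(part = "S", sync_index = i, onset_s = pmax(0, s_on),
                   chord_group = cg))
    }
    df <- do.call(rbind, rows)
    s_ref <- tapply(df$onset_s[df$part == "S"], df$sync_index[df$part == "S"],
                    max)
    if (!is.unsorted(s_ref[order(as.numeric(names(s_ref)))])) break
  }
  validate_note_events(df)
}

#' Simulate a sound-intensity envelope (optionally rendered as audio)
#'
#' A smooth phrase-shaped dynamics curve modulates per-note amplitudes;
#' each note decays exponentially after its onset. The envelope is emitted
#' at the rating rate; with `render_audio = TRUE` a sine-tone rendition is
#' returned as well, for audio round-trips through [rms_envelope()].
#'
#' @param cfg a [sim_config()].
#' @param events note events (see [simulate_onsets()]).
#' @param seed optional seed.
#' @param render_audio also return `audio = list(samples, rate)`.
#' @return an [intensity_envelope()], or a list `(envelope, audio)` when
#'   rendering.
#' @export
simulate_intensity <- function(cfg, events, seed = NULL, render_audio = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  n10 <- round(cfg$duration * cfg$rating_rate)
  t10 <- (seq_len(n10) - 1) / cfg$rating_rate
  dyn <- function(tt) {
    pmax(0.08, 0.4 + 0.25 * sin(2 * pi * tt / (cfg$duration / 1.5) +
                                  stats::runif(1, 0, 2 * pi)) +
           0.15 * sin(2 * pi * tt / 7.3 + stats::runif(1, 0, 2 * pi)))
  }
  d10 <- dyn(t10)
  onsets <- sort(events$onset_s)
  last_on <- findInterval(t10, onsets)
  since <- ifelse(last_on == 0, Inf, t10 - onsets[pmax(last_on, 1L)])
  env <- d10 * (0.25 + 0.75 * exp(-since / 1.2))
  envelope <- intensity_envelope(env, cfg$rating_rate)
  if (!render_audio) return(envelope)
  fs <- cfg$audio_rate
  ta <- (seq_len(round(cfg$duration * fs)) - 1) / fs
  amp <- stats::approx(t10, env, xout = ta, rule = 2)$y
  carrier <- sin(2 * pi * 330 * ta)
  samples <- amp * carrier  # window RMS ~ amp / sqrt(2)
  list(envelope = envelope, audio = list(samples = pmin(1, pmax(-1, samples)),
                                         rate = fs))
}

# absolute-asynchrony step feature: |async| of the most recent sync point
async_step_feature <- function(events, duration, rate = 10) {
  asyn <- note_asynchronies(events)
  refs <- stats::aggregate(onset_s ~ sync_index, data = events, FUN = max)
  refs <- merge(refs, asyn, by = "sync_index")
  refs <- refs[order(refs$onset_s), ]
  n <- round(duration * rate)
  tg <- (seq_len(n) - 1) / rate
  # the feature becomes available at the rating sample nearest the
  # reference onset (grid resolution), matching the nearest-sample
  # convention used when responses are read back at reference + lag
  idx <- findInterval(tg + 0.5 / rate + 1e-9, refs$onset_s)
  ifelse(idx == 0, 0, refs$abs_ms[pmax(idx, 1L)])
}

#' Simulate a participant's slider-rating stream for one trial
#'
#' The latent togetherness trace is
#' `r(t) = 50 + sum_j beta_j (x_j(t - L) - mean(x_j)) + e(t)`
#' where the `x_j` are the log-transformed stimulus features available in
#' the trial's modality (audio features in AO/AV, motion features in
#' VO/AV), `L` is the true lag and `e` is AR(1) noise. The trace is clipped
#' to the slider bounds and emitted as sparse change events: the slider
#' moves whenever the latent value drifts at least `threshold` rating
#' units from the last emitted value.
#'
#' @param cfg a [sim_config()].
#' @param features data frame at the rating rate with column `t` and raw
#'   (not logged) feature columns `intensity`, `qom`, `power_<part>`,
#'   `abs_async`.
#' @param participant_id,background trial participant and their music
#'   background (`novice`/`semipro`; selects the ground-truth betas).
#' @param stimulus_id,modality trial stimulus and modality.
#' @param seed optional seed.
#' @param threshold overrides `cfg$slider_threshold` (0 = dense emission of
#'   every sample).
#' @param intercept_shift additive shift of the latent level for this
#'   trial's participant (their random intercept, drawn once per
#'   participant at study level with SD `cfg$participant_sd`).
#' @param centers,eps optional named numerics (by feature): study-wide
#'   centering constants for the (logged) features and log offsets. When a
#'   study is generated as a whole these are pooled across stimuli, so that
#'   between-stimulus feature differences carry the effect too; standalone
#'   calls default to per-stimulus values.
#' @return a [slider_stream()].
#' @export
simulate_ratings <- function(cfg, features, participant_id, background,
                             stimulus_id, modality, seed = NULL,
                             threshold = NULL, centers = NULL, eps = NULL,
                             intercept_shift = 0) {
  if (!is.null(seed)) set.seed(seed)
  threshold <- threshold %||% cfg$slider_threshold
  rate <- cfg$rating_rate
  n <- nrow(features)
  lag_steps <- as.integer(round(cfg$true_lag_s * rate))
  betas <- cfg$beta[[background]] %||% numeric(0)
  audio_ok <- modality %in% c("AO", "AV")
  video_ok <- modality %in% c("VO", "AV")
  latent <- rep(50 + intercept_shift, n)
  for (nm in names(betas)) {
    uses_audio <- nm %in% c("intensity", "async")
    if ((uses_audio && !audio_ok) || (!uses_audio && !video_ok)) next
    col <- if (nm == "async") "abs_async" else nm
    if (is.null(features[[col]])) next
    x <- if (nm == "async") {
      features[[col]]
    } else {
      as.numeric(log_offset(features[[col]], eps = eps[[nm]] %||% NULL))
    }
    x_lagged <- c(rep(x[1], lag_steps), x)[seq_len(n)]
    ctr <- centers[[nm]] %||% mean(x)
    latent <- latent + betas[[nm]] * (x_lagged - ctr)
  }
  if (cfg$noise_sd > 0) {
    innov_sd <- cfg$noise_sd * sqrt(1 - cfg$rho^2)
    e <- as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd), cfg$rho,
                                  method = "recursive",
                                  init = stats::rnorm(1, 0, cfg$noise_sd)))
    latent <- latent + e
  }
  latent <- pmin(100, pmax(0, latent))
  tg <- (seq_len(n) - 1) / rate
  if (threshold <= 0) {
    ev <- data.frame(t = tg[-1], value = latent[-1])
  } else {
    last <- 50
    keep <- logical(n)
    for (i in seq_len(n)) {
      if (abs(latent[i] - last) >= threshold) { keep[i] <- TRUE; last <- latent[i] }
    }
    ev <- data.frame(t = tg[keep], value = latent[keep])
  }
  slider_stream(participant_id, stimulus_id, modality, ev)
}

#' Simulate AOI-labelled gaze samples for one trial
#'
#' Gaze dwells on one AOI for an exponentially distributed duration, then
#' jumps to an AOI drawn from `cfg$gaze_probs` (upper body of the Secondo
#' most likely).
#'
#' @param cfg a [sim_config()].
#' @param participant_id,stimulus_id trial identifiers.
#' @param seed optional seed.
#' @return data frame: `participant`, `stimulus`, `t`, `aoi`.
#' @export
simulate_fixations <- function(cfg, participant_id, stimulus_id, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- round(cfg$duration * cfg$gaze_rate)
  tg <- (seq_len(n) - 1) / cfg$gaze_rate
  aoi <- character(0)
  while (length(aoi) < n) {
    dwell <- max(1L, round(stats::rexp(1, 1 / cfg$gaze_dwell_s) * cfg$gaze_rate))
    lab <- sample(names(cfg$gaze_probs), 1, prob = cfg$gaze_probs)
    aoi <- c(aoi, rep(lab, dwell))
  }
  data.frame(participant = participant_id, stimulus = stimulus_id,
             t = tg, aoi = aoi[seq_len(n)])
}
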