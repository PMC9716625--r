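# Shared fixtures, all built in code.

# a small duo recording with sinusoidal markers (deterministic, no RNG)
toy_recording <- function(parts = c("head", "chest"), rate = 60, duration = 10,
                          amp = c(head = 10, chest = 5), group = "piano") {
  n <- round(duration * rate)
  t <- (seq_len(n) - 1) / rate
  traj <- list()
  for (p in parts) {
    for (m in c("P", "S")) {
      a <- amp[[p]] * if (m == "P") 1 else 0.9
      sig <- a * sin(2 * pi * t / 1.3 + match(p, parts))
      xyz <- cbind(sig, 0.3 * sig, 1000 + 0.1 * sig)
      id <- paste0(m, "_", p)
      traj[[id]] <- marker_trajectory(id, xyz, rate)
    }
  }
  duo_recording("toy", group, traj, duration = duration)
}

# note-event table with known asynchronies (ms), one sync point each
events_from_asynchronies <- function(async_ms, t0 = 2, gap = 2.5) {
  n <- length(async_ms)
  p_on <- t0 + gap * (seq_len(n) - 1)
  rbind(data.frame(part = "P", sync_index = seq_len(n), onset_s = p_on,
                   chord_group = NA_character_),
        data.frame(part = "S", sync_index = seq_len(n),
                   onset_s = p_on + async_ms / 1000,
                   chord_group = NA_character_))
}

# intensity/asynchrony feature tables for an audio-only synthetic study
# (no motion capture), using the generator's own operations
make_ao_features <- function(cfg, n_stimuli, feature_seed = 1) {
  set.seed(feature_seed)
  events <- list()
  feats <- lapply(seq_len(n_stimuli), function(i) {
    ev <- simulate_onsets(cfg, "piano")
    events[[i]] <<- ev
    env <- simulate_intensity(cfg, ev)
    n <- length(env$values)
    data.frame(t = (seq_len(n) - 1) / cfg$rating_rate,
               intensity = env$values,
               abs_async = duosync:::async_step_feature(ev, n / cfg$rating_rate,
                                                        cfg$rating_rate))
  })
  names(feats) <- sprintf("st%02d", seq_len(n_stimuli))
  names(events) <- names(feats)
  pooled <- unlist(lapply(feats, `[[`, "intensity"))
  lg <- log_offset(pooled)
  list(features = feats, events = events,
       eps = list(intensity = attr(lg, "eps")),
       centers = list(intensity = mean(lg),
                      async = mean(unlist(lapply(feats, `[[`, "abs_async")))))
}

# draw one rating stream per participant x stimulus and align the same
# streams at every candidate lag; returns named list of model tables
make_ao_tables <- function(cfg, fx, n_participants, rating_seed = 2,
                           lags = c(1, 2, 3), threshold = NULL) {
  logged <- lapply(fx$features, function(f) {
    data.frame(t = f$t,
               log_intensity = as.numeric(log_offset(f$intensity,
                                                     fx$eps$intensity)))
  })
  set.seed(rating_seed)
  participants <- sprintf("p%02d", seq_len(n_participants))
  pint <- rnorm(n_participants, 0, cfg$participant_sd)
  series_list <- list()
  for (pi in seq_along(participants)) {
    for (sid in names(fx$features)) {
      f <- fx$features[[sid]]
      s <- simulate_ratings(cfg, f, participants[pi], "novice", sid, "AO",
                            centers = fx$centers, eps = fx$eps,
                            intercept_shift = pint[pi], threshold = threshold)
      series_list[[paste(pi, sid)]] <- list(
        series = densify(s, nrow(f) / cfg$rating_rate), sid = sid)
    }
  }
  tables <- lapply(lags, function(L) {
    do.call(rbind, lapply(series_list, function(s) {
      lag_align(s$series, logged[[s$sid]], L)
    }))
  })
  names(tables) <- as.character(lags)
  tables
}
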