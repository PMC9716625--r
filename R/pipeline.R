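# End-to-end pipeline: study bundle generation and reading, 10 Hz feature
# extraction, model-table assembly, lag selection and the model battery.

#' Extract the 10 Hz feature table of one stimulus
#'
#' Computes sound intensity (RMS envelope), total QoM, the six body-part
#' cross-wavelet power series at their dominant periods, and the
#' absolute-asynchrony step feature, all aligned on the 10 Hz grid
#' (t = 0.0, 0.1, ...) and truncated to a common length.
#'
#' @param rec a [duo_recording()] (uses `rec$intensity` if present, else
#'   computes it from `rec$audio`).
#' @param grid a [period_grid()] for the wavelet analysis.
#' @param out_rate feature rate, Hz.
#' @param window,polyorder Savitzky-Golay settings.
#' @return data frame: `t`, `intensity`, `qom`, `power_<part>` x 6,
#'   `abs_async` (0 when no note events). Dominant periods are attached as
#'   attribute `"dominant_periods"`.
#' @export
extract_stimulus_features <- function(rec, grid = period_grid(), out_rate = 10,
                                      window = 25L, polyorder = 2L) {
  cols <- list()
  if (!is.null(rec$intensity)) {
    cols$intensity <- rec$intensity$values
  } else if (!is.null(rec$audio)) {
    cols$intensity <- rms_envelope(rec$audio, out_rate = out_rate)$values
  }
  dps <- c()
  if (length(rec$trajectories)) {
    cols$qom <- quantity_of_motion(rec, "total", out_rate = out_rate,
                                   window = window, polyorder = polyorder)$values
    for (p in coordination_parts()) {
      cs <- coordination_series(rec, p, grid, out_rate, window = window,
                                polyorder = polyorder)
      cols[[paste0("power_", p)]] <- cs$power
      dps[p] <- cs$dominant_period
    }
  }
  if (!length(cols)) stop_ds("recording has neither motion nor audio/intensity")
  n <- min(vapply(cols, length, integer(1)), round(rec$duration * out_rate))
  out <- data.frame(t = (seq_len(n) - 1) / out_rate)
  for (nm in names(cols)) out[[nm]] <- cols[[nm]][seq_len(n)]
  out$abs_async <- if (!is.null(rec$note_events) && nrow(rec$note_events)) {
    async_step_feature(rec$note_events, n / out_rate, out_rate)[seq_len(n)]
  } else 0
  attr(out, "dominant_periods") <- dps
  out
}

#' Generate a synthetic study bundle on disk
#'
#' Writes a complete, analysable study: marker trajectories, note events
#' and intensity envelopes per stimulus, slider-event logs for every
#' participant x stimulus x modality trial (ratings generated from the
#' extracted features of the simulated motion, so recovery analyses target
#' exactly what the pipeline measures), gaze samples, participant metadata
#' and a ground-truth manifest holding every true parameter and the seed.
#' Given the same configuration, output is byte-identical across runs.
#'
#' @param cfg a [sim_config()].
#' @param dir target directory; must not exist unless `force`.
#' @param force overwrite an existing directory.
#' @return `dir`, invisibly; the manifest is at `<dir>/manifest.json`.
#' @export
generate_study <- function(cfg, dir, force = FALSE) {
  if (dir.exists(dir)) {
    if (!force) stop_ds("directory exists (use force = TRUE): ", dir)
    unlink(dir, recursive = TRUE)
  }
  for (d in c("metadata", "stimuli", "ratings", "fixations")) {
    dir.create(file.path(dir, d), recursive = TRUE)
  }
  set.seed(cfg$seed)
  participants <- sim_participants(cfg)
  utils::write.csv(participants, file.path(dir, "metadata", "participants.csv"),
                   row.names = FALSE, quote = FALSE)
  groups <- c("piano", "clarinet")
  stim <- expand.grid(idx = seq_len(cfg$n_stimuli), group = groups,
                      stringsAsFactors = FALSE)
  stim$stimulus <- sprintf("%s%02d", substr(stim$group, 1, 2), stim$idx)
  utils::write.csv(data.frame(stimulus = stim$stimulus,
                              stimulus_group = stim$group,
                              duration = cfg$duration),
                   file.path(dir, "metadata", "stimuli.csv"),
                   row.names = FALSE, quote = FALSE)

  features <- list()
  for (i in seq_len(nrow(stim))) {
    sid <- stim$stimulus[i]
    rec <- simulate_duo_motion(cfg, sid, stim$group[i])
    events <- simulate_onsets(cfg, stim$group[i])
    env <- simulate_intensity(cfg, events)
    rec$note_events <- events
    rec$intensity <- env
    write_marker_trajectories(rec$trajectories,
                              file.path(dir, "stimuli", paste0(sid, "_markers.csv")))
    write_note_events(events,
                      file.path(dir, "stimuli", paste0(sid, "_events.csv")))
    utils::write.csv(
      format(data.frame(t = (seq_along(env$values) - 1) / env$rate,
                        rms = env$values),
             digits = 17, trim = TRUE, scientific = FALSE),
      file.path(dir, "stimuli", paste0(sid, "_intensity.csv")),
      row.names = FALSE, quote = FALSE)
    features[[sid]] <- extract_stimulus_features(rec)
  }

  # study-wide log offsets and centers so between-stimulus differences in
  # the features carry the ground-truth effects as well
  feat_names <- unique(unlist(lapply(cfg$beta, names)))
  eps <- list(); centers <- list()
  for (nm in setdiff(feat_names, "async")) {
    pooled <- unlist(lapply(features, `[[`, nm), use.names = FALSE)
    if (is.null(pooled)) next
    lg <- log_offset(pooled)
    eps[[nm]] <- attr(lg, "eps")
    centers[[nm]] <- mean(lg)
  }
  if ("async" %in% feat_names) {
    centers$async <- mean(unlist(lapply(features, `[[`, "abs_async")))
  }

  # repeated presentations: first 2 stimuli of each group shown twice
  repeats <- if (cfg$include_repeats) {
    stim$stimulus[stim$idx <= 2]
  } else character(0)

  streams <- list()
  gaze_rows <- list()
  p_intercepts <- stats::rnorm(nrow(participants), 0, cfg$participant_sd)
  for (pi in seq_len(nrow(participants))) {
    p <- participants$participant[pi]
    bg <- participants$background[pi]
    for (sid in stim$stimulus) {
      for (mod in cfg$modalities) {
        pres <- c(1L, if (sid %in% repeats && mod == cfg$modalities[1]) 2L)
        for (pr in pres) {
          s <- simulate_ratings(cfg, features[[sid]], p, bg, sid, mod,
                                centers = centers, eps = eps,
                                intercept_shift = p_intercepts[pi])
          s$presentation <- pr
          streams[[length(streams) + 1L]] <- s
        }
      }
      if (cfg$simulate_gaze) {
        gaze_rows[[length(gaze_rows) + 1L]] <- simulate_fixations(cfg, p, sid)
      }
    }
  }
  write_slider_events(streams, file.path(dir, "ratings", "slider_events.csv"))
  trial_rows <- do.call(rbind, lapply(streams, function(s) {
    data.frame(participant = s$participant_id, stimulus = s$stimulus_id,
               modality = s$modality, presentation = s$presentation)
  }))
  utils::write.csv(trial_rows, file.path(dir, "ratings", "trials.csv"),
                   row.names = FALSE, quote = FALSE)
  if (length(gaze_rows)) {
    utils::write.csv(
      format(do.call(rbind, gaze_rows), digits = 10, trim = TRUE,
             scientific = FALSE),
      file.path(dir, "fixations", "fixations.csv"),
      row.names = FALSE, quote = FALSE)
  }
  manifest <- list(generator = "duosync", seed = cfg$seed,
                   design = list(n_participants = nrow(participants),
                                 n_stimuli_per_group = cfg$n_stimuli,
                                 stimulus_groups = groups,
                                 modalities = cfg$modalities,
                                 duration_s = cfg$duration,
                                 mocap_rate_hz = cfg$mocap_rate,
                                 rating_rate_hz = cfg$rating_rate,
                                 repeats = repeats),
                   truth = list(true_lag_s = cfg$true_lag_s, beta = cfg$beta,
                                rho = cfg$rho, noise_sd = cfg$noise_sd,
                                participant_sd = cfg$participant_sd,
                                kappa = as.list(cfg$kappa),
                                sigma_async_ms = as.list(cfg$sigma_async_ms),
                                amplitude_mm = as.list(cfg$amplitude_mm),
                                base_period_s = as.list(cfg$base_period_s),
                                slider_threshold = cfg$slider_threshold))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a study bundle from disk
#'
#' @param dir directory written by [generate_study()] (or hand-assembled in
#'   the same layout).
#' @param read_markers also load marker trajectories (the expensive part).
#' @return list: `manifest`, `participants`, `stimuli` (metadata),
#'   `recordings` (named list of [duo_recording()]), `streams` (slider
#'   streams), `fixations` (data frame or NULL).
#' @export
read_study <- function(dir, read_markers = TRUE) {
  manifest_path <- file.path(dir, "manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  } else NULL
  participants <- utils::read.csv(file.path(dir, "metadata", "participants.csv"))
  stimuli <- utils::read.csv(file.path(dir, "metadata", "stimuli.csv"))
  rate <- manifest$design$mocap_rate_hz %||% 240
  recordings <- list()
  for (i in seq_len(nrow(stimuli))) {
    sid <- stimuli$stimulus[i]
    traj <- if (read_markers) {
      read_marker_trajectories(file.path(dir, "stimuli", paste0(sid, "_markers.csv")),
                               rate = rate)
    } else list()
    events <- read_note_events(file.path(dir, "stimuli", paste0(sid, "_events.csv")))
    intens <- utils::read.csv(file.path(dir, "stimuli", paste0(sid, "_intensity.csv")))
    recordings[[sid]] <- duo_recording(
      sid, stimuli$stimulus_group[i], traj, note_events = events,
      intensity = intensity_envelope(intens$rms, rate = 1 / diff(intens$t[1:2])),
      duration = stimuli$duration[i])
  }
  streams <- read_slider_events(file.path(dir, "ratings", "slider_events.csv"),
                                trials = file.path(dir, "ratings", "trials.csv"))
  fx_path <- file.path(dir, "fixations", "fixations.csv")
  fixations <- if (file.exists(fx_path)) utils::read.csv(fx_path) else NULL
  list(manifest = manifest, participants = participants, stimuli = stimuli,
       recordings = recordings, streams = streams, fixations = fixations)
}

#' Assemble lag-aligned model tables for each modality
#'
#' De-sparsifies every retained trial, log-transforms the predictors (with
#' a shared data-driven offset per feature, recorded in the result), and
#' lag-aligns responses against the stimulus features.
#'
#' @param study list as returned by [read_study()].
#' @param features named list of feature tables per stimulus (from
#'   [extract_stimulus_features()]).
#' @param lag response lag, s.
#' @param modalities modalities to assemble.
#' @return named list of model tables (one per modality), each with
#'   attribute `"eps"` (log offsets used).
#' @export
build_model_tables <- function(study, features, lag,
                               modalities = c("AO", "VO", "AV")) {
  kept <- exclude_trials(study$streams)
  streams <- kept$streams
  feat_cols <- setdiff(names(features[[1]]), c("t", "abs_async"))
  eps <- vapply(feat_cols, function(fc) {
    pooled <- unlist(lapply(features, function(f) f[[fc]]), use.names = FALSE)
    attr(log_offset(pooled), "eps")
  }, numeric(1))
  logged <- lapply(features, function(f) {
    out <- data.frame(t = f$t)
    for (fc in feat_cols) {
      out[[paste0("log_", fc)]] <- as.numeric(log_offset(f[[fc]], eps[[fc]]))
    }
    out
  })
  meta <- study$participants
  smeta <- study$stimuli
  out <- lapply(modalities, function(mod) {
    rows <- lapply(streams, function(s) {
      if (s$modality != mod) return(NULL)
      f <- logged[[s$stimulus_id]]
      if (is.null(f)) return(NULL)
      series <- densify(s, duration = nrow(f) / 10)
      lag_align(series, f, lag)
    })
    tab <- do.call(rbind, rows)
    if (is.null(tab)) stop_ds("no trials for modality ", mod)
    tab$background <- meta$background[match(tab$participant, meta$participant)]
    tab$instrument <- meta$instrument[match(tab$participant, meta$participant)]
    tab$stimulus_group <- smeta$stimulus_group[match(tab$stimulus, smeta$stimulus)]
    attr(tab, "eps") <- eps
    tab
  })
  stats::setNames(out, modalities)
}

#' Assemble the per-sync-point response table for the synchronization models
#'
#' @param study list as returned by [read_study()].
#' @param lag selected response lag, s.
#' @param modalities modalities with audible onsets (default AO and AV).
#' @return data frame consumable by [run_sync_models()].
#' @export
build_sync_table <- function(study, lag, modalities = c("AO", "AV")) {
  kept <- exclude_trials(study$streams)$streams
  meta <- study$participants
  rows <- lapply(kept, function(s) {
    if (!s$modality %in% modalities) return(NULL)
    rec <- study$recordings[[s$stimulus_id]]
    if (is.null(rec$note_events) || !nrow(rec$note_events)) return(NULL)
    series <- densify(s, duration = rec$duration)
    resp <- sync_reference_ratings(series, rec$note_events, lag)
    asyn <- note_asynchronies(rec$note_events)
    m <- merge(resp, asyn, by = "sync_index")
    data.frame(participant = s$participant_id, stimulus = s$stimulus_id,
               modality = s$modality, sync_index = m$sync_index,
               t_ref = m$t_ref, asynchrony_ms = m$asynchrony_ms,
               abs_ms = m$abs_ms, rating = m$value)
  })
  tab <- do.call(rbind, rows)
  tab$background <- meta$background[match(tab$participant, meta$participant)]
  tab$instrument <- meta$instrument[match(tab$participant, meta$participant)]
  tab
}

#' Per-trial mean ratings for the factorial ANOVAs
#'
#' @param study list as returned by [read_study()].
#' @return data frame: one mean rating per participant x stimulus x
#'   modality, with background, instrument and stimulus-group columns.
#' @export
mean_rating_table <- function(study) {
  kept <- exclude_trials(study$streams)$streams
  meta <- study$participants
  smeta <- study$stimuli
  rows <- lapply(kept, function(s) {
    dur <- smeta$duration[match(s$stimulus_id, smeta$stimulus)]
    data.frame(participant = s$participant_id, stimulus = s$stimulus_id,
               modality = s$modality,
               mean_rating = mean(densify(s, dur)$values))
  })
  tab <- do.call(rbind, rows)
  tab$background <- meta$background[match(tab$participant, meta$participant)]
  tab$instrument <- meta$instrument[match(tab$participant, meta$participant)]
  tab$stimulus_group <- smeta$stimulus_group[match(tab$stimulus, smeta$stimulus)]
  tab
}

#' Run the full togetherness analysis on a study bundle
#'
#' Extracts features, selects the response lag by participant-folded
#' 10-fold cross-validation over lags 1-3 s per modality (overall lag =
#' majority vote, ties toward the shorter lag), then fits the model
#' battery, the synchronization models, the two factorial ANOVAs and
#' (when gaze data are present) the fixation model.
#'
#' @param study a study list from [read_study()], or a bundle directory.
#' @param lags candidate lags, s.
#' @param K CV folds.
#' @param seed seed for the CV fold assignment.
#' @param grid [period_grid()] for the wavelet analysis.
#' @param cv_modalities modalities entered in the lag CV (default: all
#'   available).
#' @param groups battery participant groups to fit.
#' @return list: `features`, `cv` (per modality), `selected_lag`, `tables`,
#'   `battery`, `sync_models`, `anova_background`, `anova_expertise`,
#'   `fixation_model`, `asynchrony_summary` (per stimulus group),
#'   `exclusions`.
#' @export
run_study_analysis <- function(study, lags = c(1, 2, 3), K = 10, seed = 1,
                               grid = period_grid(),
                               cv_modalities = NULL,
                               groups = c("a", "b", "c", "d")) {
  if (is.character(study)) study <- read_study(study)
  features <- lapply(study$recordings, extract_stimulus_features, grid = grid)
  cv_modalities <- cv_modalities %||% intersect(c("AO", "VO", "AV"),
                                                unique(vapply(study$streams,
                                                              function(s) s$modality,
                                                              character(1))))
  tables_by_lag <- lapply(lags, function(L) {
    build_model_tables(study, features, L, modalities = cv_modalities)
  })
  names(tables_by_lag) <- as.character(lags)
  cv <- lapply(cv_modalities, function(mod) {
    tabs <- lapply(tables_by_lag, `[[`, mod)
    lag_crossvalidation(tabs, K = K, seed = seed)
  })
  names(cv) <- cv_modalities
  picks <- vapply(cv, function(x) x$selected_lag, numeric(1))
  counts <- table(picks)
  selected_lag <- min(as.numeric(names(counts)[counts == max(counts)]))
  tables <- tables_by_lag[[as.character(selected_lag)]]
  battery <- run_togetherness_models(tables, groups = groups)
  sync_tab <- tryCatch(build_sync_table(study, selected_lag),
                       error = function(e) NULL)
  sync_models <- if (!is.null(sync_tab) && nrow(sync_tab)) {
    run_sync_models(sync_tab, groups = groups)
  } else NULL
  means <- mean_rating_table(study)
  anova_background <- anova_mean_ratings(
    means, c("background", "modality", "stimulus_group"))
  anova_expertise <- if (any(means$instrument %in% c("pianist", "clarinetist"))) {
    anova_mean_ratings(means[means$instrument != "none", ],
                       c("instrument", "modality", "stimulus_group"))
  } else NULL
  asummary <- lapply(split(study$stimuli$stimulus, study$stimuli$stimulus_group),
                     function(sids) {
    recs <- lapply(study$recordings[sids], function(r) {
      if (is.null(r$note_events) || !nrow(r$note_events)) NULL else
        note_asynchronies(r$note_events)
    })
    recs <- recs[!vapply(recs, is.null, logical(1))]
    if (!length(recs)) return(NULL)
    summarize_asynchrony(do.call(rbind, recs))
  })
  fixation_model <- if (!is.null(study$fixations)) {
    pct <- fixation_percentages(study$fixations)
    pct$training <- study$participants$background[
      match(pct$participant, study$participants$participant)]
    fit_fixation_model(pct)
  } else NULL
  list(features = features, cv = cv, selected_lag = selected_lag,
       tables = tables, battery = battery, sync_models = sync_models,
       anova_background = anova_background, anova_expertise = anova_expertise,
       fixation_model = fixation_model, asynchrony_summary = asummary,
       exclusions = exclude_trials(study$streams)$report)
}
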