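# Domain types and on-disk formats.
#
# Marker naming convention: "<P|S>_<part>" where P = Primo, S = Secondo and
# part is one of head, chest, l_shoulder, r_shoulder, l_arm, r_arm, l_hand,
# r_hand, instrument. Time columns are seconds (decimal floats); marker
# coordinates are millimetres (OptiTrack convention).

#' Body parts used in the coordination analysis
#'
#' The six paired body parts whose acceleration is cross-wavelet analysed:
#' chest, front head, left/right shoulder and left/right arm. Hands are
#' excluded because hand motion is dictated by sound production.
#' @export
coordination_parts <- function() {
  c("head", "chest", "l_shoulder", "r_shoulder", "l_arm", "r_arm")
}

all_parts <- function() {
  c(coordination_parts(), "l_hand", "r_hand")
}

#' Construct a marker trajectory
#'
#' @param marker_id label such as `"P_head"`; prefix `P`/`S` encodes the
#'   musician, the rest the body part or instrument.
#' @param xyz numeric matrix (n x 3) of positions in mm, uniformly sampled.
#' @param rate sampling rate in Hz (the study recorded at 240 Hz).
#' @return object of class `marker_trajectory`.
#' @export
marker_trajectory <- function(marker_id, xyz, rate) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L) stop_ds("xyz must have 3 columns")
  if (rate <= 0) stop_ds("rate must be positive")
  if (any(!is.finite(xyz))) stop_ds("non-finite coordinates in marker ", marker_id)
  structure(list(marker_id = marker_id, xyz = xyz, rate = rate),
            class = "marker_trajectory")
}

#' @export
print.marker_trajectory <- function(x, ...) {
  cat("<marker_trajectory> ", x$marker_id, ": ", nrow(x$xyz), " samples @ ",
      x$rate, " Hz\n", sep = "")
  invisible(x)
}

marker_musician <- function(marker_id) substr(marker_id, 1, 1)
marker_part <- function(marker_id) substring(marker_id, 3)

#' Construct a duo recording
#'
#' Bundles everything known about one stimulus: paired marker trajectories of
#' the two musicians (Primo and Secondo), optional instrument markers, note
#' events at the score-notated synchronization points, and audio or a
#' precomputed intensity envelope.
#'
#' @param stimulus_id identifier.
#' @param stimulus_group `"piano"` or `"clarinet"`.
#' @param trajectories named list of [marker_trajectory()] objects (names are
#'   marker ids); may be empty for audio-only material.
#' @param note_events data frame as returned by [read_note_events()], or NULL.
#' @param audio list(samples, rate) or NULL.
#' @param intensity an `intensity_envelope` (see [rms_envelope()]) or NULL.
#' @param duration seconds; inferred from trajectories if missing.
#' @return object of class `duo_recording`.
#' @export
duo_recording <- function(stimulus_id, stimulus_group = c("piano", "clarinet"),
                          trajectories = list(), note_events = NULL,
                          audio = NULL, intensity = NULL, duration = NULL) {
  stimulus_group <- match.arg(stimulus_group)
  if (length(trajectories)) {
    rates <- vapply(trajectories, function(tr) tr$rate, numeric(1))
    lens <- vapply(trajectories, function(tr) nrow(tr$xyz), numeric(1))
    if (length(unique(rates)) != 1L) stop_ds("all trajectories must share one rate")
    if (length(unique(lens)) != 1L) stop_ds("all trajectories must share one duration")
    mus <- vapply(names(trajectories), marker_musician, character(1))
    if (!all(c("P", "S") %in% mus)) stop_ds("both musicians (P and S) must be present")
    if (is.null(duration)) duration <- lens[[1]] / rates[[1]]
    rate <- rates[[1]]
  } else {
    rate <- NA_real_
    if (is.null(duration)) stop_ds("duration required when no trajectories given")
  }
  structure(list(stimulus_id = stimulus_id, stimulus_group = stimulus_group,
                 trajectories = trajectories, note_events = note_events,
                 audio = audio, intensity = intensity,
                 rate = rate, duration = duration),
            class = "duo_recording")
}

#' @export
print.duo_recording <- function(x, ...) {
  cat("<duo_recording> ", x$stimulus_id, " (", x$stimulus_group, "), ",
      round(x$duration, 2), " s, ", length(x$trajectories), " markers",
      if (!is.na(x$rate)) paste0(" @ ", x$rate, " Hz"), "\n", sep = "")
  invisible(x)
}

# ---- marker trajectories --------------------------------------------------

#' Read marker trajectories from a CSV/TSV file
#'
#' Expects a header row with a `time` column (seconds) followed by
#' `<marker>_x`, `<marker>_y`, `<marker>_z` triples in mm. Runs of missing
#' samples up to `max_gap` frames are linearly interpolated; longer gaps are
#' an error (occlusions that long cannot be reconstructed credibly).
#'
#' @param path CSV (or TSV) file.
#' @param rate expected sampling rate in Hz.
#' @param max_gap longest interpolatable run of missing samples, in frames
#'   (default 12, i.e. 50 ms at 240 Hz).
#' @param grid_tol tolerance on time-grid uniformity, as a fraction of the
#'   sample interval.
#' @return named list of [marker_trajectory()] objects.
#' @export
read_marker_trajectories <- function(path, rate, max_gap = 12L, grid_tol = 0.01) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  if (!"time" %in% names(df)) stop_ds("missing 'time' column in ", path)
  tt <- df$time
  dt <- 1 / rate
  if (length(tt) < 2L) stop_ds("fewer than 2 samples in ", path)
  if (max(abs(diff(tt) - dt)) > grid_tol * dt) {
    stop_ds("non-uniform time grid in ", path, " (expected ", rate, " Hz)")
  }
  cols <- setdiff(names(df), "time")
  m <- regmatches(cols, regexec("^(.*)_([xyz])$", cols))
  ok <- lengths(m) == 3L
  if (!all(ok)) stop_ds("columns not in <marker>_{x,y,z} form: ",
                        paste(cols[!ok], collapse = ", "))
  ids <- unique(vapply(m, `[`, character(1), 2))
  out <- list()
  for (id in ids) {
    need <- paste0(id, "_", c("x", "y", "z"))
    if (!all(need %in% cols)) stop_ds("incomplete x/y/z triple for marker ", id)
    xyz <- as.matrix(df[, need])
    if (all(!is.finite(xyz))) stop_ds("all-NaN marker ", id)
    xyz <- apply(xyz, 2, fill_gaps, max_gap = max_gap, id = id)
    colnames(xyz) <- c("x", "y", "z")
    out[[id]] <- marker_trajectory(id, xyz, rate)
  }
  out
}

fill_gaps <- function(v, max_gap, id) {
  bad <- !is.finite(v)
  if (!any(bad)) return(v)
  r <- rle(bad)
  runs <- r$lengths[r$values]
  ends <- cumsum(r$lengths)
  if (bad[1] || bad[length(v)]) stop_ds("gap too long in marker ", id,
                                        " (missing data at series edge)")
  if (any(runs > max_gap)) {
    stop_ds("gap too long in marker ", id, " (", max(runs),
            " > max_gap = ", max_gap, " samples)")
  }
  idx <- seq_along(v)
  stats::approx(idx[!bad], v[!bad], xout = idx)$y
}

#' Write marker trajectories to CSV
#'
#' Inverse of [read_marker_trajectories()]; values round-trip to double
#' precision (times are regenerated from the rate).
#'
#' @param trajectories named list of [marker_trajectory()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_marker_trajectories <- function(trajectories, path) {
  n <- nrow(trajectories[[1]]$xyz)
  rate <- trajectories[[1]]$rate
  df <- data.frame(time = (seq_len(n) - 1) / rate)
  for (tr in trajectories) {
    df[[paste0(tr$marker_id, "_x")]] <- tr$xyz[, 1]
    df[[paste0(tr$marker_id, "_y")]] <- tr$xyz[, 2]
    df[[paste0(tr$marker_id, "_z")]] <- tr$xyz[, 3]
  }
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- note events ----------------------------------------------------------

#' Read note events (score-notated synchronization points)
#'
#' From CSV with columns `part` (P/S), `sync_index`, `onset_s` and optional
#' `chord_group`, or from a Standard MIDI File via [read_note_events_midi()].
#' Each `sync_index` must appear in both parts; chord members share a
#' `chord_group`.
#'
#' @param path CSV file, or `.mid` file (then `sync_table` is required).
#' @param sync_table for SMF input: see [read_note_events_midi()].
#' @return data frame (`part`, `sync_index`, `onset_s`, `chord_group`),
#'   sorted by part then onset.
#' @export
read_note_events <- function(path, sync_table = NULL) {
  if (grepl("\\.midi?$", path, ignore.case = TRUE)) {
    return(read_note_events_midi(path, sync_table))
  }
  df <- utils::read.csv(path)
  if (nrow(df) == 0L) {
    warning("empty note-event file: ", path)
    return(data.frame(part = character(), sync_index = integer(),
                      onset_s = numeric(), chord_group = character()))
  }
  validate_note_events(df)
}

validate_note_events <- function(df) {
  need <- c("part", "sync_index", "onset_s")
  if (!all(need %in% names(df))) {
    stop_ds("note events need columns ", paste(need, collapse = ", "))
  }
  if (!"chord_group" %in% names(df)) df$chord_group <- NA_character_
  if (!all(df$part %in% c("P", "S"))) stop_ds("part must be P or S")
  if (any(df$onset_s < 0)) stop_ds("negative onset")
  for (p in c("P", "S")) {
    sub <- df[df$part == p, ]
    # chord members may be rolled in any order; the per-sync-point
    # reference (latest onset) must still advance through the piece
    ref <- tapply(sub$onset_s, sub$sync_index, max)
    if (is.unsorted(ref[order(as.numeric(names(ref)))])) {
      stop_ds("onsets not non-decreasing within part ", p)
    }
  }
  both <- split(df$sync_index, df$part)
  miss <- union(setdiff(unique(both$P), unique(both$S)),
                setdiff(unique(both$S), unique(both$P)))
  if (length(miss)) {
    stop_ds("sync_index present in only one part: ", paste(miss, collapse = ", "))
  }
  df <- df[order(df$part, df$onset_s), ]
  rownames(df) <- NULL
  df
}

#' Write note events to CSV
#' @param events data frame as returned by [read_note_events()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_note_events <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read note events from a Standard MIDI File
#'
#' Thin adapter for SMF format 0/1: note-on times (velocity > 0) are
#' extracted per track, the first two note-carrying tracks are mapped to
#' Primo and Secondo, and the `sync_table` selects and annotates the
#' score-notated synchronization notes. Sustain and velocity are ignored.
#'
#' @param path `.mid` file.
#' @param sync_table data frame with columns `part` (P/S), `note_index`
#'   (1-based ordinal of the note-on within that part's track), `sync_index`
#'   and optional `chord_group`.
#' @return data frame as [read_note_events()].
#' @export
read_note_events_midi <- function(path, sync_table) {
  if (is.null(sync_table)) stop_ds("SMF input requires a sync_table annotation")
  notes <- parse_smf_noteons(path)
  parts <- c("P", "S")
  if (length(notes) < 2L) stop_ds("SMF must contain two note-carrying tracks")
  if (!"chord_group" %in% names(sync_table)) sync_table$chord_group <- NA_character_
  rows <- lapply(seq_len(nrow(sync_table)), function(i) {
    p <- sync_table$part[i]
    tr <- notes[[match(p, parts)]]
    k <- sync_table$note_index[i]
    if (k > length(tr)) stop_ds("note_index ", k, " beyond track for part ", p)
    data.frame(part = p, sync_index = sync_table$sync_index[i],
               onset_s = tr[k], chord_group = sync_table$chord_group[i])
  })
  validate_note_events(do.call(rbind, rows))
}

# Parses an SMF and returns, per note-carrying track, the sorted vector of
# note-on times in seconds. Tempo changes (meta 0x51) from any track are
# honoured; default tempo 500000 us per quarter note.
parse_smf_noteons <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  u8 <- as.integer(raw)
  be <- function(i, n) sum(u8[i:(i + n - 1)] * 256^((n - 1):0))
  if (rawToChar(raw[1:4]) != "MThd") stop_ds("not a Standard MIDI File: ", path)
  division <- be(13, 2)
  if (division >= 32768) stop_ds("SMPTE time division not supported")
  ntrk <- be(11, 2)
  pos <- 15
  tracks <- list()
  tempo_map <- list()  # (tick, us_per_qn)
  for (trk in seq_len(ntrk)) {
    if (rawToChar(raw[pos:(pos + 3)]) != "MTrk") stop_ds("bad track chunk")
    len <- be(pos + 4, 4)
    i <- pos + 8
    end <- i + len
    tick <- 0
    status <- 0L
    ons <- numeric(0)
    ticks <- numeric(0)
    while (i < end) {
      # variable-length delta time
      dv <- 0
      repeat {
        b <- u8[i]; i <- i + 1
        dv <- dv * 128 + (b %% 128)
        if (b < 128) break
      }
      tick <- tick + dv
      b <- u8[i]
      if (b >= 128) { status <- b; i <- i + 1 }
      hi <- status %/% 16
      if (status == 255L) {          # meta event
        type <- u8[i]; i <- i + 1
        mlen <- 0
        repeat {
          bb <- u8[i]; i <- i + 1
          mlen <- mlen * 128 + (bb %% 128)
          if (bb < 128) break
        }
        if (type == 81L && mlen == 3L) {
          tempo_map[[length(tempo_map) + 1L]] <- c(tick, be(i, 3))
        }
        i <- i + mlen
      } else if (status %in% c(240L, 247L)) {  # sysex
        mlen <- 0
        repeat {
          bb <- u8[i]; i <- i + 1
          mlen <- mlen * 128 + (bb %% 128)
          if (bb < 128) break
        }
        i <- i + mlen
      } else if (hi %in% c(12L, 13L)) {        # 1 data byte
        i <- i + 1
      } else {                                  # 2 data bytes
        if (hi == 9L && u8[i + 1] > 0) { ticks <- c(ticks, tick) }
        i <- i + 2
      }
    }
    if (length(ticks)) tracks[[length(tracks) + 1L]] <- ticks
    pos <- end
  }
  # tick -> seconds with piecewise-constant tempo
  tm <- if (length(tempo_map)) do.call(rbind, tempo_map) else cbind(0, 500000)
  tm <- tm[order(tm[, 1]), , drop = FALSE]
  if (tm[1, 1] > 0) tm <- rbind(c(0, 500000), tm)
  tick2s <- function(tk) {
    vapply(tk, function(x) {
      s <- 0; prev_tick <- 0; prev_tempo <- tm[1, 2]
      for (r in seq_len(nrow(tm))) {
        if (tm[r, 1] >= x) break
        s <- s + (tm[r, 1] - prev_tick) * prev_tempo / (division * 1e6)
        prev_tick <- tm[r, 1]; prev_tempo <- tm[r, 2]
      }
      s + (x - prev_tick) * prev_tempo / (division * 1e6)
    }, numeric(1))
  }
  lapply(tracks, function(tk) sort(tick2s(tk)))
}

# ---- slider event streams -------------------------------------------------

#' Construct a slider event stream
#'
#' One participant x stimulus x modality trial: the sparse log of slider
#' changes on a 0-100 togetherness scale (the platform reports a value only
#' when the slider moves; the handle starts at the center, 50).
#'
#' @param participant_id,stimulus_id,modality trial identifiers
#'   (modality one of AO, VO, AV).
#' @param events data frame with columns `t` (s) and `value` (0-100),
#'   strictly increasing in `t`.
#' @param presentation 1 for first presentation, 2+ for repeats.
#' @param trial_status `"complete"`, `"partial"` (interrupted load) or
#'   `"no_change"` (slider never moved).
#' @param bounds slider bounds, default `c(0, 100)`.
#' @return object of class `slider_stream`.
#' @export
slider_stream <- function(participant_id, stimulus_id, modality, events,
                          presentation = 1L, trial_status = NULL,
                          bounds = c(0, 100)) {
  if (!modality %in% c("AO", "VO", "AV")) stop_ds("unknown modality code: ", modality)
  if (nrow(events)) {
    if (any(diff(events$t) <= 0)) stop_ds("event times must be strictly increasing")
    if (any(events$t < 0)) stop_ds("event time before stimulus start")
    if (any(events$value < bounds[1] | events$value > bounds[2])) {
      stop_ds("slider value outside bounds [", bounds[1], ", ", bounds[2], "]")
    }
  }
  if (is.null(trial_status)) {
    trial_status <- if (nrow(events)) "complete" else "no_change"
  }
  structure(list(participant_id = participant_id, stimulus_id = stimulus_id,
                 modality = modality, presentation = as.integer(presentation),
                 events = events, trial_status = trial_status, bounds = bounds),
            class = "slider_stream")
}

#' @export
print.slider_stream <- function(x, ...) {
  cat("<slider_stream> ", x$participant_id, " x ", x$stimulus_id, " (",
      x$modality, ", pres ", x$presentation, "): ", nrow(x$events),
      " events, ", x$trial_status, "\n", sep = "")
  invisible(x)
}

#' Read sparse slider-event logs
#'
#' CSV columns: `participant`, `stimulus`, `modality`, `t`, `value`, with
#' optional `presentation` (repeat index, default 1) and `load` (load
#' attempt). When a trial was loaded twice the first load is flagged
#' `"partial"` (interrupted) and only the last is `"complete"`. An optional
#' trial roster supplies trials with zero events (participant never moved
#' the slider), which are valid and flagged `"no_change"`.
#'
#' @param path events CSV.
#' @param trials optional data frame or CSV path listing all trials
#'   (`participant`, `stimulus`, `modality`, optional `presentation`).
#' @param bounds slider bounds.
#' @return list of [slider_stream()] objects.
#' @export
read_slider_events <- function(path, trials = NULL, bounds = c(0, 100)) {
  df <- utils::read.csv(path)
  need <- c("participant", "stimulus", "modality", "t", "value")
  if (!all(need %in% names(df))) {
    stop_ds("slider events need columns ", paste(need, collapse = ", "))
  }
  if (!"presentation" %in% names(df)) df$presentation <- 1L
  if (!"load" %in% names(df)) df$load <- 1L
  key <- interaction(df$participant, df$stimulus, df$modality, df$presentation,
                     drop = TRUE)
  streams <- lapply(split(df, key), function(sub) {
    loads <- sort(unique(sub$load))
    out <- lapply(loads, function(ld) {
      s <- sub[sub$load == ld, ]
      s <- s[order(s$t), ]
      slider_stream(s$participant[1], s$stimulus[1], s$modality[1],
                    data.frame(t = s$t, value = s$value),
                    presentation = s$presentation[1],
                    trial_status = if (ld == max(loads)) "complete" else "partial",
                    bounds = bounds)
    })
    out
  })
  streams <- unlist(streams, recursive = FALSE, use.names = FALSE)
  if (!is.null(trials)) {
    if (is.character(trials)) trials <- utils::read.csv(trials)
    if (!"presentation" %in% names(trials)) trials$presentation <- 1L
    have <- vapply(streams, function(s) {
      paste(s$participant_id, s$stimulus_id, s$modality, s$presentation)
    }, character(1))
    for (i in seq_len(nrow(trials))) {
      k <- paste(trials$participant[i], trials$stimulus[i], trials$modality[i],
                 trials$presentation[i])
      if (!k %in% have) {
        streams[[length(streams) + 1L]] <- slider_stream(
          trials$participant[i], trials$stimulus[i], trials$modality[i],
          data.frame(t = numeric(0), value = numeric(0)),
          presentation = trials$presentation[i], trial_status = "no_change",
          bounds = bounds)
      }
    }
  }
  streams
}

#' Write slider streams back to the events CSV format
#' @param streams list of [slider_stream()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_slider_events <- function(streams, path) {
  rows <- lapply(streams, function(s) {
    if (!nrow(s$events)) return(NULL)
    data.frame(participant = s$participant_id, stimulus = s$stimulus_id,
               modality = s$modality, presentation = s$presentation,
               load = 1L, t = s$events$t, value = s$events$value)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
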