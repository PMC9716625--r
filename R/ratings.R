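# Togetherness ratings: de-sparsification of slider logs, trial exclusion,
# lag alignment against stimulus features, and extraction of per-sync-point
# responses.

#' Densify a sparse slider stream to an evenly sampled series
#'
#' Previous-value (constant) interpolation on a 10 Hz grid: the value at
#' grid time t is the last reported slider value at or before t, and the
#' slider center before the first event (the handle starts at the center of
#' the scale). Samples lie at t = 0.0, 0.1, ...; an event exactly on a grid
#' time takes effect at that sample.
#'
#' @param stream a [slider_stream()].
#' @param duration stimulus duration, s. Where response logs run slightly
#'   short of the stimulus, pass the shorter of the two durations.
#' @param rate grid rate, Hz (default 10).
#' @return object of class `rating_series`: `values`
#'   (length `round(duration * rate)`), `rate`, trial identifiers,
#'   `lag_applied = 0`.
#' @export
densify <- function(stream, duration, rate = 10) {
  stopifnot(inherits(stream, "slider_stream"))
  if (duration <= 0) stop_ds("duration must be positive")
  n <- round(duration * rate)
  tgrid <- (seq_len(n) - 1) / rate
  center <- mean(stream$bounds)
  ev <- stream$events
  if (!nrow(ev)) {
    vals <- rep(center, n)
  } else {
    idx <- findInterval(tgrid + 1e-9, ev$t)
    vals <- ifelse(idx == 0L, center, ev$value[pmax(idx, 1L)])
  }
  structure(list(participant_id = stream$participant_id,
                 stimulus_id = stream$stimulus_id, modality = stream$modality,
                 values = vals, rate = rate, lag_applied = 0),
            class = "rating_series")
}

#' @export
print.rating_series <- function(x, ...) {
  cat("<rating_series> ", x$participant_id, " x ", x$stimulus_id, " (",
      x$modality, "): ", length(x$values), " samples @ ", x$rate,
      " Hz, lag ", x$lag_applied, " s\n", sep = "")
  invisible(x)
}

#' Align a rating series with stimulus features at a response lag
#'
#' Pairs the response at time t + lag with the predictors at time t:
#' ratings trail the audiovisual events they respond to, so row t of the
#' model table carries predictors(t) and response(t + lag). The trailing
#' `lag` seconds of predictors (which have no matching response) are
#' dropped; if the feature and rating series differ slightly in length the
#' pair is truncated to the shorter.
#'
#' @param series a [rating_series()].
#' @param features data frame for the same stimulus with column `t`
#'   (seconds, on the same 10 Hz grid from 0) plus predictor columns.
#' @param lag response lag in seconds; the candidate set is `{1, 2, 3}`
#'   unless `allow_zero` permits 0. Must be a multiple of the grid step.
#' @param allow_zero allow `lag = 0` (outside the candidate set; for
#'   diagnostics only).
#' @return data frame: trial identifiers, `t` (predictor time), `response`,
#'   and the predictor columns.
#' @export
lag_align <- function(series, features, lag, allow_zero = FALSE) {
  stopifnot(inherits(series, "rating_series"))
  ok_lags <- c(if (allow_zero) 0, 1, 2, 3)
  if (!lag %in% ok_lags) {
    stop_ds("lag must be one of {", paste(ok_lags, collapse = ", "), "} s")
  }
  step <- lag * series$rate
  if (abs(step - round(step)) > 1e-9) stop_ds("lag must be a multiple of the grid step")
  step <- as.integer(round(step))
  n <- min(length(series$values), nrow(features))
  if (step >= n) stop_ds("lag exceeds series duration")
  keep <- seq_len(n - step)
  out <- data.frame(participant = series$participant_id,
                    stimulus = series$stimulus_id, modality = series$modality,
                    t = features$t[keep],
                    response = series$values[keep + step])
  pred_cols <- setdiff(names(features), "t")
  out[pred_cols] <- features[keep, pred_cols, drop = FALSE]
  out
}

#' Exclude invalid trials
#'
#' Removes partial trials (interrupted loads) and second presentations of
#' repeated stimuli; trials where the slider never moved are retained (a
#' constant rating is valid data).
#'
#' @param streams list of [slider_stream()] objects.
#' @return list with `streams` (retained) and `report` (counts per reason).
#' @export
exclude_trials <- function(streams) {
  status <- vapply(streams, function(s) s$trial_status, character(1))
  pres <- vapply(streams, function(s) s$presentation, integer(1))
  drop_partial <- status == "partial"
  drop_repeat <- !drop_partial & pres > 1L
  keep <- !(drop_partial | drop_repeat)
  list(streams = streams[keep],
       report = list(total = length(streams),
                     partial = sum(drop_partial),
                     repeats = sum(drop_repeat),
                     no_change = sum(status[keep] == "no_change"),
                     retained = sum(keep)))
}

#' Ratings at lagged synchronization reference points
#'
#' For each sync point the reference time is the latest note onset at that
#' point across both musicians (for chords, the last onset of the chord);
#' the response is the rating at reference + lag, at the nearest 10 Hz
#' sample. Points whose lagged reference falls beyond the series end are
#' dropped and counted.
#'
#' @param series a [rating_series()].
#' @param events note events data frame (see [read_note_events()]).
#' @param lag response lag, s.
#' @return data frame (`sync_index`, `t_ref`, `value`) with attribute
#'   `"dropped"` (number of out-of-range points).
#' @export
sync_reference_ratings <- function(series, events, lag) {
  stopifnot(inherits(series, "rating_series"))
  events <- validate_note_events(events)
  refs <- stats::aggregate(onset_s ~ sync_index, data = events, FUN = max)
  idx <- round((refs$onset_s + lag) * series$rate) + 1L
  inside <- idx >= 1L & idx <= length(series$values)
  out <- data.frame(sync_index = refs$sync_index[inside],
                    t_ref = refs$onset_s[inside],
                    value = series$values[idx[inside]])
  attr(out, "dropped") <- sum(!inside)
  out
}
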