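# Auditory cues: RMS sound intensity at 10 Hz, perceptual onset estimation,
# and note/chord onset asynchronies.

#' Construct an intensity envelope
#'
#' @param values non-negative RMS amplitudes (linear units) at `rate` Hz.
#' @param rate envelope rate, Hz (default 10).
#' @param window,hop analysis window and hop, s (hop = window/2: 50% overlap).
#' @return object of class `intensity_envelope`.
#' @export
intensity_envelope <- function(values, rate = 10, window = 2 / rate,
                               hop = window / 2) {
  if (any(values < 0)) stop_ds("RMS values must be non-negative")
  if (abs(hop - window / 2) > 1e-9) stop_ds("hop must equal window/2 (50% overlap)")
  structure(list(values = as.numeric(values), rate = rate, window = window,
                 hop = hop),
            class = "intensity_envelope")
}

#' @export
print.intensity_envelope <- function(x, ...) {
  cat("<intensity_envelope> ", length(x$values), " samples @ ", x$rate,
      " Hz (window ", x$window, " s, 50% overlap)\n", sep = "")
  invisible(x)
}

#' RMS intensity envelope of mono audio
#'
#' Root-mean-square amplitude in rectangular windows of `2/out_rate`
#' seconds hopping by `1/out_rate` (50% overlap), i.e. 0.2 s windows every
#' 0.1 s for the default 10 Hz. Window k is centred on t = k/out_rate and
#' clipped at the signal edges, so the envelope aligns sample-for-sample
#' with the 10 Hz rating grid.
#'
#' @param audio numeric vector of mono samples, or a list with `samples`
#'   and `rate` as returned by [read_wav()].
#' @param rate audio sampling rate, Hz (>= 8000); ignored when `audio`
#'   carries its own.
#' @param out_rate envelope rate, Hz (default 10).
#' @return an [intensity_envelope()].
#' @export
rms_envelope <- function(audio, rate = NULL, out_rate = 10) {
  if (is.list(audio)) { rate <- audio$rate; audio <- audio$samples }
  if (is.null(rate) || rate < 8000) stop_ds("audio rate must be >= 8000 Hz")
  n <- length(audio)
  if (n == 0L) stop_ds("empty audio")
  half <- round(rate / out_rate)          # half-window = hop, in samples
  n_out <- floor(n / half)
  centers <- (seq_len(n_out) - 1L) * half + 1L
  vals <- vapply(centers, function(c0) {
    lo <- max(1L, c0 - half)
    hi <- min(n, c0 + half - 1L)
    sqrt(mean(audio[lo:hi]^2))
  }, numeric(1))
  intensity_envelope(vals, out_rate)
}

#' Perceptual onset within a coarse region
#'
#' Estimates the perceived note start as the start time of the first 10-ms
#' RMS window whose RMS reaches 70% of the maximum window RMS within the
#' region. The threshold is inclusive (>=) and the window start (not
#' center) is reported, biasing estimates consistently early. If the
#' envelope falls back below half of the maximum after the first qualifying
#' window and then re-crosses the threshold, the region contains more than
#' one attack and an error is raised.
#'
#' @param audio mono samples or list(samples, rate).
#' @param rate audio sampling rate, Hz.
#' @param region numeric length-2: start and end of the search region, s.
#' @param threshold fraction of the regional max RMS (default 0.70).
#' @param window_s RMS window, s (default 0.010).
#' @param multiple policy when several attacks are detected: `"error"`
#'   (default) or `"earliest"`.
#' @return onset time in seconds (absolute, not region-relative).
#' @export
perceptual_onset <- function(audio, rate = NULL, region,
                             threshold = 0.70, window_s = 0.010,
                             multiple = c("error", "earliest")) {
  multiple <- match.arg(multiple)
  if (is.list(audio)) { rate <- audio$rate; audio <- audio$samples }
  i0 <- max(1L, floor(region[1] * rate) + 1L)
  i1 <- min(length(audio), ceiling(region[2] * rate))
  seg <- audio[i0:i1]
  wlen <- round(window_s * rate)
  nw <- floor(length(seg) / wlen)
  if (nw < 3L) stop_ds("region shorter than 3 analysis windows")
  rms <- vapply(seq_len(nw), function(k) {
    sqrt(mean(seg[((k - 1L) * wlen + 1L):(k * wlen)]^2))
  }, numeric(1))
  peak <- max(rms)
  if (peak == 0) stop_ds("all-zero region")
  hit <- which(rms >= threshold * peak)
  first <- hit[1]
  # multiple-attack check: drop below 50% of max after the first hit, then
  # a renewed threshold crossing
  after <- rms[seq(first, nw)]
  dropped <- which(after < 0.5 * peak)
  if (length(dropped) && any(after[seq(dropped[1], length(after))] >=
                             threshold * peak)) {
    if (multiple == "error") stop_ds("region appears to contain multiple attacks")
  }
  (i0 - 1L + (first - 1L) * wlen) / rate
}

#' Note and chord onset asynchronies
#'
#' Signed asynchrony at each synchronization point, defined as
#' onset(Secondo) - onset(Primo) in milliseconds, so positive values mean
#' the Primo was leading. For chords (several notes sharing a sync point
#' within a part) the latest onset within the chord is used for each
#' musician before subtracting.
#'
#' @param events data frame as returned by [read_note_events()].
#' @return data frame of class `asynchrony_records`: `sync_index`,
#'   `asynchrony_ms` (signed, S - P), `abs_ms`.
#' @export
note_asynchronies <- function(events) {
  events <- validate_note_events(events)
  if (!nrow(events)) stop_ds("no events")
  ref <- stats::aggregate(onset_s ~ part + sync_index, data = events, FUN = max)
  wide <- stats::reshape(ref, idvar = "sync_index", timevar = "part",
                         direction = "wide")
  if (any(is.na(wide$onset_s.P)) || any(is.na(wide$onset_s.S))) {
    stop_ds("unmatched sync_index")
  }
  out <- data.frame(sync_index = wide$sync_index,
                    asynchrony_ms = (wide$onset_s.S - wide$onset_s.P) * 1000)
  out$abs_ms <- abs(out$asynchrony_ms)
  out <- out[order(out$sync_index), ]
  rownames(out) <- NULL
  class(out) <- c("asynchrony_records", "data.frame")
  out
}

#' Summarize absolute asynchronies
#'
#' Mean and SD of the absolute asynchronies, pooled across whatever set of
#' records is supplied (typically all sync points of the recordings in one
#' stimulus group).
#'
#' @param records an `asynchrony_records` data frame (or anything with an
#'   `abs_ms` column), possibly row-bound across stimuli.
#' @param sd_type `"population"` (default: divisor n, pooled-notes
#'   convention) or `"sample"` (divisor n - 1).
#' @return list with `mean_abs` and `sd` (ms), plus `n`. A single record
#'   yields `sd = 0` with a warning.
#' @export
summarize_asynchrony <- function(records, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  a <- records$abs_ms
  if (!length(a)) stop_ds("empty input")
  m <- mean(a)
  s <- if (length(a) == 1L) {
    warning("single record: SD undefined, reported as 0")
    0
  } else if (sd_type == "population") {
    sqrt(mean((a - m)^2))
  } else {
    stats::sd(a)
  }
  list(mean_abs = m, sd = s, n = length(a))
}
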