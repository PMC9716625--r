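# Quantity of motion: Savitzky-Golay smoothing/differentiation of marker
# trajectories, per-marker speeds, total and local QoM at 10 Hz.

#' Construct a kinematic series
#'
#' @param kind one of position, velocity, acceleration, speed, qom.
#' @param values numeric vector (speed/qom) or n x 3 matrix.
#' @param rate sampling rate, Hz.
#' @param units measurement units (mm, mm/s, mm/s^2, or summed mm/s).
#' @return object of class `kinematic_series`.
#' @export
kinematic_series <- function(kind = c("position", "velocity", "acceleration",
                                      "speed", "qom"),
                             values, rate, units = NULL) {
  kind <- match.arg(kind)
  if (rate <= 0) stop_ds("rate must be positive")
  if (kind %in% c("speed", "qom")) {
    values <- as.numeric(values)
    if (any(values < -1e-9)) stop_ds(kind, " values must be non-negative")
    values <- pmax(values, 0)
  } else {
    values <- as.matrix(values)
  }
  units <- units %||% switch(kind, position = "mm", velocity = "mm/s",
                             acceleration = "mm/s^2", speed = "mm/s",
                             qom = "summed mm/s")
  structure(list(kind = kind, values = values, rate = rate, units = units),
            class = "kinematic_series")
}

#' @export
print.kinematic_series <- function(x, ...) {
  n <- if (is.matrix(x$values)) nrow(x$values) else length(x$values)
  cat("<kinematic_series> ", x$kind, " (", x$units, "), ", n, " samples @ ",
      x$rate, " Hz\n", sep = "")
  invisible(x)
}

#' Savitzky-Golay smoothing and differentiation of a marker trajectory
#'
#' Fits a local polynomial of order `polyorder` in a sliding window and
#' returns the smoothed position (`order = 0`), velocity (`order = 1`,
#' mm/s) or acceleration (`order = 2`, mm/s^2), applied per axis. The
#' filter is same-length; derivative values are scaled by the sampling
#' rate. Defaults match the study's smoothing: a 25-frame window at 240 Hz
#' with a quadratic local fit.
#'
#' @param traj a [marker_trajectory()].
#' @param window odd window length in frames (default 25).
#' @param polyorder local polynomial order (default 2); must be < window.
#' @param order derivative order 0, 1 or 2.
#' @return a [kinematic_series()] with 3-column values.
#' @export
smooth_and_differentiate <- function(traj, window = 25L, polyorder = 2L,
                                     order = 0L) {
  stopifnot(inherits(traj, "marker_trajectory"))
  if (window %% 2L == 0L) stop_ds("window must be odd")
  if (window > nrow(traj$xyz)) stop_ds("window longer than trajectory")
  if (polyorder >= window) stop_ds("polyorder must be < window")
  if (!order %in% 0:2) stop_ds("order must be 0, 1 or 2")
  if (order > polyorder) stop_ds("derivative order exceeds polyorder")
  out <- apply(traj$xyz, 2, function(v) {
    signal::sgolayfilt(v, p = polyorder, n = window, m = order,
                       ts = 1 / traj$rate)
  })
  colnames(out) <- c("x", "y", "z")
  kinematic_series(c("position", "velocity", "acceleration")[order + 1L],
                   out, traj$rate)
}

#' Per-sample Euclidean speed of a velocity series
#'
#' @param vel a velocity [kinematic_series()] (3-vector values, mm/s).
#' @return a speed [kinematic_series()] (scalar mm/s).
#' @export
marker_speed <- function(vel) {
  stopifnot(inherits(vel, "kinematic_series"))
  if (vel$kind != "velocity") stop_ds("marker_speed expects a velocity series")
  kinematic_series("speed", sqrt(rowSums(vel$values^2)), vel$rate)
}

# speed series for one marker of a recording (shared by QoM and diagnostics)
recording_marker_speed <- function(rec, marker_id, window = 25L, polyorder = 2L) {
  tr <- rec$trajectories[[marker_id]]
  if (is.null(tr)) stop_ds("marker ", marker_id, " absent from recording ",
                           rec$stimulus_id)
  marker_speed(smooth_and_differentiate(tr, window, polyorder, order = 1L))
}

#' Quantity of motion of a duo recording
#'
#' Total QoM sums per-marker speeds across markers at each timestamp for
#' each musician, then averages the two musicians' sums per timestamp; for
#' clarinet recordings the instrument markers contribute to the total.
#' Local QoM is the duo mean of one paired marker's speed. The series is
#' resampled to `out_rate` (default 10 Hz, the rating rate) by
#' block-averaging.
#'
#' @param rec a [duo_recording()].
#' @param scope `"total"` or `"local"`.
#' @param markers for local scope, the body part (e.g. `"head"`); for total
#'   scope, an optional subset of parts (defaults to every body marker,
#'   plus instrument markers for clarinet recordings).
#' @param out_rate output rate in Hz; must divide the mocap rate.
#' @param window,polyorder Savitzky-Golay settings.
#' @return a qom [kinematic_series()] at `out_rate`.
#' @export
quantity_of_motion <- function(rec, scope = c("total", "local"), markers = NULL,
                               out_rate = 10, window = 25L, polyorder = 2L) {
  stopifnot(inherits(rec, "duo_recording"))
  scope <- match.arg(scope)
  ids <- names(rec$trajectories)
  if (scope == "local") {
    if (is.null(markers) || length(markers) != 1L) {
      stop_ds("local scope needs exactly one body part")
    }
    part <- markers
    pair <- paste0(c("P_", "S_"), part)
    if (!all(pair %in% ids)) stop_ds("marker ", part, " absent for one musician")
    sp <- vapply(pair, function(id) {
      recording_marker_speed(rec, id, window, polyorder)$values
    }, numeric(nrow(rec$trajectories[[1]]$xyz)))
    duo <- rowMeans(sp)
  } else {
    parts <- markers %||% {
      p <- intersect(all_parts(), unique(vapply(ids, marker_part, character(1))))
      if (rec$stimulus_group == "clarinet" &&
          "instrument" %in% vapply(ids, marker_part, character(1))) {
        p <- c(p, "instrument")
      }
      p
    }
    if (!length(parts)) stop_ds("empty marker set")
    per_mus <- lapply(c("P", "S"), function(m) {
      use <- paste0(m, "_", parts)
      use <- use[use %in% ids]
      if (!length(use)) stop_ds("no requested markers for musician ", m)
      sp <- vapply(use, function(id) {
        recording_marker_speed(rec, id, window, polyorder)$values
      }, numeric(nrow(rec$trajectories[[1]]$xyz)))
      rowSums(as.matrix(sp))
    })
    duo <- (per_mus[[1]] + per_mus[[2]]) / 2
  }
  kinematic_series("qom", block_average(duo, rec$rate, out_rate), out_rate)
}

#' Grand-mean QoM of a recording
#'
#' Time mean of total QoM over non-overlapping 1-s bins aligned to t = 0;
#' a single scalar per recording used to characterize stimuli.
#'
#' @inheritParams quantity_of_motion
#' @return scalar, summed mm/s.
#' @export
grand_mean_qom <- function(rec, window = 25L, polyorder = 2L) {
  if (rec$duration < 1) stop_ds("duration below 1 s")
  q <- quantity_of_motion(rec, "total", out_rate = 1,
                          window = window, polyorder = polyorder)
  mean(q$values)
}
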