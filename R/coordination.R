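# Between-musician coordination: cross-wavelet (Morlet) power of paired
# body-part acceleration at the dominant common period.
#
# The continuous wavelet transform is computed in the frequency domain
# (zero-padded FFT) with the complex Morlet mother wavelet
#   psi(eta) = pi^(-1/4) exp(i omega0 eta) exp(-eta^2 / 2),
# whose Fourier transform is a Gaussian centred at omega0. Coefficients are
# normalized so that |W|^2 is comparable across scales (energy
# normalization sqrt(2 pi s / dt)).

#' Construct a period grid
#'
#' Logarithmic grid of Fourier periods for the wavelet analysis. The
#' default span, 0.3-7 s, covers movement periodicities up to the length of
#' a musical semi-phrase.
#'
#' @param min_period,max_period span in seconds.
#' @param res suboctaves per octave (default 20).
#' @return object of class `period_grid` with fields `periods` and `res`.
#' @export
period_grid <- function(min_period = 0.3, max_period = 7, res = 20) {
  if (min_period <= 0 || max_period <= min_period) stop_ds("invalid period span")
  n_oct <- log2(max_period / min_period)
  periods <- min_period * 2^(seq(0, n_oct, by = 1 / res))
  structure(list(periods = periods, res = res), class = "period_grid")
}

morlet_fourier_factor <- function(omega0) 4 * pi / (omega0 + sqrt(2 + omega0^2))

#' Continuous Morlet wavelet transform
#'
#' @param series a [kinematic_series()] with scalar values, or a plain
#'   numeric vector (then `rate` must be given).
#' @param grid a [period_grid()].
#' @param omega0 Morlet central frequency (dimensionless, default 6; values
#'   below ~5 violate admissibility in practice).
#' @param rate sampling rate when `series` is a bare vector. The series
#'   mean is removed before the transform.
#' @return object of class `cwt_matrix`: complex matrix `W`
#'   (periods x time), `periods`, `rate`, `omega0`.
#' @export
morlet_cwt <- function(series, grid = period_grid(), omega0 = 6, rate = NULL) {
  if (inherits(series, "kinematic_series")) {
    x <- as.numeric(series$values)
    rate <- series$rate
  } else {
    x <- as.numeric(series)
    if (is.null(rate)) stop_ds("rate required for plain numeric input")
  }
  if (omega0 < 5) stop_ds("omega0 must be >= 5 (Morlet admissibility)")
  x <- x - mean(x)  # remove the mean so zero-padding introduces no step
  n <- length(x)
  dt <- 1 / rate
  scales <- grid$periods / morlet_fourier_factor(omega0)
  if (max(grid$periods) > n * dt) {
    stop_ds("series (", round(n * dt, 2), " s) shorter than the largest ",
            "wavelet period (", max(grid$periods), " s)")
  }
  # pad to a power of two that also covers the widest wavelet's half-support
  # (12 scales ~ e^(-72) truncation), so the circular FFT correlation equals
  # the linear one; padding is removed before return
  support <- ceiling(12 * max(scales) / dt)
  npad <- next_pow2(n + support)
  xhat <- stats::fft(c(x, numeric(npad - n)))
  k <- 0:(npad - 1)
  omega <- 2 * pi * ifelse(k <= npad / 2, k, k - npad) / (npad * dt)
  W <- matrix(0i, nrow = length(scales), ncol = n)
  for (j in seq_along(scales)) {
    s <- scales[j]
    daughter <- sqrt(2 * pi * s / dt) * pi^(-1 / 4) *
      exp(-(s * omega - omega0)^2 / 2)
    W[j, ] <- (stats::fft(xhat * daughter, inverse = TRUE) / npad)[seq_len(n)]
  }
  structure(list(W = W, periods = grid$periods, rate = rate, omega0 = omega0),
            class = "cwt_matrix")
}

#' Cross-wavelet transform of two coefficient matrices
#'
#' Element-wise `a * Conj(b)`; the modulus is the cross-wavelet power, the
#' argument the relative phase.
#'
#' @param a,b `cwt_matrix` objects on identical grids.
#' @return a `cwt_matrix` holding the complex cross spectrum.
#' @export
cross_wavelet <- function(a, b) {
  stopifnot(inherits(a, "cwt_matrix"), inherits(b, "cwt_matrix"))
  if (!isTRUE(all.equal(a$periods, b$periods)) || a$rate != b$rate ||
      !identical(dim(a$W), dim(b$W))) {
    stop_ds("grid mismatch between coefficient matrices")
  }
  structure(list(W = a$W * Conj(b$W), periods = a$periods, rate = a$rate,
                 omega0 = a$omega0),
            class = "cwt_matrix")
}

#' Dominant common period of a cross-wavelet matrix
#'
#' The grid period maximizing time-averaged cross power; exact ties break
#' toward the shorter period.
#'
#' @param cross a `cwt_matrix` (typically from [cross_wavelet()]).
#' @return period in seconds.
#' @export
dominant_period <- function(cross) {
  stopifnot(inherits(cross, "cwt_matrix"))
  pw <- rowMeans(Mod(cross$W))
  if (all(pw == 0)) stop_ds("all-zero cross matrix")
  cross$periods[which.max(pw)]  # periods ascend, so first max = shortest
}

#' Coordination series of one paired body part
#'
#' Pipeline for one stimulus and one body-part pair: acceleration of each
#' musician's marker (second Savitzky-Golay derivative of smoothed
#' positions), Euclidean norm over the three axes, Morlet CWT of each
#' musician, cross-wavelet power, extraction of the row at the dominant
#' period, and block-averaging down to `out_rate`.
#'
#' @param rec a [duo_recording()].
#' @param pair body part (one of [coordination_parts()]).
#' @param grid a [period_grid()].
#' @param out_rate output rate, Hz (default 10).
#' @param omega0 Morlet central frequency.
#' @param window,polyorder Savitzky-Golay settings.
#' @param period optional fixed period: skip the argmax and extract this
#'   grid period instead (used when one period per stimulus is preferred
#'   over one per pair).
#' @return object of class `coordination_series`: `pair`,
#'   `dominant_period` (s), `power` (non-negative, at `out_rate`), `rate`,
#'   `grid`.
#' @export
coordination_series <- function(rec, pair, grid = period_grid(), out_rate = 10,
                                omega0 = 6, window = 25L, polyorder = 2L,
                                period = NULL) {
  stopifnot(inherits(rec, "duo_recording"))
  if (!pair %in% coordination_parts()) {
    stop_ds("pair must be one of: ", paste(coordination_parts(), collapse = ", "))
  }
  ids <- paste0(c("P_", "S_"), pair)
  if (!all(ids %in% names(rec$trajectories))) {
    stop_ds("marker ", pair, " missing for one musician in ", rec$stimulus_id)
  }
  cw <- lapply(ids, function(id) {
    acc <- smooth_and_differentiate(rec$trajectories[[id]], window, polyorder,
                                    order = 2L)
    mag <- sqrt(rowSums(acc$values^2))
    morlet_cwt(mag, grid, omega0, rate = rec$rate)
  })
  cross <- cross_wavelet(cw[[1]], cw[[2]])
  dp <- if (is.null(period)) dominant_period(cross) else {
    grid$periods[which.min(abs(grid$periods - period))]
  }
  row <- Mod(cross$W[match(dp, cross$periods), ])
  structure(list(pair = pair, dominant_period = dp,
                 power = block_average(row, rec$rate, out_rate),
                 rate = out_rate, grid = grid),
            class = "coordination_series")
}

#' @export
print.coordination_series <- function(x, ...) {
  cat("<coordination_series> ", x$pair, ": dominant period ",
      round(x$dominant_period, 3), " s, ", length(x$power), " samples @ ",
      x$rate, " Hz\n", sep = "")
  invisible(x)
}

#' Period-by-time cross power of one pair, for diagnostics
#'
#' Returns the full cross-wavelet power matrix of a body-part pair as a
#' long data frame (`period`, `t`, `power`), suitable for writing to CSV
#' and plotting.
#'
#' @inheritParams coordination_series
#' @return data frame with one row per period x time cell.
#' @export
coordination_power_matrix <- function(rec, pair, grid = period_grid(),
                                      omega0 = 6, window = 25L, polyorder = 2L) {
  ids <- paste0(c("P_", "S_"), pair)
  cw <- lapply(ids, function(id) {
    acc <- smooth_and_differentiate(rec$trajectories[[id]], window, polyorder,
                                    order = 2L)
    morlet_cwt(sqrt(rowSums(acc$values^2)), grid, omega0, rate = rec$rate)
  })
  cross <- cross_wavelet(cw[[1]], cw[[2]])
  n <- ncol(cross$W)
  data.frame(period = rep(cross$periods, times = n),
             t = rep((seq_len(n) - 1) / rec$rate, each = length(cross$periods)),
             power = as.numeric(Mod(cross$W)))
}
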