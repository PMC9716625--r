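#' @keywords internal
"_PACKAGE"

# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ds <- function(...) stop(..., call. = FALSE)

next_pow2 <- function(n) {
  stopifnot(n >= 1)
  2L^ceiling(log2(n))
}

#' Block-average a uniformly sampled series to a lower rate
#'
#' Downsamples by taking the mean over consecutive non-overlapping blocks of
#' `rate / out_rate` samples. Conserves the series mean (up to a trailing
#' partial block, which is dropped).
#'
#' @param x numeric vector, uniformly sampled at `rate`.
#' @param rate input sampling rate in Hz.
#' @param out_rate output rate in Hz; must divide `rate`.
#' @return numeric vector of length `floor(length(x) / (rate/out_rate))`.
#' @export
block_average <- function(x, rate, out_rate) {
  if (out_rate <= 0 || rate <= 0) stop_ds("rates must be positive")
  k <- rate / out_rate
  if (abs(k - round(k)) > 1e-9) {
    stop_ds("out_rate (", out_rate, " Hz) must divide the native rate (", rate, " Hz)")
  }
  k <- as.integer(round(k))
  if (k == 1L) return(x)
  nb <- floor(length(x) / k)
  if (nb < 1L) stop_ds("series too short to resample to ", out_rate, " Hz")
  colMeans(matrix(x[seq_len(nb * k)], nrow = k))
}

#' Log-transform skewed predictors with a data-driven offset
#'
#' Computes `log(x + eps)` where `eps` defaults to the smallest positive
#' observed value times 1e-3, so that zero frames (silence, motionless
#' samples) remain finite while order statistics are preserved.
#'
#' @param x non-negative numeric vector.
#' @param eps offset; defaults to `min(x[x > 0]) * 1e-3`.
#' @return numeric vector with attribute `"eps"` recording the offset used.
#' @export
log_offset <- function(x, eps = NULL) {
  if (any(x < 0, na.rm = TRUE)) stop_ds("log_offset expects non-negative input")
  if (is.null(eps)) {
    pos <- x[is.finite(x) & x > 0]
    eps <- if (length(pos)) min(pos) * 1e-3 else 1e-12
  }
  out <- log(x + eps)
  attr(out, "eps") <- eps
  out
}

# double moving-average lowpass of white noise (sharper roll-off than a
# single pass), unit variance target
smooth_noise2 <- function(n, rate, cutoff_hz) {
  k <- max(3L, round(rate / cutoff_hz))
  z <- stats::rnorm(n)
  for (i in 1:2) {
    z <- as.numeric(stats::filter(z, rep(1 / k, k), sides = 2,
                                  circular = TRUE))
  }
  if (stats::sd(z) > 0) z <- z / stats::sd(z)
  z
}

# deterministic child seed, kept well below .Machine$integer.max
derive_seed <- function(seed, index) {
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(index) * 7L + 13L
}
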