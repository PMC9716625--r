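# Eye-gaze: AOI fixation aggregation over 1-s bins and the fixation LMM.

#' The closed set of areas of interest
#'
#' Five AOIs defined on the stimulus display: head and upper body (with
#' hands/instrument) of each musician, plus the screen center. Samples with
#' no AOI (track loss, off-screen gaze) are labelled `"none"`.
#' @export
aoi_levels <- function() {
  c("P_Head", "P_UpperBody", "S_Head", "S_UpperBody", "Center")
}

#' Percentage of fixation time per AOI
#'
#' Splits each trial into `bin`-second bins aligned to stimulus start,
#' computes the percentage of tracked samples (samples carrying any AOI)
#' fixating each AOI within a bin, and averages the bins per participant x
#' stimulus x AOI. Percentages are of tracked time, not wall time, so the
#' result is invariant to the sampling rate; a final partial bin is
#' weighted by its share of a full bin.
#'
#' @param samples data frame: `participant`, `stimulus`, `t` (s), `aoi`
#'   (one of [aoi_levels()] or `"none"`).
#' @param bin bin width, s (default 1).
#' @param rate nominal sampling rate (Hz), used only to weight the final
#'   partial bin; inferred from the median time step when NULL.
#' @return data frame: `participant`, `stimulus`, `aoi`, `mean_pct`.
#'   Trials with no tracked samples yield `NA` percentages.
#' @export
fixation_percentages <- function(samples, bin = 1, rate = NULL) {
  stopifnot(all(c("participant", "stimulus", "t", "aoi") %in% names(samples)))
  bad <- setdiff(unique(samples$aoi), c(aoi_levels(), "none"))
  if (length(bad)) stop_ds("unknown AOI label(s): ", paste(bad, collapse = ", "))
  trials <- split(samples, interaction(samples$participant, samples$stimulus,
                                       drop = TRUE))
  rows <- lapply(trials, function(tr) {
    tr <- tr[order(tr$t), ]
    r <- rate %||% (1 / stats::median(diff(tr$t)))
    full_bin_n <- bin * r
    tr$bin <- floor(tr$t / bin)
    tracked <- tr[tr$aoi != "none", , drop = FALSE]
    base <- data.frame(participant = tr$participant[1],
                       stimulus = tr$stimulus[1], aoi = aoi_levels())
    if (!nrow(tracked)) {
      base$mean_pct <- NA_real_
      return(base)
    }
    bins <- split(tracked, tracked$bin)
    bin_sizes <- vapply(split(tr, tr$bin), nrow, integer(1))  # incl. none
    pct <- vapply(bins, function(b) {
      vapply(aoi_levels(), function(a) 100 * mean(b$aoi == a), numeric(1))
    }, numeric(length(aoi_levels())))
    w <- pmin(1, bin_sizes[names(bins)] / full_bin_n)
    base$mean_pct <- as.numeric(pct %*% w) / sum(w)
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mixed model of fixation by AOI and music training
#'
#' Fits mean fixation percentage on fixed effects of AOI and music
#' training, with crossed random intercepts for stimulus and participant.
#' AOI contrasts are reported against `reference` (default `S_UpperBody`,
#' the most-fixated area), so the other AOIs' coefficients are the drop in
#' fixation relative to it.
#'
#' @param means output of [fixation_percentages()], joined with a
#'   `training` column (`"novice"` / `"semipro"`).
#' @param reference reference AOI level.
#' @return object of class `lmm_fit` (random structure: crossed intercepts;
#'   `rho` is NA). The lme4 fit is in `$model`; singular fits are flagged,
#'   not dropped.
#' @export
fit_fixation_model <- function(means, reference = "S_UpperBody") {
  means <- means[!is.na(means$mean_pct), , drop = FALSE]
  if (length(unique(means$aoi)) < 2L) stop_ds("need >= 2 AOI levels")
  means$aoi <- stats::relevel(factor(means$aoi), ref = reference)
  means$training <- factor(means$training)
  form <- if (nlevels(means$training) >= 2L) {
    mean_pct ~ training + aoi + (1 | participant) + (1 | stimulus)
  } else {  # single training group: the effect is inestimable, drop it
    mean_pct ~ aoi + (1 | participant) + (1 | stimulus)
  }
  fit <- lmerTest::lmer(form, data = means)
  ct <- stats::coef(summary(fit))
  tcrit <- stats::qt(0.975, ct[, "df"])
  fixed_df <- data.frame(term = rownames(ct), estimate = ct[, "Estimate"],
                         se = ct[, "Std. Error"],
                         ci_lo = ct[, "Estimate"] - tcrit * ct[, "Std. Error"],
                         ci_hi = ct[, "Estimate"] + tcrit * ct[, "Std. Error"],
                         t = ct[, "t value"], df = ct[, "df"],
                         p = ct[, "Pr(>|t|)"], row.names = NULL)
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(fixed = fixed_df, rho = NA_real_,
                 ranef_sd = stats::setNames(vc$sdcor[vc$grp != "Residual"],
                                            vc$grp[vc$grp != "Residual"]),
                 sigma = vc$sdcor[vc$grp == "Residual"],
                 logLik = as.numeric(stats::logLik(fit)), n_obs = nrow(means),
                 method = "REML", singular = lme4::isSingular(fit),
                 model = fit),
            class = "lmm_fit")
}
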