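# Mixed-model machinery: Gaussian LMMs with AR(1) residual correlation
# within stimulus time series, VIF, participant-folded k-fold CV for lag
# selection, the modality x expertise model battery, synchronization
# models, factorial ANOVAs with Tukey HSD, and body-part comparisons.

# integer time index per AR(1) series (rows are sorted along the way)
add_time_index <- function(data, series, time) {
  key <- interaction(data[series], drop = TRUE)
  ord <- order(key, data[[time]])
  data <- data[ord, , drop = FALSE]
  data$.series <- interaction(data[series], drop = TRUE)[ord]
  data$.tindex <- stats::ave(seq_len(nrow(data)), data$.series,
                             FUN = seq_along)
  data
}

#' Fit a Gaussian linear mixed model with AR(1) residuals
#'
#' Maximum-likelihood fit of `response ~ fixed` with a random intercept per
#' `group` (typically participants) and first-order autoregressive residual
#' correlation within each time series identified by `series` (typically
#' participant x stimulus). Wald confidence intervals on the fixed effects.
#'
#' @param data model table (one row per time sample); must contain the
#'   `time` column and all model variables.
#' @param response,fixed response column name and character vector of fixed
#'   effect columns.
#' @param group grouping column for the random intercept, or NULL for no
#'   random effect (then a GLS fit is used, which reduces to OLS when
#'   `ar1 = FALSE`).
#' @param series character vector of columns identifying one AR(1) time
#'   series (default: group and stimulus).
#' @param time time column name (default `"t"`).
#' @param ar1 include the AR(1) residual correlation (default TRUE).
#' @param method `"ML"` (default; needed for cross-model comparability) or
#'   `"REML"`.
#' @param conf_level confidence level for the Wald intervals.
#' @return object of class `lmm_fit`: `fixed` (data frame of term,
#'   estimate, se, ci_lo, ci_hi, t, df, p), `rho` (AR(1) correlation, NA if
#'   `ar1 = FALSE`), `ranef_sd`, `sigma`, `logLik`, `n_obs`, `singular`
#'   flag and the underlying nlme fit in `$model`.
#' @export
fit_lmm_ar1 <- function(data, response, fixed, group = "participant",
                        series = c(group, "stimulus"), time = "t",
                        ar1 = TRUE, method = c("ML", "REML"),
                        conf_level = 0.95) {
  method <- method[1]
  if (!is.null(group) && length(unique(data[[group]])) < 2L) {
    stop_ds("need at least 2 levels of ", group)
  }
  bad <- fixed[vapply(fixed, function(f) {
    v <- data[[f]]
    is.numeric(v) && (any(!is.finite(v)) || stats::var(v) == 0)
  }, logical(1))]
  if (length(bad)) {
    stop_ds("degenerate predictor(s): ", paste(bad, collapse = ", "),
            " (constant or non-finite)")
  }
  data <- add_time_index(data, series, time)
  form <- stats::reformulate(fixed, response)
  fit <- tryCatch({
    if (!is.null(group)) {
      data$.group <- factor(data[[group]])
      # the correlation grouping must be expressed as nested under the
      # random-effect grouping for lme
      cor_struct <- if (ar1) nlme::corAR1(form = ~ .tindex | .group / .series) else NULL
      nlme::lme(form, random = ~ 1 | .group, correlation = cor_struct,
                data = data, method = method,
                control = nlme::lmeControl(maxIter = 100, msMaxIter = 100,
                                           niterEM = 10, tolerance = 1e-4,
                                           returnObject = TRUE))
    } else {
      cor_struct <- if (ar1) nlme::corAR1(form = ~ .tindex | .series) else NULL
      nlme::gls(form, correlation = cor_struct, data = data, method = method,
                control = nlme::glsControl(maxIter = 100, msMaxIter = 100,
                                           returnObject = TRUE))
    }
  }, error = function(e) {
    stop_ds("mixed model did not converge: ", conditionMessage(e),
            " [n = ", nrow(data), ", fixed: ", paste(fixed, collapse = " + "), "]")
  })
  tt <- summary(fit)$tTable
  is_lme <- inherits(fit, "lme")
  df <- if (is_lme) tt[, "DF"] else rep(nrow(data) - nrow(tt), nrow(tt))
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df)
  fixed_df <- data.frame(term = rownames(tt), estimate = tt[, "Value"],
                         se = tt[, "Std.Error"],
                         ci_lo = tt[, "Value"] - tcrit * tt[, "Std.Error"],
                         ci_hi = tt[, "Value"] + tcrit * tt[, "Std.Error"],
                         t = tt[, "t-value"], df = df,
                         p = tt[, "p-value"], row.names = NULL)
  rho <- if (ar1) {
    unname(stats::coef(fit$modelStruct$corStruct, unconstrained = FALSE))
  } else NA_real_
  ranef_sd <- if (is_lme) {
    as.numeric(nlme::VarCorr(fit)["(Intercept)", "StdDev"])
  } else NA_real_
  structure(list(fixed = fixed_df, rho = rho, ranef_sd = ranef_sd,
                 sigma = fit$sigma, logLik = as.numeric(stats::logLik(fit)),
                 n_obs = nrow(data), method = method,
                 singular = isTRUE(!is.na(ranef_sd) && ranef_sd < 1e-6 * fit$sigma),
                 model = fit),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, digits = 4, ...) {
  cat("<lmm_fit> n =", x$n_obs, "| method", x$method,
      "| rho =", round(x$rho, 3), "| ranef sd =", round(x$ranef_sd, 3),
      "| sigma =", round(x$sigma, 3),
      if (x$singular) "| SINGULAR random effect", "\n")
  print(format(x$fixed, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Marginal (fixed-effects) predictions from an `lmm_fit`
#'
#' Predictions for new observations use the fixed effects only: random
#' intercepts of unseen participants are set to their population mean, 0.
#'
#' @param object an `lmm_fit`.
#' @param newdata data frame with the fixed-effect columns.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.lmm_fit <- function(object, newdata, ...) {
  fit <- object$model
  X <- stats::model.matrix(stats::formula(fit)[-2], data = newdata)
  as.numeric(X %*% nlme::fixef(fit))
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` is from regressing predictor j
#' on all the others. Perfect collinearity yields `Inf`.
#'
#' @param data model table.
#' @param predictors character vector (>= 2) of predictor columns.
#' @return named numeric vector of VIFs.
#' @export
compute_vif <- function(data, predictors) {
  if (length(predictors) < 2L) stop_ds("need at least 2 predictors")
  X <- data[predictors]
  if (any(vapply(X, function(v) stats::var(v) == 0, logical(1)))) {
    stop_ds("constant predictor")
  }
  out <- vapply(predictors, function(p) {
    # perfect fits are reported as Inf below; silence lm's complaint
    r2 <- suppressWarnings(
      summary(stats::lm(stats::reformulate(setdiff(predictors, p), p),
                        data = X))$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  out
}

#' Participant-folded k-fold cross-validation over candidate response lags
#'
#' For each candidate lag, fits the AR(1) mixed model on K-1 participant
#' folds and predicts the held-out participants' ratings from the fixed
#' effects (the AR(1) structure contributes nothing to the marginal mean of
#' unseen series). Model accuracy is the mean MAE and RMSE across folds;
#' the selected lag has the lowest MAE and RMSE. When the two measures
#' disagree MAE decides; exact ties break toward the shorter lag.
#'
#' @param tables named list of model tables, one per candidate lag, names
#'   the lag in seconds (e.g. `list("1" = ..., "2" = ..., "3" = ...)`).
#'   Each table is one modality's lag-aligned data.
#' @param fixed fixed-effect columns; default: every `log_`-prefixed column
#'   of the first table.
#' @param K number of folds (default 10); participants are partitioned into
#'   folds differing in size by at most 1.
#' @param seed integer seed for the fold assignment.
#' @param response response column.
#' @return object of class `cv_result`: `table` (lag, mae, rmse),
#'   `selected_lag` (s), `folds` (participant -> fold).
#' @export
lag_crossvalidation <- function(tables, fixed = NULL, K = 10, seed = 1,
                                response = "response") {
  lags <- as.numeric(names(tables))
  if (any(is.na(lags))) stop_ds("tables must be named by lag in seconds")
  fixed <- fixed %||% grep("^log_", names(tables[[1]]), value = TRUE)
  participants <- unique(tables[[1]]$participant)
  if (length(participants) < K) stop_ds("need at least K participants")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  shuffled <- sample(participants)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  fold_of <- stats::setNames(rep(seq_len(K), length.out = length(shuffled)),
                             shuffled)
  per_lag <- lapply(seq_along(tables), function(li) {
    tab <- tables[[li]]
    fold_err <- vapply(seq_len(K), function(k) {
      test_p <- names(fold_of)[fold_of == k]
      train <- tab[!tab$participant %in% test_p, , drop = FALSE]
      test <- tab[tab$participant %in% test_p, , drop = FALSE]
      if (!nrow(test)) stop_ds("fold ", k, " has zero rows")
      fit <- fit_lmm_ar1(train, response, fixed)
      pred <- predict(fit, test)
      err <- test[[response]] - pred
      c(mae = mean(abs(err)), rmse = sqrt(mean(err^2)))
    }, c(mae = 0, rmse = 0))
    c(mae = mean(fold_err["mae", ]), rmse = mean(fold_err["rmse", ]))
  })
  tab <- data.frame(lag = lags,
                    mae = vapply(per_lag, `[[`, 0, "mae"),
                    rmse = vapply(per_lag, `[[`, 0, "rmse"))
  tab <- tab[order(tab$lag), ]
  best_mae <- tab$lag[which.min(tab$mae)]    # which.min: first = shortest lag
  best_rmse <- tab$lag[which.min(tab$rmse)]
  structure(list(table = tab, selected_lag = best_mae,
                 agreement = best_mae == best_rmse, folds = fold_of),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> selected lag:", x$selected_lag, "s",
      if (!x$agreement) "(MAE and RMSE disagreed; MAE decided)", "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

battery_groups <- function() {
  list(a = list(label = "semipro", filter = function(d) d$background == "semipro"),
       b = list(label = "novice", filter = function(d) d$background == "novice"),
       c = list(label = "pianist", filter = function(d) d$instrument == "pianist"),
       d = list(label = "clarinetist", filter = function(d) d$instrument == "clarinetist"))
}

#' Run the togetherness model battery (models 1a-d, 2a-d, 3a-d)
#'
#' Model group 1 relates ratings of audio-only (AO) stimuli to log sound
#' intensity; group 2 relates video-only (VO) ratings to log total QoM and
#' the six log pair CWT powers; group 3 relates audio-plus-video (AV)
#' ratings to all of these. Within each group, model (a) uses the
#' semi-professional musicians, (b) the novices, (c) the pianists and (d)
#' the clarinetists. Each fit has a participant random intercept and AR(1)
#' residuals within stimulus time. Significance is flagged at
#' `alpha = 0.0125` (Bonferroni: four models per modality).
#'
#' @param tables named list with elements `AO`, `VO`, `AV`: lag-aligned
#'   model tables carrying `background` and `instrument` columns.
#' @param alpha per-model alpha after Bonferroni correction.
#' @param groups subset of `c("a","b","c","d")` to fit.
#' @return object of class `model_battery`: `fits` (named `1a` ... `3d`),
#'   `summary` (tidy data frame, one row per fixed effect), `alpha`.
#' @export
run_togetherness_models <- function(tables, alpha = 0.0125,
                                    groups = c("a", "b", "c", "d")) {
  specs <- list("1" = "AO", "2" = "VO", "3" = "AV")
  gdefs <- battery_groups()[groups]
  fits <- list()
  rows <- list()
  for (mn in names(specs)) {
    mod <- specs[[mn]]
    if (is.null(tables[[mod]])) next
    tab <- tables[[mod]]
    fixed <- switch(mod,
                    AO = "log_intensity",
                    VO = grep("^log_(qom|power_)", names(tab), value = TRUE),
                    AV = grep("^log_(intensity|qom|power_)", names(tab), value = TRUE))
    for (g in names(gdefs)) {
      sub <- tab[gdefs[[g]]$filter(tab), , drop = FALSE]
      if (!nrow(sub)) stop_ds("empty subset for model ", mn, g)
      fit <- fit_lmm_ar1(sub, "response", fixed)
      id <- paste0(mn, g)
      fits[[id]] <- fit
      fx <- fit$fixed
      rows[[id]] <- data.frame(model = id, modality = mod,
                               group = gdefs[[g]]$label, fx,
                               significant = fx$p < alpha)
    }
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  structure(list(fits = fits, summary = summary, alpha = alpha),
            class = "model_battery")
}

#' @export
print.model_battery <- function(x, ...) {
  cat("<model_battery>", length(x$fits), "models, alpha =", x$alpha, "\n")
  s <- x$summary[x$summary$term != "(Intercept)", ]
  print(format(s[, c("model", "group", "term", "estimate", "ci_lo", "ci_hi",
                     "t", "p", "significant")], digits = 3),
        row.names = FALSE)
  invisible(x)
}

#' Run the synchronization models (models 4a-d AO, 5a-d AV)
#'
#' Relates per-sync-point togetherness ratings to onset asynchrony with a
#' participant random intercept, per modality (AO = model 4, AV = model 5)
#' and participant group. The default predictor is the asynchrony magnitude
#' in ms (`abs_ms`); the signed asynchrony (`asynchrony_ms`) is available.
#'
#' @param data data frame with one row per participant x stimulus x sync
#'   point: `participant`, `background`, `instrument`, `modality` (AO/AV),
#'   `stimulus`, `sync_index`, `asynchrony_ms`, `abs_ms`, `rating`.
#' @param predictor `"abs"` (default) or `"signed"`.
#' @param alpha significance threshold (Bonferroni-corrected).
#' @param groups subset of `c("a","b","c","d")`.
#' @return a `model_battery` with models named `4a` ... `5d`.
#' @export
run_sync_models <- function(data, predictor = c("abs", "signed"),
                            alpha = 0.0125, groups = c("a", "b", "c", "d")) {
  predictor <- match.arg(predictor)
  pcol <- if (predictor == "abs") "abs_ms" else "asynchrony_ms"
  if (length(unique(data$sync_index)) < 2L) stop_ds("need >= 2 sync points")
  specs <- list("4" = "AO", "5" = "AV")
  gdefs <- battery_groups()[groups]
  fits <- list(); rows <- list()
  for (mn in names(specs)) {
    mod <- specs[[mn]]
    tab <- data[data$modality == mod, , drop = FALSE]
    if (!nrow(tab)) next
    for (g in names(gdefs)) {
      sub <- tab[gdefs[[g]]$filter(tab), , drop = FALSE]
      if (!nrow(sub)) stop_ds("empty subset for model ", mn, g)
      if (stats::var(sub[[pcol]]) == 0) {
        stop_ds("asynchronies are constant in model ", mn, g,
                ": slope inestimable")
      }
      sub$t <- sub$t_ref %||% sub$sync_index
      fit <- fit_lmm_ar1(sub, "rating", pcol, ar1 = FALSE,
                         series = c("participant", "stimulus"))
      id <- paste0(mn, g)
      fits[[id]] <- fit
      fx <- fit$fixed
      rows[[id]] <- data.frame(model = id, modality = mod,
                               group = gdefs[[g]]$label, fx,
                               significant = fx$p < alpha)
    }
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  structure(list(fits = fits, summary = summary, alpha = alpha),
            class = "model_battery")
}

#' Factorial ANOVA on per-trial mean ratings, with Tukey HSD
#'
#' Fixed-effects factorial ANOVA (type-II sums of squares) on mean
#' togetherness ratings, one mean per participant x stimulus x modality,
#' with all interactions among the requested factors; Tukey HSD contrasts
#' on a requested term.
#'
#' @param means data frame with `mean_rating` plus the factor columns.
#' @param factors character vector of factor columns, e.g.
#'   `c("background", "modality", "stimulus_group")` or
#'   `c("instrument", "modality", "stimulus_group")`.
#' @param tukey term(s) for Tukey HSD contrasts (default: the two-way
#'   interaction of the first two factors).
#' @return object of class `anova_result`: `anova` (term, df, df_res, F,
#'   p), `tukey` (named list of contrast tables), `empty_cells` count.
#' @export
anova_mean_ratings <- function(means, factors,
                               tukey = paste(factors[1:2], collapse = ":")) {
  for (f in factors) means[[f]] <- factor(means[[f]])
  counts <- table(means[factors])
  form <- stats::as.formula(paste("mean_rating ~", paste(factors, collapse = "*")))
  lmfit <- stats::lm(form, data = means)
  a2 <- car::Anova(lmfit, type = 2)
  df_res <- a2["Residuals", "Df"]
  terms <- setdiff(rownames(a2), "Residuals")
  anova_df <- data.frame(term = terms, df = a2[terms, "Df"], df_res = df_res,
                         F = a2[terms, "F value"], p = a2[terms, "Pr(>F)"],
                         row.names = NULL)
  aovfit <- stats::aov(form, data = means)
  tk <- lapply(tukey, function(term) {
    h <- stats::TukeyHSD(aovfit, which = term)[[term]]
    data.frame(contrast = rownames(h), diff = unname(h[, "diff"]),
               ci_lo = unname(h[, "lwr"]), ci_hi = unname(h[, "upr"]),
               p_adj = unname(h[, "p adj"]), row.names = NULL)
  })
  names(tk) <- tukey
  structure(list(anova = anova_df, tukey = tk,
                 empty_cells = sum(counts == 0)),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat("<anova_result>\n")
  print(format(x$anova, digits = 4), row.names = FALSE)
  if (x$empty_cells) cat("NOTE:", x$empty_cells, "empty design cells\n")
  invisible(x)
}

#' Compare body parts in local QoM or coordination power
#'
#' LMM of the 10 Hz series value on body part with a random stimulus
#' intercept and AR(1) residuals within each stimulus x part series,
#' followed by Tukey-adjusted pairwise contrasts between parts.
#'
#' @param data long data frame: `stimulus`, `part`, `t`, `value`.
#' @param response response column (default `"value"`).
#' @return list with `fit` (an `lmm_fit`), `contrasts` (Tukey-adjusted
#'   pairwise comparisons) and `means` (estimated marginal mean per part).
#' @export
compare_body_parts <- function(data, response = "value") {
  if (length(unique(data$part)) < 2L) stop_ds("need >= 2 body parts")
  data$part <- factor(data$part)
  fit <- fit_lmm_ar1(data, response, "part", group = "stimulus",
                     series = c("stimulus", "part"))
  emm <- emmeans::emmeans(fit$model, "part", data = fit$model$data,
                          mode = "containment")
  ct <- as.data.frame(emmeans::contrast(emm, "pairwise", adjust = "tukey"))
  list(fit = fit, contrasts = ct, means = as.data.frame(emm))
}
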