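# direct simulation of the AR(1) mixed model (independent of the study
# generator): participant intercepts + beta * x + AR(1) errors
sim_lmm_data <- function(n_part = 8, n_stim = 3, n_time = 120, beta = 2,
                         rho = 0.5, sigma = 3, tau = 5, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (p in seq_len(n_part)) {
    b0 <- rnorm(1, 0, tau)
    for (s in seq_len(n_stim)) {
      x <- as.numeric(arima.sim(list(ar = 0.8), n_time, sd = 1))
      e <- as.numeric(stats::filter(rnorm(n_time, 0, sigma * sqrt(1 - rho^2)),
                                    rho, method = "recursive",
                                    init = rnorm(1, 0, sigma)))
      rows[[paste(p, s)]] <- data.frame(
        participant = sprintf("p%02d", p), stimulus = paste0("s", s),
        t = (seq_len(n_time) - 1) / 10, x = x,
        response = 50 + b0 + beta * x + e)
    }
  }
  do.call(rbind, rows)
}

test_that("fit_lmm_ar1 recovers slope, AR(1) correlation and intercept variance", {
  d <- sim_lmm_data(n_part = 10, n_stim = 3, n_time = 150, beta = 2,
                    rho = 0.5, sigma = 3, tau = 5, seed = 42)
  fit <- fit_lmm_ar1(d, "response", "x")
  est <- fit$fixed[fit$fixed$term == "x", ]
  expect_lt(abs(est$estimate - 2), 4 * est$se)
  expect_equal(fit$rho, 0.5, tolerance = 0.1)
  expect_equal(fit$ranef_sd, 5, tolerance = 0.5 * 5)
  expect_true(est$ci_lo < est$estimate && est$estimate < est$ci_hi)
  expect_gt(fit$sigma, 0)
  expect_false(fit$singular)
})

test_that("with independent errors the estimated AR(1) correlation is near zero", {
  d <- sim_lmm_data(n_part = 10, n_stim = 2, n_time = 200, beta = 1,
                    rho = 0, sigma = 2, tau = 3, seed = 7)
  fit <- fit_lmm_ar1(d, "response", "x")
  expect_lt(abs(fit$rho), 0.05)
})

test_that("without random effect and AR(1), fit_lmm_ar1 equals ordinary least squares", {
  d <- sim_lmm_data(n_part = 4, n_stim = 2, n_time = 60, seed = 3)
  d$x2 <- rnorm(nrow(d))
  fit <- fit_lmm_ar1(d, "response", c("x", "x2"), group = NULL, ar1 = FALSE,
                     series = c("participant", "stimulus"))
  ols <- stats::lm(response ~ x + x2, data = d)
  expect_lt(max(abs(fit$fixed$estimate - coef(ols))), 1e-6)
})

test_that("degenerate designs are rejected with diagnostics", {
  d <- sim_lmm_data(seed = 5)
  d$const <- 1
  expect_error(fit_lmm_ar1(d, "response", "const"), "degenerate")
  expect_error(fit_lmm_ar1(d[d$participant == "p01", ], "response", "x"),
               "2 levels")
})

test_that("VIF matches the closed form and a brute-force oracle", {
  n <- 400
  x1 <- rep(c(-1, 1), n / 2)
  x2 <- rep(c(-1, 1), each = n / 2)  # exactly orthogonal to x1
  d <- data.frame(x1 = x1, x2 = x2)
  expect_equal(unname(compute_vif(d, c("x1", "x2"))), c(1, 1),
               tolerance = 1e-12)

  # two predictors with empirical r = 0.8 -> VIF = 1/(1 - 0.64) = 2.78
  set.seed(19)
  z1 <- scale(rnorm(n))[, 1]
  z2r <- scale(stats::resid(lm(rnorm(n) ~ z1)))[, 1]
  d2 <- data.frame(a = z1, b = 0.8 * z1 + sqrt(1 - 0.64) * z2r)
  expect_equal(unname(compute_vif(d2, c("a", "b"))),
               rep(1 / (1 - 0.64), 2), tolerance = 1e-9)

  set.seed(23)
  d3 <- data.frame(p = rnorm(n), q = rnorm(n), r = rnorm(n))
  d3$q <- d3$q + 0.5 * d3$p
  d3$y <- rnorm(n)
  got <- compute_vif(d3, c("p", "q", "r"))
  oracle <- unname(car::vif(lm(y ~ p + q + r, data = d3)))
  expect_equal(unname(got), oracle, tolerance = 1e-9)

  d3$s <- 2 * d3$p  # perfect collinearity
  expect_equal(unname(compute_vif(d3, c("p", "s"))[1]), Inf)
  expect_error(compute_vif(d3, "p"), "2 predictors")
  d3$c0 <- 3
  expect_error(compute_vif(d3, c("p", "c0")), "constant")
})

test_that("CV folds partition participants with sizes differing by at most one", {
  cfg <- sim_config(seed = 31, duration = 12, n_sync = 6, chord_sync = 5,
                    noise_sd = 4)
  fx <- make_ao_features(cfg, n_stimuli = 2, feature_seed = 31)
  tabs <- make_ao_tables(cfg, fx, n_participants = 13, rating_seed = 32)
  cv <- lag_crossvalidation(tabs, K = 5, seed = 9)
  folds <- cv$folds
  expect_setequal(names(folds), sprintf("p%02d", 1:13))
  sizes <- table(folds)
  expect_lte(diff(range(sizes)), 1)
  expect_true(all(cv$table$mae <= cv$table$rmse))
  expect_true(cv$selected_lag %in% c(1, 2, 3))
})

test_that("leave-one-participant-out is the K = n boundary of the fold scheme", {
  cfg <- sim_config(seed = 33, duration = 10, n_sync = 5, chord_sync = 4)
  fx <- make_ao_features(cfg, n_stimuli = 1, feature_seed = 33)
  tabs <- make_ao_tables(cfg, fx, n_participants = 5, rating_seed = 34,
                         lags = c(1, 2))
  cv <- lag_crossvalidation(tabs, K = 5, seed = 1)
  expect_equal(sort(unique(unname(cv$folds))), 1:5)
  expect_true(all(table(cv$folds) == 1))
  expect_error(lag_crossvalidation(tabs, K = 6, seed = 1), "K participants")
})

test_that("battery runs one fit per modality x group and flags at alpha = 0.0125", {
  d <- sim_lmm_data(n_part = 6, n_stim = 2, n_time = 80, beta = 1.5, seed = 13)
  names(d)[names(d) == "x"] <- "log_intensity"
  d$background <- ifelse(d$participant <= "p03", "novice", "semipro")
  d$instrument <- "none"
  b <- run_togetherness_models(list(AO = d), groups = c("a", "b"))
  expect_length(b$fits, 2)
  expect_setequal(names(b$fits), c("1a", "1b"))
  s <- b$summary
  expect_equal(unname(s$significant), unname(s$p < 0.0125))
  expect_error(run_togetherness_models(list(AO = d[d$background == "x", ])),
               "empty|2 levels")
})

test_that("sync models recover a negative asynchrony slope and reject constant input", {
  set.seed(17)
  n_part <- 8; n_pts <- 48
  rows <- list()
  for (p in seq_len(n_part)) {
    b0 <- rnorm(1, 0, 3)
    asy <- abs(rnorm(n_pts, 0, 150))
    rows[[p]] <- data.frame(
      participant = sprintf("p%02d", p), stimulus = "s1", modality = "AV",
      sync_index = seq_len(n_pts), t_ref = seq_len(n_pts),
      asynchrony_ms = asy, abs_ms = asy,
      rating = 60 + b0 - 0.01 * asy + rnorm(n_pts, 0, 2),
      background = if (p <= 4) "novice" else "semipro",
      instrument = "none")
  }
  d <- do.call(rbind, rows)
  m <- run_sync_models(d, groups = c("a", "b"))
  slopes <- m$summary[m$summary$term == "abs_ms", ]
  expect_true(all(slopes$estimate < 0))
  expect_equal(mean(slopes$estimate), -0.01, tolerance = 0.3)

  d0 <- d
  d0$abs_ms <- 100
  expect_error(run_sync_models(d0, groups = "a"), "constant")
  d1 <- d
  d1$sync_index <- 1
  expect_error(run_sync_models(d1[d1$sync_index == 1 &
                                    d1$t_ref == 1, ], groups = "a"),
               "sync points")
})

test_that("factorial ANOVA matches a hand-computed sums-of-squares oracle", {
  # balanced 2 x 3 design with known cell means
  set.seed(25)
  d <- expand.grid(background = c("novice", "semipro"),
                   modality = c("AO", "VO", "AV"), rep = 1:20)
  cell_mean <- with(d, 50 + 5 * (background == "novice") +
                      3 * (modality == "AV"))
  d$mean_rating <- cell_mean + rnorm(nrow(d), 0, 2)
  res <- anova_mean_ratings(d, c("background", "modality"))

  # oracle: explicit between/within sums of squares
  grand <- mean(d$mean_rating)
  ss <- function(groups) {
    agg <- tapply(d$mean_rating, groups, mean)
    cnt <- tapply(d$mean_rating, groups, length)
    sum(cnt * (agg - grand)^2)
  }
  ss_a <- ss(d$background)
  ss_b <- ss(d$modality)
  ss_cells <- ss(interaction(d$background, d$modality))
  ss_ab <- ss_cells - ss_a - ss_b
  ss_res <- sum((d$mean_rating -
                   ave(d$mean_rating,
                       interaction(d$background, d$modality)))^2)
  df_res <- nrow(d) - 6
  f_oracle <- c(ss_a / 1, ss_b / 2, ss_ab / 2) / (ss_res / df_res)
  expect_equal(res$anova$F, f_oracle, tolerance = 1e-9)
  expect_equal(res$anova$df_res[1], df_res)
})

test_that("two-group Tukey HSD reduces to the unadjusted t-test", {
  set.seed(27)
  d <- data.frame(background = rep(c("novice", "semipro"), each = 15))
  d$mean_rating <- 50 + 4 * (d$background == "novice") + rnorm(30, 0, 3)
  res <- anova_mean_ratings(d, "background", tukey = "background")
  tt <- t.test(mean_rating ~ background, data = d, var.equal = TRUE)
  expect_equal(res$tukey$background$p_adj, tt$p.value, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("under identical cell distributions ANOVA p-values are uniform", {
  set.seed(29)
  ps <- replicate(200, {
    d <- expand.grid(background = c("a", "b"), modality = c("x", "y", "z"),
                     rep = 1:6)
    d$mean_rating <- rnorm(nrow(d), 50, 5)
    anova_mean_ratings(d, c("background", "modality"))$anova$p[1]
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("body-part comparison recovers a doubled-amplitude part", {
  set.seed(35)
  rows <- list()
  for (s in 1:4) {
    b0 <- rnorm(1, 0, 1)
    for (p in c("head", "chest", "r_arm")) {
      mu <- if (p == "head") 8 else 4
      e <- as.numeric(stats::filter(rnorm(80, 0, 1), 0.4, method = "recursive"))
      rows[[paste(s, p)]] <- data.frame(stimulus = paste0("s", s), part = p,
                                        t = (0:79) / 10,
                                        value = mu + b0 + e)
    }
  }
  d <- do.call(rbind, rows)
  res <- compare_body_parts(d)
  means <- res$means
  expect_gt(means$emmean[means$part == "head"],
            max(means$emmean[means$part != "head"]))
  head_contrasts <- res$contrasts[grepl("head", res$contrasts$contrast), ]
  expect_true(all(head_contrasts$p.value < 0.01))

  # two parts reduce to a paired comparison; sign matches the group means
  d2 <- d[d$part != "r_arm", ]
  res2 <- compare_body_parts(d2)
  expect_equal(nrow(res2$contrasts), 1)
  expect_equal(sign(res2$contrasts$estimate[1]),
               sign(mean(d2$value[d2$part == "chest"]) -
                      mean(d2$value[d2$part == "head"])) *
                 (if (grepl("^chest", res2$contrasts$contrast[1])) 1 else -1))
  expect_error(compare_body_parts(d[d$part == "head", ]), "2 body parts")
})
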