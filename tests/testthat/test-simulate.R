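mini_cfg <- function(...) {
  sim_config(seed = 1, n_novices = 2, n_pianists = 1, n_clarinetists = 1,
             n_stimuli = 1, duration = 10, mocap_rate = 60, n_sync = 5,
             chord_sync = 4, gaze_rate = 30, ...)
}

test_that("fully coupled, noise-free partners move identically up to amplitude scale", {
  cfg <- mini_cfg(kappa = 1, noise_frac = 0)
  rec <- simulate_duo_motion(cfg, "s1", "piano", seed = 2)
  p <- rec$trajectories$P_head$xyz
  s <- rec$trajectories$S_head$xyz
  p_c <- sweep(p, 2, colMeans(p))
  s_c <- sweep(s, 2, colMeans(s))
  expect_lt(max(abs(s_c - 0.9 * p_c)), 1e-9)
})

test_that("uncoupled partners are indistinguishable from a time-reversed surrogate", {
  cfg <- sim_config(seed = 1, duration = 20, mocap_rate = 60, kappa = 0,
                    noise_frac = 0.1)
  rec <- simulate_duo_motion(cfg, "s1", "piano", seed = 6)
  grid <- period_grid(0.3, 5, res = 10)
  cs <- coordination_series(rec, "head", grid)
  surro <- rec
  surro$trajectories$S_head$xyz <-
    surro$trajectories$S_head$xyz[rev(seq_len(nrow(surro$trajectories$S_head$xyz))), ]
  cs_s <- coordination_series(surro, "head", grid, period = cs$dominant_period)
  ratio <- stats::median(cs$power) / stats::median(cs_s$power)
  expect_gt(ratio, 1 / 3)
  expect_lt(ratio, 3)
})

test_that("coupling only at the arms puts the arm pairs on top of the power ranking", {
  kap <- c(head = 0, chest = 0, l_shoulder = 0, r_shoulder = 0,
           l_arm = 0.95, r_arm = 0.95)
  amp <- c(head = 10, r_arm = 10, l_arm = 10, r_shoulder = 10,
           l_shoulder = 10, chest = 10, l_hand = 5, r_hand = 5,
           instrument = 5)
  per <- c(head = 1.1, chest = 1.1, l_shoulder = 1.1, r_shoulder = 1.1,
           l_arm = 1.1, r_arm = 1.1, l_hand = 0.5, r_hand = 0.45,
           instrument = 1.1)
  cfg <- sim_config(seed = 2, duration = 20, mocap_rate = 60, kappa = kap,
                    amplitude_mm = amp, base_period_s = per, noise_frac = 0.1)
  rec <- simulate_duo_motion(cfg, "s1", "piano", seed = 12)
  grid <- period_grid(0.3, 5, res = 10)
  pw <- vapply(coordination_parts(), function(p) {
    mean(coordination_series(rec, p, grid)$power)
  }, 0)
  expect_setequal(names(sort(pw, decreasing = TRUE))[1:2],
                  c("l_arm", "r_arm"))
})

test_that("asynchrony scale is controlled by sigma and chords use latest onsets", {
  cfg0 <- mini_cfg(sigma_async_ms = c(piano = 0, clarinet = 0))
  ev0 <- simulate_onsets(cfg0, "piano", seed = 3)
  expect_true(all(note_asynchronies(ev0)$abs_ms < 1e-9))

  # folded-normal mean at sigma = 150 ms over many draws
  cfg1 <- sim_config(seed = 1, duration = 200, n_sync = 64,
                     chord_sync = integer(0),
                     sigma_async_ms = c(piano = 150, clarinet = 150))
  set.seed(4)
  abs_ms <- unlist(lapply(1:40, function(i) {
    note_asynchronies(simulate_onsets(cfg1, "piano"))$abs_ms
  }))
  expect_equal(mean(abs_ms), 150 * sqrt(2 / pi), tolerance = 0.05)

  ev <- simulate_onsets(mini_cfg(), "piano", seed = 5)
  chord <- ev[ev$sync_index == 4, ]
  expect_gt(nrow(chord), 2)  # chord point carries several notes per part
  a <- note_asynchronies(ev)
  ref_p <- max(chord$onset_s[chord$part == "P"])
  ref_s <- max(chord$onset_s[chord$part == "S"])
  expect_equal(a$asynchrony_ms[a$sync_index == 4], (ref_s - ref_p) * 1000,
               tolerance = 1e-9)
})

test_that("mean |asynchrony| responds monotonically to sigma", {
  sigmas <- c(20, 60, 120, 200, 300)
  set.seed(9)
  m <- vapply(sigmas, function(sg) {
    cfg <- sim_config(seed = 1, duration = 120, n_sync = 32,
                      chord_sync = integer(0),
                      sigma_async_ms = c(piano = sg, clarinet = sg))
    mean(unlist(lapply(1:8, function(i) {
      note_asynchronies(simulate_onsets(cfg, "piano"))$abs_ms
    })))
  }, 0)
  expect_equal(stats::cor(m, sigmas, method = "spearman"), 1)
})

test_that("extracted coordination power increases with the coupling strength", {
  kappas <- c(0, 0.25, 0.5, 0.75, 1)
  grid <- period_grid(0.4, 4, res = 8)
  set.seed(13)
  mean_power <- vapply(kappas, function(k) {
    mean(vapply(1:20, function(r) {
      cfg <- sim_config(seed = 1, duration = 15, mocap_rate = 60, kappa = k,
                        noise_frac = 0.1)
      rec <- simulate_duo_motion(cfg, paste0("s", r), "piano")
      mean(coordination_series(rec, "head", grid)$power)
    }, 0))
  }, 0)
  expect_gte(stats::cor(mean_power, kappas, method = "spearman"), 0.9)
})

test_that("ratings respond to a feature step at the true lag and stay silent when null", {
  cfg <- mini_cfg(true_lag_s = 2, noise_sd = 0, slider_threshold = 1,
                  beta = list(novice = c(intensity = 5)))
  n <- 100
  feats <- data.frame(t = (0:(n - 1)) / 10,
                      intensity = c(rep(0.2, 50), rep(0.8, 50)),
                      abs_async = 0)
  s <- simulate_ratings(cfg, feats, "p1", "novice", "s1", "AO")
  # one initial adjustment away from the center, then the step response
  expect_equal(nrow(s$events), 2)
  expect_equal(s$events$t[2], 5 + 2, tolerance = 0.1)  # step at 5 s + 2 s lag
  expect_gt(s$events$value[2], s$events$value[1])

  cfg0 <- mini_cfg(noise_sd = 0, beta = list(novice = numeric(0)))
  s0 <- simulate_ratings(cfg0, feats, "p1", "novice", "s1", "AO")
  expect_equal(nrow(s0$events), 0)
  expect_equal(s0$trial_status, "no_change")
})

test_that("modality gates which cues reach the ratings", {
  cfg <- mini_cfg(noise_sd = 0, slider_threshold = 0.5,
                  beta = list(novice = c(intensity = 5)))
  feats <- data.frame(t = (0:99) / 10,
                      intensity = c(rep(0.2, 50), rep(0.8, 50)),
                      abs_async = 0)
  vo <- simulate_ratings(cfg, feats, "p1", "novice", "s1", "VO")
  expect_equal(nrow(vo$events), 0)  # intensity is inaudible in video-only
  ao <- simulate_ratings(cfg, feats, "p1", "novice", "s1", "AO")
  expect_gt(nrow(ao$events), 0)
})

test_that("rendered audio round-trips through the RMS envelope", {
  cfg <- mini_cfg()
  ev <- simulate_onsets(cfg, "piano", seed = 15)
  out <- simulate_intensity(cfg, ev, seed = 16, render_audio = TRUE)
  env_back <- rms_envelope(out$audio)
  n <- min(length(env_back$values), length(out$envelope$values))
  expect_gt(stats::cor(env_back$values[2:(n - 1)],
                       out$envelope$values[2:(n - 1)]), 0.95)
})

test_that("study bundles are byte-identical under a fixed seed", {
  cfg <- mini_cfg(simulate_gaze = FALSE)
  d1 <- file.path(withr::local_tempdir(), "a")
  d2 <- file.path(withr::local_tempdir(), "b")
  generate_study(cfg, d1)
  generate_study(cfg, d2)
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_identical(f1, f2)
  for (f in f1) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))),
                     label = f)
  }
  expect_error(generate_study(cfg, d1), "exists")
})

test_that("the generated bundle matches the configured design and round-trips", {
  cfg <- mini_cfg()
  d <- file.path(withr::local_tempdir(), "bundle")
  generate_study(cfg, d)
  st <- read_study(d)
  expect_equal(nrow(st$participants), 4)
  expect_equal(length(st$recordings), 2)  # 1 stimulus x 2 groups
  # 4 participants x 2 stimuli x 3 modalities + repeats of the 2 stimuli
  n_expected <- 4 * 2 * 3 + 4 * 2
  expect_equal(length(st$streams), n_expected)
  expect_equal(st$manifest$truth$true_lag_s, 1)
  expect_named(st$manifest$truth$beta, c("novice", "semipro"))
  rec <- st$recordings[[1]]
  expect_s3_class(rec, "duo_recording")
  expect_equal(rec$rate, 60)
  expect_equal(unique(vapply(st$fixations$aoi, function(a) {
    a %in% c(aoi_levels(), "none")
  }, TRUE)), TRUE)
})
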