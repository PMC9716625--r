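test_that("marker trajectories round-trip through CSV and honour the shape contract", {
  rate <- 240
  n <- rate * 10
  t <- (seq_len(n) - 1) / rate
  traj <- list()
  for (id in c("P_head", "P_chest", "S_head")) {
    xyz <- cbind(sin(t) * 10, cos(t) * 5, 1000 + t)
    traj[[id]] <- marker_trajectory(id, xyz, rate)
  }
  path <- withr::local_tempfile(fileext = ".csv")
  write_marker_trajectories(traj, path)
  back <- read_marker_trajectories(path, rate)
  expect_length(back, 3)
  expect_true(all(vapply(back, function(tr) nrow(tr$xyz), 0L) == 2400))
  for (id in names(traj)) {
    expect_equal(back[[id]]$xyz, traj[[id]]$xyz, ignore_attr = TRUE,
                 tolerance = 1e-12)
  }
})

test_that("short mocap gaps are interpolated, long gaps rejected", {
  rate <- 240
  n <- 1000
  t <- (seq_len(n) - 1) / rate
  base <- data.frame(time = t, m_x = seq_len(n) * 1.0, m_y = 0, m_z = 0)

  with_gap <- base
  with_gap$m_x[101:105] <- NA  # 5-sample gap, below max_gap = 12
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(with_gap, path, row.names = FALSE)
  got <- read_marker_trajectories(path, rate)
  expect_equal(got$m$xyz[101:105, 1], 101:105, tolerance = 1e-9)

  long_gap <- base
  long_gap$m_x[201:700] <- NA  # 500 samples
  utils::write.csv(long_gap, path, row.names = FALSE)
  expect_error(read_marker_trajectories(path, rate), "gap too long")
})

test_that("malformed marker files are rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(time = c(0, 1 / 240, 3 / 240, 4 / 240),
                              m_x = 1, m_y = 1, m_z = 1),
                   path, row.names = FALSE)
  expect_error(read_marker_trajectories(path, 240), "non-uniform")

  utils::write.csv(data.frame(time = (0:9) / 240, m_x = 1, m_y = 1),
                   path, row.names = FALSE)
  expect_error(read_marker_trajectories(path, 240), "triple")

  utils::write.csv(data.frame(time = (0:9) / 240, m_x = NA_real_,
                              m_y = NA_real_, m_z = NA_real_),
                   path, row.names = FALSE)
  expect_error(read_marker_trajectories(path, 240), "all-NaN|gap")
})

test_that("note events: 16 sync points x 2 parts read as 32 grouped events", {
  ev <- events_from_asynchronies(rep(c(-30, 40), 8))
  path <- withr::local_tempfile(fileext = ".csv")
  write_note_events(ev, path)
  got <- read_note_events(path)
  expect_equal(nrow(got), 32)
  expect_setequal(unique(got$part), c("P", "S"))
  expect_setequal(got$sync_index, 1:16)

  # chord rows sharing a chord_group are both retained and grouped
  chord <- data.frame(part = c("P", "P", "S"), sync_index = 5,
                      onset_s = c(5.00, 5.02, 5.01), chord_group = "c05")
  write_note_events(chord, path)
  got2 <- read_note_events(path)
  expect_equal(nrow(got2), 3)
  expect_true(all(got2$chord_group == "c05"))
})

test_that("note events reject unmatched sync points and negative onsets; empty file warns", {
  path <- withr::local_tempfile(fileext = ".csv")
  bad <- data.frame(part = c("P", "S"), sync_index = c(1, 2),
                    onset_s = c(1, 2), chord_group = NA)
  write_note_events(bad, path)
  expect_error(read_note_events(path), "only one part")

  neg <- data.frame(part = c("P", "S"), sync_index = 1,
                    onset_s = c(-0.5, 0.2), chord_group = NA)
  write_note_events(neg, path)
  expect_error(read_note_events(path), "negative")

  writeLines("part,sync_index,onset_s,chord_group", path)
  expect_warning(empty <- read_note_events(path), "empty")
  expect_equal(nrow(empty), 0)
})

# minimal format-1 SMF writer used only as a test fixture
write_test_smf <- function(path, onsets_p, onsets_s, division = 480,
                           tempo = 500000) {
  vlq <- function(x) {
    out <- as.raw(x %% 128)
    x <- x %/% 128
    while (x > 0) {
      out <- c(as.raw(128 + x %% 128), out)
      x <- x %/% 128
    }
    out
  }
  be <- function(x, n) as.raw(rev((x %/% 256^(0:(n - 1))) %% 256))
  track <- function(onsets, with_tempo = FALSE) {
    body <- raw(0)
    if (with_tempo) {
      body <- c(body, vlq(0), as.raw(c(0xFF, 0x51, 0x03)), be(tempo, 3))
    }
    prev <- 0
    for (on in onsets) {
      tick <- round(on * division * 1e6 / tempo)
      body <- c(body, vlq(tick - prev), as.raw(c(0x90, 60, 100)),
                vlq(10), as.raw(c(0x80, 60, 0)))
      prev <- tick + 10
    }
    body <- c(body, vlq(0), as.raw(c(0xFF, 0x2F, 0x00)))
    c(charToRaw("MTrk"), be(length(body), 4), body)
  }
  hdr <- c(charToRaw("MThd"), be(6, 4), be(1, 2), be(2, 2), be(division, 2))
  writeBin(c(hdr, track(onsets_p, TRUE), track(onsets_s)), path)
}

test_that("Standard MIDI File adapter extracts annotated sync onsets", {
  path <- withr::local_tempfile(fileext = ".mid")
  onsets_p <- c(1.0, 2.5, 4.0)
  onsets_s <- c(1.05, 2.45, 4.02)
  write_test_smf(path, onsets_p, onsets_s)
  sync_table <- data.frame(part = rep(c("P", "S"), each = 3),
                           note_index = rep(1:3, 2),
                           sync_index = rep(1:3, 2))
  got <- read_note_events(path, sync_table = sync_table)
  expect_equal(nrow(got), 6)
  tick <- 500000 / (480 * 1e6)  # seconds per tick
  expect_equal(got$onset_s[got$part == "P"], onsets_p, tolerance = tick * 2)
  expect_equal(got$onset_s[got$part == "S"], onsets_s, tolerance = tick * 2)
  expect_error(read_note_events(path), "sync_table")
})

test_that("slider logs split into streams with partial/repeat/no-change flags", {
  df <- rbind(
    data.frame(participant = "p1", stimulus = "s1", modality = "AO",
               presentation = 1, load = 1, t = c(1.1, 2.0), value = c(60, 70)),
    data.frame(participant = "p1", stimulus = "s2", modality = "AV",
               presentation = 1, load = c(1, 2, 2), t = c(0.5, 0.8, 1.9),
               value = c(40, 55, 52)),
    data.frame(participant = "p2", stimulus = "s1", modality = "AO",
               presentation = 2, load = 1, t = 3.0, value = 20))
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  trials <- rbind(unique(df[c("participant", "stimulus", "modality",
                              "presentation")]),
                  data.frame(participant = "p3", stimulus = "s1",
                             modality = "VO", presentation = 1))
  got <- read_slider_events(path, trials = trials)
  status <- vapply(got, function(s) s$trial_status, character(1))
  expect_equal(sum(status == "partial"), 1)   # first load of the double-load
  expect_equal(sum(status == "no_change"), 1) # roster-only trial
  pres <- vapply(got, function(s) s$presentation, integer(1))
  expect_equal(sum(pres == 2), 1)
  partial <- got[[which(status == "partial")]]
  expect_equal(nrow(partial$events), 1)       # only the interrupted first load
})

test_that("slider validation rejects out-of-bounds values and unknown modalities", {
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(participant = "p1", stimulus = "s1",
                              modality = "AO", t = 1, value = 130),
                   path, row.names = FALSE)
  expect_error(read_slider_events(path), "bounds")
  utils::write.csv(data.frame(participant = "p1", stimulus = "s1",
                              modality = "XX", t = 1, value = 50),
                   path, row.names = FALSE)
  expect_error(read_slider_events(path), "modality")
  expect_error(slider_stream("p", "s", "AO",
                             data.frame(t = c(2, 1), value = c(50, 60))),
               "increasing")
})
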