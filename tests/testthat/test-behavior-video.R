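make_blob_frames <- function(positions, h = 48, w = 64, intensity = 200) {
  yy <- matrix(seq_len(h), h, w); xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  frames <- array(0, dim = c(h, w, length(positions)))
  for (f in seq_along(positions)) {
    p <- positions[[f]]
    frames[, , f] <- 30 + intensity *
      exp(-((yy - p[1])^2 + (xx - p[2])^2) / (2 * 3^2))
  }
  frames
}

test_that("frame differencing flags translated blobs and ignores noise", {
  # identical frames: nothing moves
  fr <- make_blob_frames(list(c(24, 32), c(24, 32)))
  expect_equal(quantify_movement(fr, fps = 30)$moved, c(0L, 0L))
  # blob translated by 5 px: second frame moves, and the changed area
  # exceeds the threshold by brute-force pixel count
  fr2 <- make_blob_frames(list(c(24, 30), c(24, 35)))
  delta <- abs(fr2[, , 2] - fr2[, , 1])
  expect_gt(sum(delta > 25), 8)
  expect_equal(quantify_movement(fr2, fps = 30)$moved, c(0L, 1L))
  # sub-threshold pixel noise stays still
  set.seed(1)
  fr3 <- array(100 + rnorm(48 * 64 * 5, sd = 4), dim = c(48, 64, 5))
  expect_equal(quantify_movement(fr3, pixel_threshold = 25, fps = 30)$moved,
               rep(0L, 5))
  expect_error(quantify_movement(array(0, c(4, 4, 1)), fps = 30), "2 frames")
})

test_that("pruning removes short movement runs and is idempotent", {
  tr <- movement_trace(c(0L, 1L, 0L), fps = 1)
  expect_equal(prune_movement(tr, 2)$moved, c(0L, 0L, 0L))
  tr2 <- movement_trace(c(1L, 1L, 1L), fps = 1)
  expect_equal(prune_movement(tr2, 2)$moved, c(1L, 1L, 1L))
  set.seed(2)
  for (i in 1:10) {
    tr3 <- movement_trace(rbinom(200, 1, 0.4), fps = 10)
    expect_equal(prune_movement(tr3, 1)$moved, tr3$moved) # min_run 1 no-op
    once <- prune_movement(tr3, 7)
    expect_equal(prune_movement(once, 7)$moved, once$moved) # idempotent
  }
})

test_that("the 5-minute immobility rule segments sleep bouts", {
  fps <- 2
  # immobile 0-360 s then movement
  tr <- movement_trace(c(rep(0L, 360 * fps), rep(1L, 60 * fps)), fps)
  b <- label_states(tr)
  sleep <- b[b$kind == "sleep", ]
  expect_equal(nrow(sleep), 1)
  expect_equal(c(sleep$start_s, sleep$end_s), c(0, 360))
  # 240 s immobility is below threshold
  tr2 <- movement_trace(c(rep(0L, 240 * fps), rep(1L, 120 * fps)), fps)
  expect_equal(sum(label_states(tr2)$kind == "sleep"), 0)
  # bouts cover the recording without overlap
  expect_equal(b$start_s[-1], b$end_s[-nrow(b)])
  # day flag follows bout onset: bout starting 19:55, lights off 20:00
  tr3 <- movement_trace(c(rep(1L, 60 * fps), rep(0L, 900 * fps),
                          rep(1L, 60 * fps)), fps)
  b3 <- label_states(tr3, clock_start = "19:54")
  expect_true(b3$day_flag[b3$kind == "sleep"]) # onset 19:55 is still day
})

test_that("stage partition follows the printed 2-minute windows", {
  mk_bouts <- function(a, b, dur) {
    bouts <- data.frame(start_s = c(0, a, b), end_s = c(a, b, dur),
                        kind = c("awake", "sleep", "awake"))
    attr(bouts, "clock_start") <- "08:00"
    class(bouts) <- c("bout_set", "data.frame")
    bouts
  }
  st <- segment_sleep_epochs(mk_bouts(300, 900, 1500), 1500)
  get <- function(stage) unlist(st[st$stage == stage, c("start_s", "end_s")],
                                use.names = FALSE)
  expect_equal(get("presleep"), c(180, 300))
  expect_equal(get("earlysleep"), c(300, 420))
  expect_equal(get("midsleep"), c(420, 780))
  expect_equal(get("latesleep"), c(780, 900))
  expect_equal(get("pre2_probe"), c(60, 180))
  expect_equal(get("post2_probe"), c(900, 1020))
  # a 300-s bout leaves a 60-s midsleep
  st2 <- segment_sleep_epochs(mk_bouts(400, 700, 1200), 1200)
  mid <- st2[st2$stage == "midsleep", ]
  expect_equal(mid$end_s - mid$start_s, 60)
  # bout at recording start: presleep truncated and flagged partial
  st3 <- segment_sleep_epochs(mk_bouts(60, 460, 900), 900)
  pre <- st3[st3$stage == "presleep", ]
  expect_equal(c(pre$start_s, pre$end_s), c(0, 60))
  expect_true(pre$partial)
})

test_that("stage windows partition each bout exactly", {
  for (seed in 1:4) {
    cfg <- session_config(duration = 5400, seed = seed)
    b <- flysleeplfp:::with_seed(seed,
                                 flysleeplfp:::simulate_bout_sequence(cfg))
    attr(b, "clock_start") <- "08:00"
    class(b) <- c("bout_set", "data.frame")
    st <- segment_sleep_epochs(b, cfg$duration)
    for (id in stats::na.omit(unique(st$bout_id))) {
      bi <- st[!is.na(st$bout_id) & st$bout_id == id, ]
      core <- bi[bi$stage %in% c("earlysleep", "midsleep", "latesleep"), ]
      core <- core[order(core$start_s), ]
      # disjoint and tiling the bout
      expect_equal(core$start_s[-1], core$end_s[-nrow(core)])
      expect_equal(min(core$start_s), bi$bout_start[1])
      expect_equal(max(core$end_s), bi$bout_end[1])
      pre <- bi[bi$stage == "presleep", ]
      if (nrow(pre)) expect_lte(pre$end_s, bi$bout_start[1])
    }
  }
})

test_that("the full movement pipeline recovers ground-truth bouts", {
  cfg <- session_config(duration = 1500, fps_video = 5, seed = 4)
  s <- generate_session(cfg, components = c("movement", "frames"))
  mt <- quantify_movement(s$frames, fps = cfg$fps_video)
  pr <- prune_movement(mt, min_run_frames = 3)
  det <- label_states(pr, cfg$clock_start)
  det <- det[det$kind == "sleep", ]
  tru <- s$truth$bouts[s$truth$bouts$kind == "sleep", ]
  expect_equal(nrow(det), nrow(tru)) # no spurious bouts
  expect_true(all(abs(det$start_s - tru$start_s) < 2))
  expect_true(all(abs(det$end_s - tru$end_s) < 2))
})

test_that("crepuscular z-profile peaks at dawn and uses the printed bins", {
  # constant movement: zero variance convention
  tr <- movement_trace(rep(1L, 600), fps = 1)
  expect_warning(cp <- crepuscular_profile(tr, "05:00"), "zero variance")
  expect_true(all(cp$z == 0))
  # clock binning: a minute at 6:30 a.m. is predawn
  cp2 <- suppressWarnings(crepuscular_profile(tr, "06:30"))
  expect_equal(as.character(cp2$period[1]), "predawn")
  # generator cohort: dawn multiplier raises z relative to predawn
  zdiff <- vapply(1:3, function(i) {
    cfg <- session_config(duration = 6 * 3600, clock_start = "05:00",
                          seed = 600 + i)
    s <- generate_session(cfg, components = "movement")
    cp <- crepuscular_profile(session_movement_trace(s), cfg$clock_start)
    mean(cp$z[cp$period == "dawn"], na.rm = TRUE) -
      mean(cp$z[cp$period == "predawn"], na.rm = TRUE)
  }, numeric(1))
  expect_gt(mean(zdiff), 0)
})

test_that("night sleep bouts run longer than day bouts as configured", {
  day_d <- c(); night_d <- c()
  for (seed in 1:10) {
    cfg <- session_config(duration = 8 * 3600, clock_start = "14:00",
                          seed = seed)
    b <- flysleeplfp:::with_seed(seed,
                                 flysleeplfp:::simulate_bout_sequence(cfg))
    sl <- b[b$kind == "sleep", ]
    if (!nrow(sl)) next
    day <- flysleeplfp:::is_day(sl$start_s, cfg$clock_start)
    day_d <- c(day_d, (sl$end_s - sl$start_s)[day])
    night_d <- c(night_d, (sl$end_s - sl$start_s)[!day])
  }
  expect_gt(stats::median(night_d), stats::median(day_d))
})
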