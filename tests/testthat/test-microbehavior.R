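toy_pose <- function(n = 600, fps = 30) {
  s <- generate_session(session_config(duration = n / fps, seed = 77),
                        components = "pose")
  s$pose
}

test_that("pose filtering keeps constants and attenuates fast motion", {
  tr <- toy_pose()
  tr$eye_x <- rep(3, nrow(tr)) # constant trace passes through unchanged
  f <- filter_pose(tr)
  interior <- 100:(nrow(tr) - 100)
  expect_true(all(abs(f$eye_x_lp[interior] - 3) < 1e-3))
  expect_true(all(abs(f$eye_x_ma - 3) < 1e-9))
  # 5-sample moving average of an impulse of height 5 has center 1
  imp <- rep(0, 21); imp[11] <- 5
  ma <- stats::filter(imp, rep(1 / 5, 5), sides = 2)
  expect_equal(as.numeric(ma[11]), 1)
  # a 2-Hz oscillation is cut by >= 20 dB by the 0.1-Hz low-pass
  tr$eye_x <- sin(2 * pi * 2 * (seq_len(nrow(tr)) - 1) / 30)
  f2 <- filter_pose(tr)
  expect_lt(20 * log10(stats::sd(f2$eye_x_lp) / stats::sd(tr$eye_x)), -20)
  expect_error(filter_pose(tr[1:5, ]), "warm-up")
})

test_that("proboscis-eye distance is likelihood weighted", {
  tr <- data.frame(eye_x = 0, eye_y = 0, proboscis_x = 3, proboscis_y = 4,
                   proboscis_likelihood = 0.5)
  expect_equal(dist_eyeprob(tr), 2.5)
  tr$proboscis_likelihood <- 0
  expect_equal(dist_eyeprob(tr), 0)
  tr$proboscis_x <- 0; tr$proboscis_y <- 0; tr$proboscis_likelihood <- 1
  expect_equal(dist_eyeprob(tr), 0)
  expect_error(dist_eyeprob(data.frame(eye_x = 1)), "missing")
})

test_that("candidate runs become events, bursts and state tags", {
  tr <- toy_pose(1200)
  fps <- 30
  cand <- rep(FALSE, nrow(tr))
  mark <- function(t0) cand[round(t0 * fps) + (-3:3)] <<- TRUE
  for (t0 in c(5, 25, 30, 31.5, 33)) mark(t0)
  states <- data.frame(start_s = c(0, 20), end_s = c(20, 40),
                       kind = c("awake", "sleep"))
  ev <- construct_pe_events(cand, tr, states, fps = fps)
  # events at 5 and 25 are separate bursts; 25..33 share one burst
  expect_equal(nrow(ev$events), 5)
  expect_equal(ev$events$burst_id, c(1, 2, 2, 2, 2))
  expect_equal(ev$bursts$is_single, c(TRUE, FALSE))
  expect_equal(ev$events$state, c("awake", rep("sleep", 4)))
  # events 20 s apart are singleton bursts
  cand2 <- rep(FALSE, nrow(tr))
  cand2[round(0.5 * fps) + (0:3)] <- TRUE
  cand2[round(20.5 * fps) + (0:3)] <- TRUE
  ev2 <- construct_pe_events(cand2, tr, NULL, fps = fps)
  expect_equal(ev2$events$burst_id, c(1, 2))
  expect_true(all(ev2$bursts$is_single))
  # candidate gaps under 0.2 s merge into one event
  cand3 <- rep(FALSE, nrow(tr))
  cand3[100:102] <- TRUE; cand3[105:107] <- TRUE
  ev3 <- construct_pe_events(cand3, tr, NULL, fps = fps)
  expect_equal(nrow(ev3$events), 1)
  empty <- construct_pe_events(rep(FALSE, nrow(tr)), tr, NULL, fps = fps)
  expect_equal(nrow(empty$events), 0)
})

test_that("periodicity flags follow the under-6-second rule", {
  tr <- toy_pose(600)
  fps <- 30
  cand <- rep(FALSE, nrow(tr))
  for (t0 in c(1, 3, 5, 13)) cand[round(t0 * fps) + (0:2)] <- TRUE
  ev <- construct_pe_events(cand, tr, NULL, fps = fps)
  expect_equal(nrow(ev$events), 4) # all within 10 s -> one burst
  st <- pe_statistics(ev$events, ev$bursts)
  # gaps 2, 2, 8: first event inherits its successor's gap
  expect_equal(st$periodic, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(st$n_single, 0)
  expect_equal(st$n_multiple, 1)
  expect_equal(st$intervals, c(2, 2, 8), tolerance = 0.05)
})

test_that("PE statistics summarize segments, singles and depth", {
  res <- fx_pe_results()
  ok <- Filter(function(r) !r$skip, res)
  r <- ok[[1]]
  st <- segment_sleep_epochs(truth_bouts(r$session),
                             r$session$config$duration)
  stats <- pe_statistics(r$events$events, r$events$bursts, st,
                         bouts = truth_bouts(r$session))
  if (!is.null(stats$segment_counts) && sum(stats$segment_counts) > 0) {
    expect_lt(abs(sum(stats$segment_counts) - 1), 1e-9)
  }
  # single event in isolation
  one <- data.frame(peak_frame = 10L, time_s = 1 / 3, state = "sleep",
                    burst_id = 1L)
  oneb <- data.frame(burst_id = 1L, n_events = 1L, is_single = TRUE,
                     start_s = 1 / 3, end_s = 1 / 3)
  s1 <- pe_statistics(one, oneb)
  expect_true(is.na(s1$interval_p95))
  expect_equal(s1$n_single, 1)
})

test_that("midsleep hosts more PE events than flanking segments", {
  res <- fx_pe_results()
  ok <- Filter(function(r) !r$skip, res)
  seg_sum <- NULL
  for (r in ok) {
    st <- segment_sleep_epochs(truth_bouts(r$session),
                               r$session$config$duration)
    s <- pe_statistics(r$events$events, r$events$bursts, st)
    if (!is.null(s$segment_counts) && sum(s$segment_counts) > 0) {
      seg_sum <- rbind(seg_sum, s$segment_counts)
    }
  }
  m <- colMeans(seg_sum)
  expect_gt(m["mid"], max(m[c("+0:+1", "+1:+2", "x:-2", "x:-1")]))
})

test_that("inter-PE intervals recover the configured burst tail", {
  res <- fx_pe_results()
  iv <- unlist(lapply(Filter(function(r) !r$skip, res), function(r) {
    pe_statistics(r$events$events, r$events$bursts)$intervals
  }))
  # configured lognormal: mean 1.5 s, sdlog 0.12 -> 95th pct ~ 1.8 s
  expect_lt(abs(stats::quantile(iv, 0.95) - 1.8), 0.4)
  expect_lt(abs(mean(iv) - 1.5), 0.3)
})

test_that("antennal angles are head-referenced and rotation invariant", {
  n <- 100
  base <- data.frame(
    antennaL_base_x = rep(-10, n), antennaL_base_y = 0,
    antennaR_base_x = rep(10, n), antennaR_base_y = 0,
    antennaR_tip_x = 10, antennaR_tip_y = 12,
    antennaL_tip_x = -10, antennaL_tip_y = 12
  )
  a <- antennal_angle(base)
  expect_equal(a$right, rep(90, n))
  expect_equal(a$left, rep(90, n)) # mirrored convention
  # rotate the whole head by 10 degrees: corrected angles unchanged
  th <- 10 * pi / 180
  rot <- base
  for (p in c("antennaL_base", "antennaR_base", "antennaL_tip",
              "antennaR_tip")) {
    x <- base[[paste0(p, "_x")]]; y <- base[[paste0(p, "_y")]]
    rot[[paste0(p, "_x")]] <- cos(th) * x - sin(th) * y
    rot[[paste0(p, "_y")]] <- sin(th) * x + cos(th) * y
  }
  a2 <- antennal_angle(rot)
  expect_equal(a2$right, a$right, tolerance = 1e-9)
  expect_equal(a2$left, a$left, tolerance = 1e-9)
  # coincident base/tip yields NA
  rot$antennaR_tip_x <- rot$antennaR_base_x
  rot$antennaR_tip_y <- rot$antennaR_base_y
  expect_true(all(is.na(antennal_angle(rot)$right)))
})

test_that("generator antennal oscillations are recovered from the pose", {
  s <- generate_session(session_config(duration = 600, seed = 31),
                        components = c("movement", "pose"))
  ang <- antennal_angle(s$pose)
  t <- (seq_len(nrow(s$pose)) - 1) / s$fps
  ps <- s$truth$periodic_segments
  if (nrow(ps)) {
    i <- which(t >= ps$start_s[1] & t < ps$end_s[1])
    truth_osc <- sin(2 * pi * s$config$antenna$periodic_freq * t[i])
    expect_gt(abs(stats::cor(ang$left[i], truth_osc)), 0.9)
  }
})

test_that("FFT periodicity flags sine segments but not white noise", {
  fps <- 30
  t <- (0:(900 - 1)) / fps
  p <- periodicity_segments(sin(2 * pi * 1 * t), fps)
  expect_true(all(p$segments$periodic))
  expect_equal(p$segments$dominant_freq, rep(1, nrow(p$segments)),
               tolerance = 0.1)
  set.seed(33)
  fp <- mean(vapply(1:60, function(i) {
    any(periodicity_segments(stats::rnorm(900), fps)$segments$periodic)
  }, logical(1)))
  expect_lte(fp, 0.05)
  expect_error(periodicity_segments(stats::rnorm(100), fps, segment_s = 3),
               "too short")
})

test_that("sleep carries more antennal periodicity than wake", {
  fracs <- vapply(1:4, function(i) {
    s <- generate_session(session_config(duration = 2400, seed = 500 + i),
                          components = c("movement", "pose"))
    ang <- antennal_angle(s$pose)
    p <- periodicity_segments(ang$left, s$fps,
                              state_labels = truth_bouts(s))
    c(p$fraction_sleep, p$fraction_wake)
  }, numeric(2))
  expect_gt(mean(fracs[1, ], na.rm = TRUE), mean(fracs[2, ], na.rm = TRUE))
})

test_that("resting-position detection keeps real extensions only", {
  x <- rep(10, 600); y <- rep(5, 600)
  bump <- 8 * sin(pi * seq(0, 1, length.out = 31))
  x[100:130] <- x[100:130] + bump * 0.8
  y[100:130] <- y[100:130] + bump * 0.6
  x[300] <- x[300] + 15 # one-frame tracking spike
  x[450:470] <- x[450:470] + 60 # implausibly distant artifact
  r <- resting_pe_detection(x, y, fps = 30)
  expect_equal(nrow(r$peaks), 1)
  expect_equal(r$peaks$frame, 115, tolerance = 2)
  expect_equal(r$resting, c(10, 5))
  # constant trace: no events
  r0 <- resting_pe_detection(rep(1, 300), rep(1, 300), fps = 30)
  expect_equal(nrow(r0$peaks), 0)
  expect_equal(nrow(r0$crossings), 0)
  # threshold-crossing variant reports duration and angle
  expect_equal(nrow(r$crossings), 2)
  expect_gt(r$crossings$duration_s[1], 0.3)
  expect_lt(r$crossings$duration_s[1], 1.1)
})

test_that("frame classifier plus augmentation recovers events", {
  res <- fx_pe_results()
  ok <- Filter(function(r) !r$skip, res)
  expect_gte(length(ok), 7)
  frame_accs <- vapply(ok, function(r) r$detection$report$accuracy,
                       numeric(1))
  expect_gt(stats::median(frame_accs), 0.8)
  ev_accs <- vapply(ok, function(r) r$match$accuracy, numeric(1))
  expect_gt(stats::median(ev_accs), 0.8)
  # event counts within 10% of truth at the median, peaks within 2 frames
  rel <- vapply(ok, function(r) {
    abs(r$match$n_detected - r$match$n_truth) / r$match$n_truth
  }, numeric(1))
  expect_lte(stats::median(rel), 0.1)
  perr <- unlist(lapply(ok, function(r) r$match$peak_errors_s))
  expect_lt(stats::quantile(abs(perr), 0.9), 2 / 30 + 1e-9)
})

test_that("occluded events are recovered by the likelihood rule", {
  # constructed occlusion: likelihood dip without classifier support is
  # added only when the classifier fires nearby
  s <- generate_session(session_config(duration = 1800, seed = 7),
                        components = c("movement", "pose"))
  tr <- filter_pose(s$pose)
  truth_t <- s$truth$pe_events$time_s
  truth_frames <- unique(unlist(lapply(truth_t, function(t0) {
    round(t0 * s$fps) + (-6:6)
  })))
  det <- detect_pe_frames(tr, truth_frames, seed = 1)
  ev <- construct_pe_events(det$candidates, tr, NULL, fps = s$fps)
  m <- match_pe_events(ev$events$time_s, truth_t)
  expect_equal(m$n_matched, m$n_truth) # including the occluded ones
  # clean stretches (no truth event, no likelihood dip nearby) produce
  # essentially no candidates
  t_frame <- (seq_len(nrow(tr)) - 1) / s$fps
  near_event <- vapply(t_frame, function(t0) {
    any(abs(t0 - truth_t) < 2)
  }, logical(1))
  dip <- tr$proboscis_likelihood < 0.9
  dip_near <- stats::filter(as.integer(dip), rep(1, 61), sides = 2)
  clean <- !near_event & (is.na(dip_near) | dip_near == 0)
  expect_lt(mean(det$candidates[clean]), 0.002)
})
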