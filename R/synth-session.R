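#' Configuration for a synthetic recording session
#'
#' Builds and validates the parameter set that drives [generate_session()].
#' Defaults encode the study conditions the downstream analyses assume: a
#' 16-channel linear probe with the polarity reversal near channel 11,
#' broadband (5-40 Hz) LFP power higher during wake than sleep, a central
#' channel (1-3) 5-10 Hz component whose level tracks the temporal sleep
#' stage, a peripheral-channel (12-16) 10-30 Hz day/night sleep difference,
#' and proboscis-extension (PE) bursts concentrated in midsleep with roughly
#' 1.5-s inter-PE intervals and about a third of bouts being single events.
#'
#' @param n_channels number of probe channels (fixed at 16).
#' @param fs_lfp LFP sampling rate in Hz.
#' @param fps_video video frame rate in frames/s.
#' @param duration recording duration in seconds.
#' @param clock_start time of day at recording onset, "HH:MM" (lights on
#'   8 a.m. to 8 p.m.).
#' @param reversal_channel ground-truth polarity-reversal channel (1-16).
#' @param sleep_bout_rate expected sleep bouts per hour.
#' @param sleep_bout_duration `c(mu, sigma)` of the lognormal bout-duration
#'   distribution in seconds (bouts are truncated below at 315 s so every
#'   generated bout satisfies the 5-min sleep criterion).
#' @param night_bout_mu_delta added to `mu` for bouts starting at night, so
#'   night sleep bouts are longer on average.
#' @param wake_broadband_gain_db dB added to 5-40 Hz power on all channels
#'   during wake relative to sleep.
#' @param stage_broadband_frac named fractions of the wake broadband gain
#'   still expressed per stage; the descent is gradual (the brain "falls
#'   asleep" before the body stops moving, and early/late sleep sit
#'   between wake and midsleep).
#' @param stage_profile named dB offsets applied to the central-channel
#'   (1-3) 5-10 Hz component per stage; must satisfy
#'   awake > presleep > earlysleep >= latesleep > midsleep with awake = 0.
#' @param daynight_peripheral_delta_db dB added to peripheral-channel
#'   (12-16) 10-30 Hz sleep power during the day relative to night.
#' @param pe_wake_middle_delta_db dB change of middle-channel (6-10)
#'   5-40 Hz power during wake PEs (negative = decrease).
#' @param pe_sleep_central_delta_db dB change of central-channel (1-5)
#'   32-40 Hz power during sleep PEs (positive = increase).
#' @param pe_burst list with `inter_pe_interval_mean` (s),
#'   `inter_pe_interval_sdlog` (lognormal sdlog), `p_single` (probability a
#'   burst is a single PE), `burst_length_lambda` (Poisson excess length of
#'   multi-event bursts), and per-context burst rates per minute
#'   (`rate_midsleep`, `rate_othersleep`, `rate_wake`).
#' @param antenna list with `periodic_freq` (Hz), `periodic_fraction_sleep`,
#'   `periodic_fraction_wake`, and `segment_s` (granularity of periodic
#'   segments).
#' @param crepuscular_peaks multipliers on wake movement probability at dawn
#'   (7-9 a.m.) and dusk (7-9 p.m.).
#' @param move_prob_wake baseline probability that a wake second contains
#'   movement.
#' @param seed integer seed; all generation is deterministic given the
#'   config.
#' @return a validated list of class `"session_config"`.
#' @export
session_config <- function(n_channels = 16L,
                           fs_lfp = 250,
                           fps_video = 30,
                           duration = 3600,
                           clock_start = "08:00",
                           reversal_channel = 11L,
                           sleep_bout_rate = 2.5,
                           sleep_bout_duration = c(mu = log(550), sigma = 0.45),
                           night_bout_mu_delta = 0.4,
                           wake_broadband_gain_db = 6,
                           stage_broadband_frac = c(awake = 1, presleep = 0.3,
                                                    earlysleep = 0.15,
                                                    latesleep = 0.1,
                                                    midsleep = 0),
                           stage_profile = c(awake = 0, presleep = -2,
                                             earlysleep = -4, latesleep = -4.5,
                                             midsleep = -7),
                           daynight_peripheral_delta_db = 3,
                           pe_wake_middle_delta_db = -3,
                           pe_sleep_central_delta_db = 3,
                           pe_burst = list(),
                           antenna = list(),
                           crepuscular_peaks = c(dawn = 1.6, dusk = 1.8),
                           move_prob_wake = 0.55,
                           seed = 1L) {
  pe_defaults <- list(
    inter_pe_interval_mean = 1.5, inter_pe_interval_sdlog = 0.12,
    p_single = 0.33, burst_length_lambda = 1.8,
    rate_midsleep = 0.6, rate_othersleep = 0.05, rate_wake = 0.15
  )
  pe_burst <- utils::modifyList(pe_defaults, pe_burst)
  ant_defaults <- list(
    periodic_freq = 1, periodic_fraction_sleep = 0.5,
    periodic_fraction_wake = 0.1, segment_s = 30
  )
  antenna <- utils::modifyList(ant_defaults, antenna)

  cfg <- list(
    n_channels = as.integer(n_channels), fs_lfp = fs_lfp,
    fps_video = fps_video, duration = duration, clock_start = clock_start,
    reversal_channel = as.integer(reversal_channel),
    sleep_bout_rate = sleep_bout_rate,
    sleep_bout_duration = sleep_bout_duration,
    night_bout_mu_delta = night_bout_mu_delta,
    wake_broadband_gain_db = wake_broadband_gain_db,
    stage_broadband_frac = stage_broadband_frac,
    stage_profile = stage_profile,
    daynight_peripheral_delta_db = daynight_peripheral_delta_db,
    pe_wake_middle_delta_db = pe_wake_middle_delta_db,
    pe_sleep_central_delta_db = pe_sleep_central_delta_db,
    pe_burst = pe_burst, antenna = antenna,
    crepuscular_peaks = crepuscular_peaks,
    move_prob_wake = move_prob_wake, seed = as.integer(seed)
  )
  validate_session_config(cfg)
  class(cfg) <- "session_config"
  cfg
}

validate_session_config <- function(cfg) {
  if (cfg$n_channels != 16L) stop("invalid config field 'n_channels': must be 16")
  stopifnot_scalar(cfg$fs_lfp, "fs_lfp")
  stopifnot_scalar(cfg$fps_video, "fps_video")
  stopifnot_scalar(cfg$duration, "duration")
  parse_clock(cfg$clock_start)
  if (cfg$reversal_channel < 1 || cfg$reversal_channel > 16) {
    stop("invalid config field 'reversal_channel': must be in 1..16")
  }
  stopifnot_scalar(cfg$sleep_bout_rate, "sleep_bout_rate")
  if (length(cfg$sleep_bout_duration) != 2 ||
      !all(is.finite(cfg$sleep_bout_duration))) {
    stop("invalid config field 'sleep_bout_duration': need finite c(mu, sigma)")
  }
  sp <- cfg$stage_profile
  need <- c("awake", "presleep", "earlysleep", "latesleep", "midsleep")
  if (!all(need %in% names(sp)) || !all(is.finite(sp))) {
    stop("invalid config field 'stage_profile': need finite named offsets for ",
         paste(need, collapse = ", "))
  }
  if (!(sp["awake"] > sp["presleep"] && sp["presleep"] > sp["earlysleep"] &&
        sp["earlysleep"] >= sp["latesleep"] && sp["latesleep"] > sp["midsleep"])) {
    stop("invalid config field 'stage_profile': must satisfy ",
         "awake > presleep > earlysleep >= latesleep > midsleep")
  }
  sbf <- cfg$stage_broadband_frac
  if (!all(need %in% names(sbf)) || !all(is.finite(sbf)) ||
      any(sbf < 0 | sbf > 1)) {
    stop("invalid config field 'stage_broadband_frac': named fractions in ",
         "[0, 1] required for every stage")
  }
  for (f in c("wake_broadband_gain_db", "daynight_peripheral_delta_db",
              "pe_wake_middle_delta_db", "pe_sleep_central_delta_db")) {
    if (!is.finite(cfg[[f]])) stop("invalid config field '", f, "': must be finite")
  }
  if (cfg$pe_burst$p_single < 0 || cfg$pe_burst$p_single > 1) {
    stop("invalid config field 'pe_burst$p_single': must be in [0, 1]")
  }
  invisible(cfg)
}

## Alternating wake/sleep bout sequence covering [0, duration).
## Cycle length is 3600/rate so the expected sleep fraction is
## E[sleep] / (E[wake] + E[sleep]) with E[wake] = 3600/rate - E[sleep].
simulate_bout_sequence <- function(cfg) {
  mu <- cfg$sleep_bout_duration[[1]]
  sigma <- cfg$sleep_bout_duration[[2]]
  e_sleep <- exp(mu + sigma^2 / 2)
  cycle <- 3600 / cfg$sleep_bout_rate
  e_wake <- max(cycle - e_sleep, 60)
  t <- 0
  rows <- list()
  repeat {
    w <- max(stats::rexp(1, rate = 1 / e_wake), 240)
    if (t + w >= cfg$duration) {
      rows[[length(rows) + 1]] <- data.frame(
        start_s = t, end_s = cfg$duration, kind = "awake"
      )
      break
    }
    rows[[length(rows) + 1]] <- data.frame(start_s = t, end_s = t + w, kind = "awake")
    t <- t + w
    mu_i <- mu + if (is_day(t, cfg$clock_start)) 0 else cfg$night_bout_mu_delta
    s <- max(stats::rlnorm(1, mu_i, sigma), 315)
    s_end <- min(t + s, cfg$duration)
    rows[[length(rows) + 1]] <- data.frame(start_s = t, end_s = s_end, kind = "sleep")
    t <- s_end
    if (t >= cfg$duration) break
  }
  bouts <- do.call(rbind, rows)
  # drop terminal sleep bouts squeezed under the 5-min criterion
  short_sleep <- bouts$kind == "sleep" & (bouts$end_s - bouts$start_s) < 300
  bouts$kind[short_sleep] <- "awake"
  bouts
}

## Per-second stage vector from the bout sequence (mirrors the temporal
## partition used downstream: presleep -2:0, earlysleep 0:2, latesleep last
## 2 min, midsleep in between).
stage_intervals_from_bouts <- function(bouts, duration) {
  sleep <- bouts[bouts$kind == "sleep", , drop = FALSE]
  rows <- list(data.frame(start_s = 0, end_s = duration, stage = "awake",
                          bout_id = NA_integer_))
  if (nrow(sleep)) {
    for (i in seq_len(nrow(sleep))) {
      a <- sleep$start_s[i]; b <- sleep$end_s[i]
      prev_end <- if (i > 1) sleep$end_s[i - 1] else 0
      rows[[length(rows) + 1]] <- data.frame(
        start_s = c(max(a - 120, prev_end, 0), a, a + 120, b - 120),
        end_s = c(a, a + 120, b - 120, b),
        stage = c("presleep", "earlysleep", "midsleep", "latesleep"),
        bout_id = i
      )
    }
  }
  iv <- do.call(rbind, rows)
  iv[iv$end_s > iv$start_s, , drop = FALSE]
}

per_second_stage <- function(bouts, duration) {
  iv <- stage_intervals_from_bouts(bouts, duration)
  iv <- iv[iv$stage != "awake", , drop = FALSE]
  fill_intervals(duration, 1, iv, iv$stage, "awake")
}

## PE bursts: onset times per context, thinned to >= 12 s apart so the 10-s
## burst-merging rule never joins two generated bursts.
simulate_pe_events <- function(cfg, bouts) {
  iv <- stage_intervals_from_bouts(bouts, cfg$duration)
  rate_of <- function(stage) {
    switch(stage,
      midsleep = cfg$pe_burst$rate_midsleep,
      earlysleep = ,
      latesleep = cfg$pe_burst$rate_othersleep,
      presleep = ,
      awake = cfg$pe_burst$rate_wake
    )
  }
  # context intervals: awake complement of sleep-stage+presleep intervals
  non_awake <- iv[iv$stage != "awake", , drop = FALSE]
  stage_sec <- per_second_stage(bouts, cfg$duration)
  events <- list()
  burst_id <- 0
  for (i in seq_len(nrow(non_awake))) {
    events[[length(events) + 1]] <-
      pe_bursts_in(non_awake$start_s[i], non_awake$end_s[i],
                   rate_of(non_awake$stage[i]), cfg)
  }
  # awake residual: seconds labeled awake
  awake_runs <- rle_runs(stage_sec == "awake")
  awake_runs <- awake_runs[awake_runs$value, , drop = FALSE]
  for (i in seq_len(nrow(awake_runs))) {
    events[[length(events) + 1]] <-
      pe_bursts_in(awake_runs$start[i] - 1, awake_runs$end[i],
                   rate_of("awake"), cfg)
  }
  events <- do.call(rbind, events)
  if (is.null(events) || !nrow(events)) {
    return(data.frame(time_s = numeric(), state = character(),
                      stage = character(), burst_id = integer()))
  }
  # thin whole bursts so distinct bursts stay >= 12 s apart
  split_bursts <- split(events, events$burst_local)
  starts <- vapply(split_bursts, function(d) min(d$time_s), numeric(1))
  split_bursts <- split_bursts[order(starts)]
  kept <- list()
  last_end <- -Inf
  for (d in split_bursts) {
    if (min(d$time_s) - last_end >= 12) {
      kept[[length(kept) + 1]] <- d
      last_end <- max(d$time_s)
    }
  }
  if (!length(kept)) {
    return(data.frame(time_s = numeric(), state = character(),
                      stage = character(), burst_id = integer()))
  }
  events <- do.call(rbind, lapply(seq_along(kept), function(i) {
    d <- kept[[i]]; d$burst_id <- i; d
  }))
  sec <- pmin(floor(events$time_s) + 1, length(stage_sec))
  events$stage <- stage_sec[sec]
  events$state <- ifelse(events$stage %in% c("awake"), "awake",
                         ifelse(events$stage == "presleep", "presleep", "sleep"))
  events[, c("time_s", "state", "stage", "burst_id")]
}

pe_bursts_in <- function(a, b, rate_per_min, cfg) {
  len_min <- (b - a) / 60
  n_bursts <- stats::rpois(1, rate_per_min * len_min)
  if (n_bursts == 0) return(NULL)
  onsets <- sort(stats::runif(n_bursts, a, b))
  out <- list()
  for (k in seq_len(n_bursts)) {
    single <- stats::runif(1) < cfg$pe_burst$p_single
    n_ev <- if (single) 1L else 2L + stats::rpois(1, cfg$pe_burst$burst_length_lambda)
    m <- cfg$pe_burst$inter_pe_interval_mean
    sdl <- cfg$pe_burst$inter_pe_interval_sdlog
    gaps <- stats::rlnorm(max(n_ev - 1, 0), log(m) - sdl^2 / 2, sdl)
    times <- onsets[k] + c(0, cumsum(gaps))
    times <- times[times < b - 0.5]
    if (length(times)) {
      out[[length(out) + 1]] <- data.frame(
        time_s = times,
        burst_local = onsets[k]
      )
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}

## Antennal periodic segments: segment_s-long chunks, periodic with the
## configured per-state probability.
simulate_periodic_segments <- function(cfg, bouts) {
  seg <- cfg$antenna$segment_s
  rows <- list()
  for (i in seq_len(nrow(bouts))) {
    a <- bouts$start_s[i]; b <- bouts$end_s[i]
    p <- if (bouts$kind[i] == "sleep") cfg$antenna$periodic_fraction_sleep
         else cfg$antenna$periodic_fraction_wake
    if (b - a < seg) next
    starts <- seq(a, b - seg, by = seg)
    flags <- stats::runif(length(starts)) < p
    if (any(flags)) {
      rows[[length(rows) + 1]] <- data.frame(
        start_s = starts[flags], end_s = starts[flags] + seg,
        state = bouts$kind[i]
      )
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(start_s = numeric(), end_s = numeric(), state = character())
}

#' Generate a labeled synthetic recording session
#'
#' Produces a multichannel LFP matrix, a movement trace (and optionally raw
#' grayscale video frames), wide-format pose traces, and ground-truth labels
#' (state sequence, stage partition, PE events, antennal periodic segments,
#' polarity-reversal channel). The LFP model is 1/f colored noise plus
#' band-limited Gaussian components with dB-calibrated, state- and
#' stage-dependent gains, plus a common-mode component shared by all
#' channels (removed downstream by re-referencing). Identical configs give
#' bit-identical sessions.
#'
#' @param config a [session_config()].
#' @param components subset of `c("lfp", "movement", "frames", "pose")`;
#'   frames are opt-in because full video stacks are bulky.
#' @return a list of class `"synthetic_session"` with elements `lfp`
#'   (channels x samples), `movement` (per-frame 0/1), `frames` (h x w x T
#'   integer array or NULL), `pose` (data.frame), `truth` (list), `fs`,
#'   `fps`, `clock_start`.
#' @export
generate_session <- function(config,
                             components = c("lfp", "movement", "pose")) {
  validate_session_config(config)
  components <- match.arg(components,
                          c("lfp", "movement", "frames", "pose"),
                          several.ok = TRUE)
  with_seed(config$seed, {
    bouts <- simulate_bout_sequence(config)
    stage_sec <- per_second_stage(bouts, config$duration)
    pe <- simulate_pe_events(config, bouts)
    periodic <- simulate_periodic_segments(config, bouts)
    truth <- list(
      bouts = bouts,
      state_sec = ifelse(stage_sec %in% c("earlysleep", "midsleep", "latesleep"),
                         "sleep", "awake"),
      stage_sec = stage_sec,
      pe_events = pe,
      periodic_segments = periodic,
      reversal_channel = config$reversal_channel
    )
    movement <- if (any(c("movement", "frames") %in% components)) {
      synth_movement(config, truth)
    } else NULL
    lfp_out <- if ("lfp" %in% components) synth_lfp(config, truth) else NULL
    truth$common_mode <- lfp_out$common
    session <- list(
      lfp = lfp_out$lfp,
      movement = movement,
      frames = if ("frames" %in% components) synth_frames(config, movement) else NULL,
      pose = if ("pose" %in% components) synth_pose(config, truth) else NULL,
      truth = truth,
      fs = config$fs_lfp, fps = config$fps_video,
      clock_start = config$clock_start, config = config
    )
    class(session) <- "synthetic_session"
    session
  })
}

## LFP synthesis. Group conventions (1-based original channel indices):
## central 1-5 (stage component on 1-3), middle 6-10, peripheral 12-16.
synth_lfp <- function(cfg, truth) {
  n <- round(cfg$duration * cfg$fs_lfp)
  fs <- cfg$fs_lfp
  db2amp <- function(db) 10^(db / 20)
  sec_idx <- pmin(floor((seq_len(n) - 1) / fs) + 1, cfg$duration)
  stage <- truth$stage_sec[sec_idx]

  # broadband 5-40 Hz envelope (dB relative to the midsleep level)
  g <- cfg$wake_broadband_gain_db
  bb_env <- db2amp(g * cfg$stage_broadband_frac[stage])

  # stage component envelope (dB offsets from config profile)
  st_env <- db2amp(cfg$stage_profile[stage])

  # day/night peripheral envelope: active during sleep only; a bout keeps
  # the day flag of its onset (the same per-bout convention used when
  # labeling daysleep/nightsleep downstream)
  sleeping <- stage %in% c("earlysleep", "midsleep", "latesleep")
  day <- rep(FALSE, n)
  sleep_bts <- truth$bouts[truth$bouts$kind == "sleep", , drop = FALSE]
  for (i in seq_len(nrow(sleep_bts))) {
    if (is_day(sleep_bts$start_s[i], cfg$clock_start)) {
      a <- max(1, floor(sleep_bts$start_s[i] * fs))
      b <- min(n, ceiling(sleep_bts$end_s[i] * fs))
      day[a:b] <- TRUE
    }
  }
  # symmetric modulation: day sleep up, night sleep down by delta/2, so the
  # pooled sleep level stays calibrated against the wake broadband gain
  dn_mod <- ifelse(sleeping,
                   ifelse(day, db2amp(cfg$daynight_peripheral_delta_db / 2),
                          db2amp(-cfg$daynight_peripheral_delta_db / 2)),
                   1)

  # PE envelopes from truth events (window +-0.75 s around each event)
  pe <- truth$pe_events
  pe_wake <- rep(FALSE, n); pe_sleep <- rep(FALSE, n)
  if (nrow(pe)) {
    for (j in seq_len(nrow(pe))) {
      a <- max(1, floor((pe$time_s[j] - 0.75) * fs))
      b <- min(n, ceiling((pe$time_s[j] + 0.75) * fs))
      if (pe$state[j] == "sleep") pe_sleep[a:b] <- TRUE
      if (pe$state[j] %in% c("awake", "presleep")) pe_wake[a:b] <- TRUE
    }
  }
  mid_bb_mod <- ifelse(pe_wake, db2amp(cfg$pe_wake_middle_delta_db), 1)
  pe_central_env <- ifelse(pe_sleep & sleeping, 1, 0)

  # non-brain physiological noise: slow drift plus a heartbeat-like band,
  # shared by every channel; kept below the 5-40 Hz analysis band so the
  # state-dependent calibration is expressed on raw channels too
  common <- 1.0 * band_noise(n, fs, 0.5, 4.5) + 0.6 * band_noise(n, fs, 2.5, 3.5)

  lfp <- matrix(0, nrow = cfg$n_channels, ncol = n)
  for (ch in seq_len(cfg$n_channels)) {
    x <- 0.35 * pink_noise(n) + common
    env <- bb_env
    if (ch %in% 6:10) env <- env * mid_bb_mod
    if (ch %in% 12:16) {
      # peripheral broadband split so the 10-30 Hz share carries the
      # day/night sleep modulation; sub-band amplitudes keep the total
      # spectral density equal to the single 5-40 Hz component
      x <- x + env * (sqrt(5 / 35) * band_noise(n, fs, 5, 10) +
                        sqrt(20 / 35) * dn_mod * band_noise(n, fs, 10, 30) +
                        sqrt(10 / 35) * band_noise(n, fs, 30, 40))
    } else {
      x <- x + env * band_noise(n, fs, 5, 40)
    }
    if (ch %in% 1:3) x <- x + st_env * band_noise(n, fs, 5, 10)
    if (ch %in% 1:5) x <- x + 0.5 * pe_central_env * band_noise(n, fs, 32, 40)
    lfp[ch, ] <- x
  }
  list(lfp = lfp, common = common)
}

## Movement: wake seconds move as whole-second blocks with probability
## move_prob_wake x crepuscular multiplier; sleep seconds contain rare
## 2-frame blips (removed by pruning).
synth_movement <- function(cfg, truth) {
  fps <- cfg$fps_video
  n_frames <- round(cfg$duration * fps)
  sec <- floor((seq_len(n_frames) - 1) / fps) + 1
  tod <- time_of_day(seq_len(cfg$duration) - 1, cfg$clock_start)
  mult <- rep(1, cfg$duration)
  dawn <- tod >= 7 * 3600 & tod < 9 * 3600
  dusk <- tod >= 19 * 3600 & tod < 21 * 3600
  mult[dawn] <- cfg$crepuscular_peaks[["dawn"]]
  mult[dusk] <- cfg$crepuscular_peaks[["dusk"]]
  p_move <- pmin(cfg$move_prob_wake * mult, 0.98)
  wake_sec <- truth$state_sec == "awake"
  # presleep is behaviorally awake; truth$state_sec already labels it awake
  sec_moved <- wake_sec & (stats::runif(cfg$duration) < p_move)
  # the fly visibly stops/starts moving at bout boundaries (immobility onset
  # is defined by the last movement), so flanking wake seconds always move
  sleep_b <- truth$bouts[truth$bouts$kind == "sleep", , drop = FALSE]
  for (i in seq_len(nrow(sleep_b))) {
    pre <- max(1, round(sleep_b$start_s[i]) - 2):max(1, round(sleep_b$start_s[i]))
    post <- min(cfg$duration, round(sleep_b$end_s[i]) + 1):
      min(cfg$duration, round(sleep_b$end_s[i]) + 3)
    sec_moved[pre[wake_sec[pre]]] <- TRUE
    sec_moved[post[wake_sec[post]]] <- TRUE
  }
  moved <- as.integer(sec_moved[sec])
  # brief noise blips during stillness
  still_sec <- which(!sec_moved)
  blip_sec <- still_sec[stats::runif(length(still_sec)) < 0.01]
  for (s in blip_sec) {
    f0 <- (s - 1) * fps + sample.int(max(fps - 2, 1), 1)
    moved[f0:min(f0 + 1, n_frames)] <- 1L
  }
  moved
}

## 64 x 48 grayscale frames: static noisy background plus a bright blob
## that takes a jitter step on moved frames.
synth_frames <- function(cfg, moved, h = 48L, w = 64L) {
  n_frames <- length(moved)
  frames <- array(0L, dim = c(h, w, n_frames))
  pos <- c(h / 2, w / 2)
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  for (f in seq_len(n_frames)) {
    if (moved[f] == 1L) {
      step <- stats::runif(2, -3, 3)
      pos <- pmin(pmax(pos + step, c(10, 10)), c(h - 10, w - 10))
    }
    blob <- 200 * exp(-((yy - pos[1])^2 + (xx - pos[2])^2) / (2 * 3.5^2))
    img <- 30 + blob + stats::rnorm(h * w, sd = 3)
    frames[, , f] <- as.integer(pmin(pmax(round(img), 0), 255))
  }
  frames
}

## Pose traces, wide format: <part>_x, <part>_y, <part>_likelihood.
synth_pose <- function(cfg, truth) {
  fps <- cfg$fps_video
  n_frames <- round(cfg$duration * fps)
  t <- (seq_len(n_frames) - 1) / fps
  sec <- pmin(floor(t) + 1, cfg$duration)
  awake <- truth$state_sec[sec] == "awake"

  tremor <- function(sd = 0.3) stats::rnorm(n_frames, sd = sd)
  lik <- function() pmin(pmax(0.97 + stats::rnorm(n_frames, sd = 0.015), 0), 1)

  eye <- list(x = 100 + tremor(), y = 60 + tremor())

  # PE displacement bump: raised-cosine of 0.4 s around each event peak
  pe_disp <- rep(0, n_frames)
  pe <- truth$pe_events
  occluded_event <- rep(FALSE, nrow(pe))
  if (nrow(pe)) {
    occluded_event <- stats::runif(nrow(pe)) < 0.15
    for (j in seq_len(nrow(pe))) {
      idx <- which(abs(t - pe$time_s[j]) <= 0.2)
      pe_disp[idx] <- pmax(pe_disp[idx],
                           12 * cos(pi * (t[idx] - pe$time_s[j]) / 0.4)^2)
    }
  }
  dirv <- c(0.8, 0.6)
  prob_lik <- lik()
  # during PEs the tracked proboscis looks different: likelihood sags
  prob_lik[pe_disp > 2] <- pmin(prob_lik[pe_disp > 2],
                                0.55 + stats::rnorm(sum(pe_disp > 2), sd = 0.05))
  prob <- list(
    x = eye$x + 8 + dirv[1] * pe_disp + tremor(),
    y = eye$y + 6 + dirv[2] * pe_disp + tremor()
  )

  # occlusions: short windows where likelihood collapses and x/y wander;
  # a subset of PE events is occluded so the likelihood-threshold
  # augmentation rule has work to do
  occ <- rep(FALSE, n_frames)
  n_occ <- stats::rpois(1, cfg$duration / 600)
  if (n_occ > 0) {
    occ_t <- stats::runif(n_occ, 0, cfg$duration - 1)
    for (o in occ_t) occ[t >= o & t < o + 1] <- TRUE
  }
  if (nrow(pe) && any(occluded_event)) {
    for (j in which(occluded_event)) occ[abs(t - pe$time_s[j]) <= 0.25] <- TRUE
  }
  prob_lik[occ] <- pmin(prob_lik[occ], 0.3 + stats::rnorm(sum(occ), sd = 0.05))
  prob$x[occ] <- prob$x[occ] + stats::rnorm(sum(occ), sd = 6)
  prob$y[occ] <- prob$y[occ] + stats::rnorm(sum(occ), sd = 6)

  walk <- awake & (stats::rbinom(n_frames, 1, 0.8) == 1)
  leg_osc <- 6 * sin(2 * pi * 3 * t) * walk
  abdomen_breath <- 1.2 * sin(2 * pi * 1 * t)

  # antennae: head axis left-base -> right-base with slow wobble
  phi <- (3 * pi / 180) * sin(2 * pi * t / 120)
  hc <- c(100, 35)
  rot <- function(p, ang) {
    list(x = hc[1] + cos(ang) * (p[1]) - sin(ang) * (p[2]),
         y = hc[2] + sin(ang) * (p[1]) + cos(ang) * (p[2]))
  }
  periodic_env <- rep(FALSE, n_frames)
  ps <- truth$periodic_segments
  if (nrow(ps)) {
    for (i in seq_len(nrow(ps))) {
      periodic_env[t >= ps$start_s[i] & t < ps$end_s[i]] <- TRUE
    }
  }
  f0 <- cfg$antenna$periodic_freq
  ant_angle <- function(side) {
    base_angle <- 60 * pi / 180
    osc <- (8 * pi / 180) * sin(2 * pi * f0 * t + ifelse(side == "L", 0, 0.7))
    noise <- (2 * pi / 180) * stats::rnorm(n_frames)
    base_angle + ifelse(periodic_env, osc, 0) + noise
  }
  ant <- list()
  for (side in c("L", "R")) {
    sgn <- if (side == "L") -1 else 1
    base_local <- c(sgn * 10, 0)
    b <- rot(base_local, phi)
    theta <- ant_angle(side) # ccw from head axis
    tip_local_x <- base_local[1] + 12 * cos(theta) * sgn
    tip_local_y <- base_local[2] + 12 * sin(theta)
    tipx <- hc[1] + cos(phi) * tip_local_x - sin(phi) * tip_local_y
    tipy <- hc[2] + sin(phi) * tip_local_x + cos(phi) * tip_local_y
    ant[[paste0("antenna", side, "_base")]] <- list(x = b$x, y = b$y)
    ant[[paste0("antenna", side, "_tip")]] <- list(x = tipx, y = tipy)
  }

  parts <- list(
    proboscis = prob,
    eye = eye,
    leg1_tip = list(x = 80 + leg_osc + tremor(), y = 90 + 0.5 * leg_osc + tremor()),
    leg1_joint = list(x = 85 + 0.4 * leg_osc + tremor(), y = 80 + tremor()),
    leg3_tip = list(x = 120 + leg_osc + tremor(), y = 92 + 0.5 * leg_osc + tremor()),
    leg3_joint = list(x = 115 + 0.4 * leg_osc + tremor(), y = 82 + tremor()),
    abdomen = list(x = 140 + tremor(), y = 70 + abdomen_breath + tremor())
  )
  parts <- c(parts, ant)
  out <- data.frame(frame = seq_len(n_frames) - 1L)
  for (p in names(parts)) {
    out[[paste0(p, "_x")]] <- parts[[p]]$x
    out[[paste0(p, "_y")]] <- parts[[p]]$y
    out[[paste0(p, "_likelihood")]] <- if (p == "proboscis") prob_lik else lik()
  }
  attr(out, "fps") <- fps
  out
}

#' Generate a visual-calibration recording
#'
#' Square-wave visual stimulation (3-s trains at 1 Hz) evokes deflections
#' whose sign flips across the probe: channels central to the reversal
#' channel deflect negatively, peripheral channels positively, and the
#' reversal channel itself stays near zero.
#'
#' @param reversal_channel true reversal channel, 2..15 (a reversal at the
#'   array edge is undetectable and rejected).
#' @param noise_sd additive white noise amplitude.
#' @param n_trains number of 3-s stimulus trains.
#' @param fs sampling rate in Hz.
#' @param seed integer seed.
#' @return list with `lfp` (16 x samples), `fs`, `stimulus_onsets` (s, one
#'   per leading edge), `truth_reversal`.
#' @export
generate_calibration <- function(reversal_channel, noise_sd = 0.2,
                                 n_trains = 10, fs = 250, seed = 1L) {
  if (reversal_channel < 2 || reversal_channel > 15) {
    stop("reversal_channel at the array edge: reversal undetectable")
  }
  with_seed(seed, {
    train_gap <- 6
    duration <- n_trains * train_gap + 2
    n <- round(duration * fs)
    onsets <- as.vector(outer(0:2, (seq_len(n_trains) - 1) * train_gap + 1, "+"))
    onsets <- sort(onsets)
    lfp <- matrix(stats::rnorm(16 * n, sd = noise_sd), nrow = 16)
    tau <- seq(0, 0.3, by = 1 / fs)
    kernel <- sin(pi * pmin(tau, 0.2) / 0.2) * (tau <= 0.2)
    for (ch in 1:16) {
      amp <- sign(ch - reversal_channel) * (0.5 + 0.1 * abs(ch - reversal_channel))
      for (o in onsets) {
        i0 <- round(o * fs) + 1
        idx <- i0:(i0 + length(kernel) - 1)
        idx <- idx[idx <= n]
        lfp[ch, idx] <- lfp[ch, idx] + amp * kernel[seq_along(idx)]
      }
    }
    list(lfp = lfp, fs = fs, stimulus_onsets = onsets,
         truth_reversal = as.integer(reversal_channel))
  })
}

#' Generate a cohort of synthetic sessions
#'
#' Per-fly seeds are derived deterministically from the cohort seed
#' (`seed + fly index`), so a fixed cohort seed reproduces the cohort
#' exactly while flies remain mutually independent.
#'
#' @param n_flies number of flies (>= 1).
#' @param config shared [session_config()]; the per-fly seed overrides
#'   `config$seed`.
#' @param seed cohort seed.
#' @param components passed to [generate_session()].
#' @return list of `synthetic_session`, names `fly01`, `fly02`, ...
#' @export
generate_cohort <- function(n_flies, config, seed = config$seed,
                            components = c("lfp", "movement", "pose")) {
  if (n_flies < 1) stop("n_flies must be >= 1")
  out <- vector("list", n_flies)
  for (i in seq_len(n_flies)) {
    cfg_i <- config
    cfg_i$seed <- as.integer(seed + i)
    out[[i]] <- generate_session(cfg_i, components = components)
  }
  names(out) <- sprintf("fly%02d", seq_len(n_flies))
  out
}

#' Write a session bundle to disk
#'
#' Pose, truth labels and movement go to plain CSV; the LFP matrix and
#' frame stack go to RDS (no HDF5 backend is used).
#'
#' @param session a `synthetic_session`.
#' @param dir output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(session$lfp, file.path(dir, "lfp.rds"))
  if (!is.null(session$frames)) saveRDS(session$frames, file.path(dir, "frames.rds"))
  if (!is.null(session$pose)) {
    utils::write.csv(session$pose, file.path(dir, "pose.csv"), row.names = FALSE)
  }
  if (!is.null(session$movement)) {
    utils::write.csv(data.frame(frame = seq_along(session$movement) - 1L,
                                moved = session$movement),
                     file.path(dir, "movement.csv"), row.names = FALSE)
  }
  b <- session$truth$bouts
  utils::write.csv(data.frame(onset_s = b$start_s, offset_s = b$end_s,
                              label = b$kind),
                   file.path(dir, "truth_bouts.csv"), row.names = FALSE)
  utils::write.csv(session$truth$pe_events, file.path(dir, "truth_pe.csv"),
                   row.names = FALSE)
  meta <- data.frame(fs = session$fs, fps = session$fps,
                     clock_start = session$clock_start,
                     reversal_channel = session$truth$reversal_channel)
  utils::write.csv(meta, file.path(dir, "meta.csv"), row.names = FALSE)
  invisible(dir)
}
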