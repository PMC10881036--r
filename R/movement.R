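#' Quantify per-frame movement from a grayscale frame stack
#'
#' Frame-differencing movement detector: absolute difference with the
#' previous frame, binarized at `pixel_threshold`, dilated (3x3 box, one
#' iteration), connected components labeled, and a frame is "moved" iff any
#' component area exceeds `area_threshold` pixels. Frame 0 is defined still.
#'
#' @param frames h x w x T numeric/integer array (grayscale). Color input
#'   (4-d array) is converted by channel-averaging with a warning.
#' @param pixel_threshold intensity difference threshold (> 0).
#' @param area_threshold minimum contour area in pixels (> 0).
#' @param fps frame rate, stored on the result.
#' @return a `movement_trace`: list with `moved` (0/1 per frame), `fps`,
#'   `per_minute_fraction`.
#' @export
quantify_movement <- function(frames, pixel_threshold = 25,
                              area_threshold = 8, fps = 30) {
  if (length(dim(frames)) == 4) {
    warning("non-grayscale input: averaging channels")
    frames <- apply(frames, c(1, 2, 4), mean)
  }
  if (length(dim(frames)) != 3 || dim(frames)[3] < 2) {
    stop("need a h x w x T stack with at least 2 frames")
  }
  if (pixel_threshold <= 0 || area_threshold <= 0) {
    stop("thresholds must be > 0")
  }
  n <- dim(frames)[3]
  brush <- EBImage::makeBrush(3, shape = "box")
  moved <- integer(n)
  for (f in 2:n) {
    delta <- abs(frames[, , f] - frames[, , f - 1])
    bin <- matrix(as.numeric(delta > pixel_threshold), nrow = nrow(delta))
    if (!any(bin > 0)) next
    dil <- EBImage::dilate(bin, brush)
    lab <- EBImage::bwlabel(dil)
    areas <- tabulate(as.integer(lab[lab > 0]))
    if (length(areas) && max(areas) > area_threshold) moved[f] <- 1L
  }
  movement_trace(moved, fps)
}

#' Construct a movement trace from a 0/1 vector
#'
#' @param moved 0/1 per frame.
#' @param fps frame rate.
#' @return a `movement_trace` list.
#' @export
movement_trace <- function(moved, fps) {
  stopifnot(all(moved %in% c(0L, 1L)))
  minute <- floor((seq_along(moved) - 1) / (fps * 60))
  out <- list(
    moved = as.integer(moved), fps = fps,
    per_minute_fraction = as.numeric(tapply(moved, minute, mean))
  )
  class(out) <- "movement_trace"
  out
}

#' Prune brief movement noise
#'
#' Runs of "moved" frames shorter than `min_run_frames` are set to still;
#' nothing else changes. The operation is idempotent.
#'
#' @param trace a `movement_trace`.
#' @param min_run_frames minimum run length (frames) for a movement run to
#'   survive; default 15 frames (0.5 s at 30 fps).
#' @return pruned `movement_trace`.
#' @export
prune_movement <- function(trace, min_run_frames = 15) {
  if (min_run_frames < 1) stop("min_run_frames must be >= 1")
  moved <- trace$moved
  runs <- rle_runs(moved)
  short <- runs$value == 1L & runs$length < min_run_frames
  for (i in which(short)) moved[runs$start[i]:runs$end[i]] <- 0L
  movement_trace(moved, trace$fps)
}

#' Segment sleep and awake bouts from a movement trace
#'
#' Maximal immobile runs of at least 300 s become sleep bouts; everything
#' else is awake. Bouts carry a day flag (lights on 8 a.m. to 8 p.m.)
#' assigned by bout onset time.
#'
#' @param trace a pruned `movement_trace`.
#' @param clock_start "HH:MM" time of day at recording start.
#' @param min_sleep_s immobility criterion in seconds (default 300).
#' @return a `bout_set`: data.frame with `start_s`, `end_s`, `kind`,
#'   `day_flag`; attribute `clock_start`.
#' @export
label_states <- function(trace, clock_start = "08:00", min_sleep_s = 300) {
  n <- length(trace$moved)
  fps <- trace$fps
  runs <- rle_runs(trace$moved)
  sleep_runs <- runs[runs$value == 0L &
                       runs$length >= min_sleep_s * fps, , drop = FALSE]
  bounds <- sort(unique(c(0, (sleep_runs$start - 1) / fps,
                          sleep_runs$end / fps, n / fps)))
  kinds <- character(length(bounds) - 1)
  for (i in seq_along(kinds)) {
    mid <- (bounds[i] + bounds[i + 1]) / 2
    in_sleep <- any(mid >= (sleep_runs$start - 1) / fps &
                      mid < sleep_runs$end / fps)
    kinds[i] <- if (in_sleep) "sleep" else "awake"
  }
  keep <- bounds[-length(bounds)] < bounds[-1]
  bouts <- data.frame(
    start_s = bounds[-length(bounds)][keep],
    end_s = bounds[-1][keep],
    kind = kinds[keep]
  )
  bouts$day_flag <- is_day(bouts$start_s, clock_start)
  attr(bouts, "clock_start") <- clock_start
  class(bouts) <- c("bout_set", "data.frame")
  bouts
}

#' Partition sleep bouts into temporal stages
#'
#' Each sleep bout of at least 300 s yields: presleep = the 2 min before
#' immobility onset, earlysleep = the first 2 min of the bout, latesleep =
#' the last 2 min, midsleep = the remainder between them, plus two probe
#' windows used only for classifier probing: `pre2_probe` = minutes -4 to
#' -2 before onset and `post2_probe` = the 2 min after the bout ends.
#' Residual time is awake. Intervals are half-open. A presleep (or probe)
#' window truncated by the recording edge is flagged `partial` and callers
#' exclude it from staging features.
#'
#' @param bouts a `bout_set` from [label_states()].
#' @param duration_s recording duration; defaults to the bout cover.
#' @return a `stage_labels` data.frame: `start_s`, `end_s`, `stage`,
#'   `bout_id`, `bout_start`, `bout_end`, `partial`.
#' @export
segment_sleep_epochs <- function(bouts, duration_s = max(bouts$end_s)) {
  sleep <- bouts[bouts$kind == "sleep", , drop = FALSE]
  rows <- list()
  add <- function(a, b, stage, id, bs, be, nominal = b - a) {
    a2 <- max(a, 0); b2 <- min(b, duration_s)
    if (b2 > a2) {
      rows[[length(rows) + 1]] <<- data.frame(
        start_s = a2, end_s = b2, stage = stage, bout_id = id,
        bout_start = bs, bout_end = be,
        partial = (b2 - a2) < nominal - 1e-9
      )
    }
  }
  if (nrow(sleep)) {
    for (i in seq_len(nrow(sleep))) {
      a <- sleep$start_s[i]; b <- sleep$end_s[i]
      if (b - a < 300) next
      prev_end <- if (i > 1) sleep$end_s[i - 1] else 0
      next_start <- if (i < nrow(sleep)) sleep$start_s[i + 1] else duration_s
      add(max(a - 240, prev_end), a - 120, "pre2_probe", i, a, b, 120)
      add(max(a - 120, prev_end), a, "presleep", i, a, b, 120)
      add(a, a + 120, "earlysleep", i, a, b)
      add(a + 120, b - 120, "midsleep", i, a, b)
      add(b - 120, b, "latesleep", i, a, b)
      add(b, min(b + 120, next_start), "post2_probe", i, a, b, 120)
    }
  }
  staged <- if (length(rows)) do.call(rbind, rows) else
    data.frame(start_s = numeric(), end_s = numeric(), stage = character(),
               bout_id = integer(), bout_start = numeric(),
               bout_end = numeric(), partial = logical())
  # awake = residual time not claimed by any stage or probe window
  claimed <- staged
  bounds <- sort(unique(c(0, duration_s, claimed$start_s, claimed$end_s)))
  for (i in seq_len(length(bounds) - 1)) {
    a <- bounds[i]; b <- bounds[i + 1]
    mid <- (a + b) / 2
    if (!any(mid >= claimed$start_s & mid < claimed$end_s)) {
      staged <- rbind(staged, data.frame(
        start_s = a, end_s = b, stage = "awake", bout_id = NA_integer_,
        bout_start = NA_real_, bout_end = NA_real_, partial = FALSE
      ))
    }
  }
  staged <- staged[order(staged$start_s, staged$stage), , drop = FALSE]
  rownames(staged) <- NULL
  class(staged) <- c("stage_labels", "data.frame")
  staged
}

#' Minute-resolved probe labels around sleep bouts
#'
#' Labels 60-s windows by minute offset relative to bout onset (minutes -4
#' through +2) and bout end (x-2 through x+2), for classifier-probability
#' probing. Windows truncated by the recording edge are dropped.
#'
#' @param stages a `stage_labels` data.frame.
#' @param duration_s recording duration.
#' @return data.frame `start_s`, `end_s`, `label` (e.g. `"m-2:-1"`,
#'   `"mx+1:+2"`), `bout_id`.
#' @export
minute_probe_labels <- function(stages, duration_s = max(stages$end_s)) {
  sl <- unique(stages[!is.na(stages$bout_id),
                      c("bout_id", "bout_start", "bout_end")])
  rows <- list()
  for (i in seq_len(nrow(sl))) {
    a <- sl$bout_start[i]; b <- sl$bout_end[i]
    for (m in -4:1) {
      s0 <- a + 60 * m
      lab <- sprintf("m%+d:%+d", m, m + 1)
      if (s0 >= 0 && s0 + 60 <= duration_s) {
        rows[[length(rows) + 1]] <- data.frame(
          start_s = s0, end_s = s0 + 60, label = lab, bout_id = sl$bout_id[i]
        )
      }
    }
    for (m in -2:1) {
      s0 <- b + 60 * m
      lab <- sprintf("mx%+d:%+d", m, m + 1)
      if (s0 >= a + 120 || m >= 0) { # keep end-relative minutes out of earlysleep
        if (s0 >= 0 && s0 + 60 <= duration_s) {
          rows[[length(rows) + 1]] <- data.frame(
            start_s = s0, end_s = s0 + 60, label = lab, bout_id = sl$bout_id[i]
          )
        }
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(start_s = numeric(), end_s = numeric(), label = character(),
               bout_id = integer())
}

#' Crepuscular activity profile
#'
#' Per-minute fraction of frames moved, z-scored within fly, binned into
#' the six twilight windows: predawn 5-7 a.m., dawn 7-9 a.m., postdawn
#' 9-11 a.m., predusk 5-7 p.m., dusk 7-9 p.m., postdusk 9-11 p.m.
#'
#' @param trace a `movement_trace`.
#' @param clock_start "HH:MM" at recording onset.
#' @return data.frame `minute`, `tod_h` (hour of day), `z`, `period`
#'   (factor, NA outside the six windows).
#' @export
crepuscular_profile <- function(trace, clock_start = "08:00") {
  frac <- trace$per_minute_fraction
  s <- stats::sd(frac)
  if (is.na(s) || s == 0) {
    warning("zero variance in per-minute movement: z undefined, emitting zeros")
    z <- rep(0, length(frac))
  } else {
    z <- (frac - mean(frac)) / s
  }
  minute <- seq_along(frac) - 1
  tod_h <- time_of_day(minute * 60, clock_start) / 3600
  period <- rep(NA_character_, length(frac))
  period[tod_h >= 5 & tod_h < 7] <- "predawn"
  period[tod_h >= 7 & tod_h < 9] <- "dawn"
  period[tod_h >= 9 & tod_h < 11] <- "postdawn"
  period[tod_h >= 17 & tod_h < 19] <- "predusk"
  period[tod_h >= 19 & tod_h < 21] <- "dusk"
  period[tod_h >= 21 & tod_h < 23] <- "postdusk"
  if (all(is.na(period))) stop("recording overlaps no crepuscular window")
  data.frame(
    minute = minute, tod_h = tod_h, z = z,
    period = factor(period, levels = c("predawn", "dawn", "postdawn",
                                       "predusk", "dusk", "postdusk"))
  )
}
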