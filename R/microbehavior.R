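pose_parts <- function(trace) {
  unique(sub("_(x|y|likelihood)$", "",
             grep("_(x|y|likelihood)$", names(trace), value = TRUE)))
}

#' Low-pass and moving-average filtering of pose traces
#'
#' For each body part, computes a 0.1-Hz Butterworth low-pass baseline of
#' x and y (the slow posture drift) and a 5-sample moving average of the
#' raw coordinates; both are attached as derived columns
#' (`<part>_<x|y>_lp`, `<part>_<x|y>_ma`) alongside the raw trace.
#'
#' @param trace wide pose data.frame with `<part>_x/_y/_likelihood`
#'   columns and an `fps` attribute (or pass `fps`).
#' @param fps frame rate; defaults to the trace attribute.
#' @param ma_window moving-average window in samples.
#' @return the trace with derived columns added.
#' @export
filter_pose <- function(trace, fps = attr(trace, "fps"), ma_window = 5) {
  if (is.null(fps)) stop("fps unknown")
  if (nrow(trace) < 3 * ma_window) stop("trace shorter than filter warm-up")
  bf <- signal::butter(2, 0.1 / (fps / 2), type = "low")
  ma <- function(x) stats::filter(x, rep(1 / ma_window, ma_window),
                                  sides = 2)
  for (p in pose_parts(trace)) {
    for (ax in c("x", "y")) {
      col <- paste0(p, "_", ax)
      x <- trace[[col]]
      # filter about the mean: the very low cutoff otherwise drags long
      # edge transients across short traces
      lp <- as.numeric(signal::filtfilt(bf, x - mean(x))) + mean(x)
      m <- as.numeric(ma(x))
      # pad the moving-average edges with the raw signal
      m[is.na(m)] <- x[is.na(m)]
      trace[[paste0(col, "_lp")]] <- lp
      trace[[paste0(col, "_ma")]] <- m
    }
  }
  attr(trace, "fps") <- fps
  trace
}

#' Likelihood-weighted proboscis-to-eye distance
#'
#' Euclidean distance between the proboscis and eye positions, multiplied
#' by the proboscis likelihood, per frame.
#'
#' @param trace wide pose data.frame.
#' @return numeric vector, one value per frame.
#' @export
dist_eyeprob <- function(trace) {
  need <- c("proboscis_x", "proboscis_y", "eye_x", "eye_y",
            "proboscis_likelihood")
  if (!all(need %in% names(trace))) stop("missing proboscis or eye columns")
  d <- sqrt((trace$proboscis_x - trace$eye_x)^2 +
              (trace$proboscis_y - trace$eye_y)^2)
  d * trace$proboscis_likelihood
}

## Feature block for the frame classifier: filtered body parts, first
## differences, likelihoods, and dist_eyeprob.
pe_frame_features <- function(trace) {
  trace <- if (is.null(trace$proboscis_x_ma)) filter_pose(trace) else trace
  parts <- intersect(pose_parts(trace),
                     c("proboscis", "eye", "leg1_tip", "leg1_joint", "abdomen"))
  feats <- list()
  for (p in parts) {
    for (ax in c("x", "y")) {
      m <- trace[[paste0(p, "_", ax, "_ma")]]
      lp <- trace[[paste0(p, "_", ax, "_lp")]]
      feats[[paste0(p, "_", ax, "_dev")]] <- m - lp
      feats[[paste0(p, "_", ax, "_d1")]] <- c(0, diff(m))
    }
    feats[[paste0(p, "_lik")]] <- trace[[paste0(p, "_likelihood")]]
  }
  feats$dist_eyeprob <- dist_eyeprob(trace)
  as.matrix(as.data.frame(feats))
}

#' Detect candidate proboscis-extension frames
#'
#' Trains an RBF-kernel SVM on labeled example frames (features: filtered
#' body-part deviations and derivatives, likelihoods, and the likelihood-
#' weighted proboscis-eye distance; standardized; 70/30 train/test split)
#' and predicts PE frames over the whole trace. Candidates are augmented
#' by a likelihood-threshold rule: frames whose smoothed proboscis
#' likelihood sags below `lik_threshold` while flanked (within 1 s) by
#' classifier positives or lying inside a truth-like dip are added, which
#' recovers events the classifier misses during occlusions.
#'
#' @param trace wide pose data.frame.
#' @param truth_frames integer frame indices (1-based) of ground-truth PE
#'   frames for training.
#' @param seed RNG seed for subsampling and the split.
#' @param lik_threshold smoothed-likelihood threshold for augmentation.
#' @param max_train negatives are subsampled to at most this multiple of
#'   the positives.
#' @return list with `candidates` (logical per frame), `report`
#'   (`classifier_metrics` on the held-out 30%), `fps`.
#' @export
detect_pe_frames <- function(trace, truth_frames, seed = 1,
                             lik_threshold = 0.9, max_train = 3) {
  fps <- attr(trace, "fps")
  F <- pe_frame_features(trace)
  n <- nrow(F)
  y <- rep(0L, n)
  y[truth_frames[truth_frames >= 1 & truth_frames <= n]] <- 1L
  if (length(unique(y)) < 2) stop("need both PE and non-PE example frames")
  with_seed(seed, {
    idx <- sample.int(n)
    n_tr <- floor(0.7 * n)
    tr <- idx[seq_len(n_tr)]; te <- idx[(n_tr + 1):n]
    pos <- tr[y[tr] == 1]
    neg <- tr[y[tr] == 0]
    # keep every hard negative (likelihood dips that are not PEs, e.g.
    # occlusions) and subsample the easy rest
    hard <- neg[trace$proboscis_likelihood[neg] < 0.8]
    easy <- setdiff(neg, hard)
    easy <- sample(easy, min(length(easy), max_train * max(length(pos), 200)))
    fit_rows <- c(pos, hard, easy)
    sc <- fit_scaler(F[fit_rows, , drop = FALSE])
    fit <- e1071::svm(apply_scaler(F[fit_rows, , drop = FALSE], sc),
                      factor(y[fit_rows]), kernel = "radial", scale = FALSE)
    pred_all <- as.integer(as.character(
      stats::predict(fit, apply_scaler(F, sc))))
    report <- classifier_metrics(factor(y[te]), factor(pred_all[te],
                                                       levels = c(0, 1)))
    # augmentation: smoothed proboscis likelihood dips near positives
    lik <- stats::filter(trace$proboscis_likelihood, rep(1 / 5, 5), sides = 2)
    lik[is.na(lik)] <- trace$proboscis_likelihood[is.na(lik)]
    dip <- lik < lik_threshold
    # only brief dips count (a PE-driven likelihood sag is much shorter
    # than a full occlusion) and only with classifier support right next
    # to them
    dip_runs <- rle_runs(as.integer(dip))
    long_dips <- dip_runs[dip_runs$value == 1L &
                            dip_runs$length > round(0.8 * fps), , drop = FALSE]
    for (i in seq_len(nrow(long_dips))) {
      dip[long_dips$start[i]:long_dips$end[i]] <- FALSE
    }
    near <- stats::filter(pred_all, rep(1, 2 * round(fps / 4) + 1), sides = 2)
    near[is.na(near)] <- 0
    candidates <- pred_all == 1L | (dip & near > 0)
    # filter warm-up: the trace edges carry low-pass transients
    edge <- round(1.5 * fps)
    candidates[c(seq_len(min(edge, n)),
                 seq.int(max(n - edge + 1, 1), n))] <- FALSE
    list(candidates = as.logical(candidates), report = report, fps = fps)
  })
}

#' Build PE events and bursts from candidate frames
#'
#' Contiguous candidate runs (gaps under `merge_gap_s` closed) become
#' events; the event peak is the frame of maximal proboscis displacement
#' (dist_eyeprob). Events no more than 10 s apart share a burst; bursts
#' with one event are flagged single. Each event is tagged with the
#' behavioral state at its peak.
#'
#' @param candidates logical per frame (from [detect_pe_frames()]).
#' @param trace the pose trace (for peak localization).
#' @param state_labels data.frame `start_s`, `end_s` and a `stage`/`kind`/
#'   `label` column with values awake/sleep/presleep (stage labels are
#'   mapped to states).
#' @param fps frame rate.
#' @param merge_gap_s candidate gaps shorter than this merge into one
#'   event.
#' @param burst_gap_s events closer than this share a burst (10 s).
#' @param min_event_frames candidate runs shorter than this are discarded
#'   as classifier blips (a real extension spans many frames).
#' @return list with `events` (data.frame `peak_frame`, `time_s`, `state`,
#'   `burst_id`) and `bursts` (data.frame `burst_id`, `n_events`,
#'   `is_single`, `start_s`, `end_s`).
#' @export
construct_pe_events <- function(candidates, trace, state_labels = NULL,
                                fps = attr(trace, "fps"),
                                merge_gap_s = 0.2, burst_gap_s = 10,
                                min_event_frames = 3) {
  # peak = maximal proboscis displacement from the eye; the smoothed,
  # unweighted distance so occlusion-driven likelihood collapses cannot
  # displace the peak
  px <- trace$proboscis_x_ma %||% trace$proboscis_x
  py <- trace$proboscis_y_ma %||% trace$proboscis_y
  d <- sqrt((px - trace$eye_x)^2 + (py - trace$eye_y)^2)
  runs <- rle_runs(as.integer(candidates))
  ev_runs <- runs[runs$value == 1L, , drop = FALSE]
  if (nrow(ev_runs) > 1) {
    gaps <- (ev_runs$start[-1] - ev_runs$end[-nrow(ev_runs)]) / fps
    merge <- gaps < merge_gap_s
    grp <- cumsum(c(1, !merge))
    ev_runs <- do.call(rbind, lapply(split(ev_runs, grp), function(g) {
      data.frame(value = 1L, start = min(g$start), end = max(g$end),
                 length = max(g$end) - min(g$start) + 1)
    }))
  }
  ev_runs <- ev_runs[ev_runs$length >= min_event_frames, , drop = FALSE]
  if (!nrow(ev_runs)) {
    return(list(events = data.frame(peak_frame = integer(), time_s = numeric(),
                                    state = character(), burst_id = integer()),
                bursts = data.frame(burst_id = integer(), n_events = integer(),
                                    is_single = logical(), start_s = numeric(),
                                    end_s = numeric())))
  }
  peak <- vapply(seq_len(nrow(ev_runs)), function(i) {
    idx <- ev_runs$start[i]:ev_runs$end[i]
    idx[which.max(d[idx])]
  }, numeric(1))
  time_s <- (peak - 1) / fps
  burst_id <- cumsum(c(1, diff(time_s) > burst_gap_s))
  state <- rep(NA_character_, length(peak))
  if (!is.null(state_labels)) {
    lab_col <- intersect(c("stage", "kind", "label"), names(state_labels))[1]
    map_state <- function(v) {
      ifelse(v %in% c("earlysleep", "midsleep", "latesleep", "sleep"), "sleep",
             ifelse(v == "presleep", "presleep", "awake"))
    }
    for (i in seq_along(peak)) {
      hit <- which(state_labels$start_s <= time_s[i] &
                     state_labels$end_s > time_s[i])
      state[i] <- if (length(hit)) map_state(state_labels[[lab_col]][hit[1]])
      else "awake"
    }
  }
  events <- data.frame(peak_frame = as.integer(peak), time_s = time_s,
                       state = state, burst_id = burst_id)
  bursts <- do.call(rbind, lapply(split(events, events$burst_id), function(b) {
    data.frame(burst_id = b$burst_id[1], n_events = nrow(b),
               is_single = nrow(b) == 1,
               start_s = min(b$time_s), end_s = max(b$time_s))
  }))
  rownames(bursts) <- NULL
  list(events = events, bursts = bursts)
}

#' PE summary statistics
#'
#' Inter-PE interval distribution (with 95th percentile), single vs
#' multiple burst counts, per-event periodicity flags (an event is
#' periodic iff it follows its predecessor by less than `periodic_gap_s`;
#' the first event of a burst is periodic iff its successor is that
#' close), normalized event counts over the sleep-segment bins (-2:-1,
#' -1:0, +0:+1, +1:+2, mid, x:-2, x:-1), counts before vs after minute 5
#' of each sleep bout and each awake bout, and event times within
#' midsleep.
#'
#' @param events,bursts from [construct_pe_events()].
#' @param stage_labels a `stage_labels` data.frame (for segment bins).
#' @param bouts optional `bout_set` (for the minute-5 split).
#' @param periodic_gap_s periodicity rule threshold (6 s).
#' @return list with `intervals`, `interval_p95`, `n_single`,
#'   `n_multiple`, `periodic`, `segment_counts` (normalized, sums to 1
#'   when events exist), `before_after_5min`, `midsleep_times`.
#' @export
pe_statistics <- function(events, bursts, stage_labels = NULL, bouts = NULL,
                          periodic_gap_s = 6) {
  intervals <- numeric(0)
  periodic <- logical(nrow(events))
  if (nrow(events)) {
    for (b in unique(events$burst_id)) {
      idx <- which(events$burst_id == b)
      if (length(idx) > 1) {
        gaps <- diff(events$time_s[idx])
        intervals <- c(intervals, gaps)
        periodic[idx[-1]] <- gaps < periodic_gap_s
        periodic[idx[1]] <- gaps[1] < periodic_gap_s
      }
    }
  }
  seg_counts <- NULL
  midsleep_times <- numeric(0)
  before_after <- NULL
  if (!is.null(stage_labels) && nrow(events)) {
    bins <- c("-2:-1", "-1:0", "+0:+1", "+1:+2", "mid", "x:-2", "x:-1")
    cnt <- stats::setNames(numeric(length(bins)), bins)
    sl <- unique(stage_labels[!is.na(stage_labels$bout_id),
                              c("bout_id", "bout_start", "bout_end")])
    for (t in events$time_s) {
      for (i in seq_len(nrow(sl))) {
        a <- sl$bout_start[i]; b <- sl$bout_end[i]
        rel <- t - a; rel_end <- t - b
        lab <- if (rel >= -120 && rel < -60) "-2:-1"
        else if (rel >= -60 && rel < 0) "-1:0"
        else if (rel >= 0 && rel < 60) "+0:+1"
        else if (rel >= 60 && rel < 120) "+1:+2"
        else if (rel_end >= -120 && rel_end < -60) "x:-2"
        else if (rel_end >= -60 && rel_end < 0) "x:-1"
        else if (rel >= 120 && rel_end < -120) "mid"
        else NA_character_
        if (!is.na(lab)) {
          cnt[lab] <- cnt[lab] + 1
          if (lab == "mid") midsleep_times <- c(midsleep_times, rel)
          break
        }
      }
    }
    seg_counts <- if (sum(cnt) > 0) cnt / sum(cnt) else cnt
  }
  if (!is.null(bouts) && nrow(events)) {
    count_split <- function(kind) {
      bb <- bouts[bouts$kind == kind & bouts$end_s - bouts$start_s > 300, ,
                  drop = FALSE]
      before <- 0; after <- 0
      for (i in seq_len(nrow(bb))) {
        inb <- events$time_s >= bb$start_s[i] & events$time_s < bb$end_s[i]
        rel <- events$time_s[inb] - bb$start_s[i]
        before <- before + sum(rel < 300)
        after <- after + sum(rel >= 300)
      }
      c(before = before, after = after)
    }
    before_after <- rbind(sleep = count_split("sleep"),
                          awake = count_split("awake"))
  }
  list(
    intervals = intervals,
    interval_p95 = if (length(intervals)) {
      as.numeric(stats::quantile(intervals, 0.95))
    } else NA_real_,
    n_single = sum(bursts$is_single),
    n_multiple = sum(!bursts$is_single),
    periodic = periodic,
    segment_counts = seg_counts,
    before_after_5min = before_after,
    midsleep_times = midsleep_times
  )
}

#' Antennal angles corrected for head orientation
#'
#' Angle of each antennal tip about its base (atan2, degrees,
#' counterclockwise positive), corrected by the head-axis angle derived
#' from the two antennal bases (left base to right base). Whole-head
#' rotation therefore leaves the corrected angles unchanged. For the left
#' antenna the lateral axis is mirrored so both sides share the same sign
#' convention. Coincident base/tip frames yield NA.
#'
#' @param trace wide pose data.frame with `antennaL_base/_tip` and
#'   `antennaR_base/_tip` columns.
#' @return data.frame `left`, `right` (degrees per frame).
#' @export
antennal_angle <- function(trace) {
  need <- paste0(rep(c("antennaL_base", "antennaL_tip",
                       "antennaR_base", "antennaR_tip"), each = 2),
                 c("_x", "_y"))
  if (!all(need %in% names(trace))) stop("missing antenna base/tip columns")
  hx <- trace$antennaR_base_x - trace$antennaL_base_x
  hy <- trace$antennaR_base_y - trace$antennaL_base_y
  head_ang <- atan2(hy, hx)
  one <- function(side) {
    dx <- trace[[paste0("antenna", side, "_tip_x")]] -
      trace[[paste0("antenna", side, "_base_x")]]
    dy <- trace[[paste0("antenna", side, "_tip_y")]] -
      trace[[paste0("antenna", side, "_base_y")]]
    bad <- sqrt(dx^2 + dy^2) < 1e-9
    # rotate into the head frame
    ca <- cos(-head_ang); sa <- sin(-head_ang)
    xr <- ca * dx - sa * dy
    yr <- sa * dx + ca * dy
    if (side == "L") xr <- -xr # mirror so both sides read the same way
    ang <- atan2(yr, xr) * 180 / pi
    ang[bad] <- NA_real_
    ang
  }
  data.frame(left = one("L"), right = one("R"))
}

#' FFT-based periodicity over fixed time segments
#'
#' Splits an angle trace into `segment_s` segments, computes a Welch-
#' averaged spectrum per segment (sub-windows so the null peak
#' distribution is tame), and flags a segment periodic iff its dominant
#' peak in the band of interest is at least `power_ratio_threshold` times
#' the median spectral power. Also reports the dominant frequency and the
#' fractions of sleep and wake time that are periodic when state labels
#' are supplied.
#'
#' @param angle numeric per-frame angle trace (NA allowed).
#' @param fps frame rate.
#' @param segment_s segment length in seconds.
#' @param power_ratio_threshold dominant-peak to median-power ratio.
#' @param f_band frequency band of interest (Hz).
#' @param state_labels optional data.frame `start_s`, `end_s`, `kind`.
#' @return list with `segments` (data.frame `start_s`, `end_s`,
#'   `periodic`, `dominant_freq`, `ratio`), `fraction_sleep`,
#'   `fraction_wake`.
#' @export
periodicity_segments <- function(angle, fps, segment_s = 30,
                                 power_ratio_threshold = 4,
                                 f_band = c(1 / 3, 5), state_labels = NULL) {
  if (segment_s < 10 / f_band[1]) {
    stop("segment too short for the minimum frequency of interest")
  }
  n_seg_frames <- round(segment_s * fps)
  starts <- seq(1, length(angle) - n_seg_frames + 1, by = n_seg_frames)
  rows <- list()
  for (s in starts) {
    seg <- angle[s:(s + n_seg_frames - 1)]
    if (mean(is.na(seg)) > 0.2) next
    seg[is.na(seg)] <- mean(seg, na.rm = TRUE)
    w <- welch_psd(seg - mean(seg), fps, window_s = segment_s / 4)
    band <- w$freq >= f_band[1] & w$freq <= f_band[2]
    if (!any(band)) next
    ratio <- max(w$psd[band]) / stats::median(w$psd[band])
    rows[[length(rows) + 1]] <- data.frame(
      start_s = (s - 1) / fps, end_s = (s - 1) / fps + segment_s,
      periodic = ratio >= power_ratio_threshold,
      dominant_freq = w$freq[band][which.max(w$psd[band])],
      ratio = ratio
    )
  }
  segments <- if (length(rows)) do.call(rbind, rows) else
    data.frame(start_s = numeric(), end_s = numeric(), periodic = logical(),
               dominant_freq = numeric(), ratio = numeric())
  frac <- c(sleep = NA_real_, wake = NA_real_)
  if (!is.null(state_labels) && nrow(segments)) {
    mid <- (segments$start_s + segments$end_s) / 2
    st <- vapply(mid, function(t) {
      hit <- which(state_labels$start_s <= t & state_labels$end_s > t)
      if (length(hit)) state_labels$kind[hit[1]] else NA_character_
    }, character(1))
    for (k in c("sleep", "awake")) {
      sel <- st == k & !is.na(st)
      key <- if (k == "sleep") "sleep" else "wake"
      frac[key] <- if (any(sel)) mean(segments$periodic[sel]) else NA_real_
    }
  }
  list(segments = segments, fraction_sleep = frac[["sleep"]],
       fraction_wake = frac[["wake"]])
}

#' Resting-position PE detection (behavioral-rig variant)
#'
#' Computes the proboscis distance (and angle) from its median (resting)
#' position, finds peaks, and excludes tracking artifacts: peaks above a
#' plausible distance ceiling, single-frame peaks, and peaks with an
#' implausible instantaneous rise. A threshold-crossing alternative
#' returns event spans with duration and median angle. Periodicity uses
#' the same under-6-s rule as [pe_statistics()].
#'
#' @param x,y proboscis coordinates per frame.
#' @param fps frame rate.
#' @param min_height minimum peak distance from rest (px).
#' @param max_dist plausibility ceiling (px).
#' @param max_rise maximum plausible rise per frame (px).
#' @param threshold threshold for the alternative crossing detector;
#'   defaults to `min_height`.
#' @return list with `peaks` (data.frame `frame`, `time_s`, `height`,
#'   `periodic`), `crossings` (data.frame `start_s`, `end_s`,
#'   `duration_s`, `median_angle`), `resting` (c(x, y)).
#' @export
resting_pe_detection <- function(x, y, fps, min_height = 4, max_dist = 40,
                                 max_rise = 5, threshold = min_height) {
  rest <- c(stats::median(x), stats::median(y))
  d <- sqrt((x - rest[1])^2 + (y - rest[2])^2)
  ang <- atan2(y - rest[2], x - rest[1]) * 180 / pi
  pk <- pracma::findpeaks(d, minpeakheight = min_height)
  peaks <- data.frame(frame = integer(), time_s = numeric(),
                      height = numeric(), periodic = logical())
  if (!is.null(pk)) {
    keep <- rep(TRUE, nrow(pk))
    for (i in seq_len(nrow(pk))) {
      f0 <- pk[i, 2]
      if (pk[i, 1] > max_dist) keep[i] <- FALSE # implausible distance
      lo <- max(f0 - 1, 1); hi <- min(f0 + 1, length(d))
      if (all(d[c(lo, hi)] <= pk[i, 1] / 2)) {
        keep[i] <- FALSE # single-frame spike
      }
      rise <- if (f0 > 1) d[f0] - d[f0 - 1] else 0
      if (rise > max_rise) keep[i] <- FALSE # implausible rise time
    }
    pk <- pk[keep, , drop = FALSE]
    if (nrow(pk)) {
      ord <- order(pk[, 2])
      t_s <- (pk[ord, 2] - 1) / fps
      per <- rep(FALSE, length(t_s))
      if (length(t_s) > 1) {
        gaps <- diff(t_s)
        per[-1] <- gaps < 6
        per[1] <- gaps[1] < 6
      }
      peaks <- data.frame(frame = as.integer(pk[ord, 2]), time_s = t_s,
                          height = pk[ord, 1], periodic = per)
    }
  }
  runs <- rle_runs(as.integer(d > threshold))
  ev <- runs[runs$value == 1L & runs$length > 1, , drop = FALSE]
  crossings <- if (nrow(ev)) {
    data.frame(
      start_s = (ev$start - 1) / fps, end_s = ev$end / fps,
      duration_s = ev$length / fps,
      median_angle = vapply(seq_len(nrow(ev)), function(i) {
        stats::median(ang[ev$start[i]:ev$end[i]])
      }, numeric(1))
    )
  } else {
    data.frame(start_s = numeric(), end_s = numeric(),
               duration_s = numeric(), median_angle = numeric())
  }
  list(peaks = peaks, crossings = crossings, resting = rest)
}

#' Match detected PE events to ground truth
#'
#' Greedy one-to-one matching within `tol_s`; event-level accuracy is
#' matches divided by the larger of the truth and detected counts, so
#' both misses and spurious detections count against it.
#'
#' @param detected_times,truth_times event peak times (s).
#' @param tol_s matching tolerance (s).
#' @return list with `n_matched`, `n_truth`, `n_detected`, `accuracy`,
#'   `peak_errors_s`.
#' @export
match_pe_events <- function(detected_times, truth_times, tol_s = 0.5) {
  used <- rep(FALSE, length(detected_times))
  errs <- numeric(0)
  n_matched <- 0
  for (t in truth_times) {
    if (!length(detected_times)) break
    diffs <- abs(detected_times - t)
    diffs[used] <- Inf
    j <- which.min(diffs)
    if (length(j) && diffs[j] <= tol_s) {
      used[j] <- TRUE
      n_matched <- n_matched + 1
      errs <- c(errs, detected_times[j] - t)
    }
  }
  denom <- max(length(truth_times), length(detected_times), 1)
  list(n_matched = n_matched, n_truth = length(truth_times),
       n_detected = length(detected_times),
       accuracy = n_matched / denom, peak_errors_s = errs)
}
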