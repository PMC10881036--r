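## Convenience layer tying the modules into per-fly pipelines. Everything
## here is thin plumbing over the module functions; tests cover the
## modules and the closures through these entry points.

#' Movement trace of a session
#' @param session a `synthetic_session`.
#' @return a `movement_trace`.
#' @export
session_movement_trace <- function(session) {
  movement_trace(session$movement, session$fps)
}

#' Detected sleep/wake bouts of a session
#'
#' Runs the movement pipeline (prune, 5-min rule) on the session's
#' movement trace.
#'
#' @param session a `synthetic_session`.
#' @param min_run_s pruning window in seconds.
#' @return a `bout_set`.
#' @export
session_bouts <- function(session, min_run_s = 0.5) {
  tr <- prune_movement(session_movement_trace(session),
                       min_run_frames = max(1, round(min_run_s * session$fps)))
  label_states(tr, clock_start = session$clock_start)
}

#' Truth bouts as a `bout_set`
#' @param session a `synthetic_session`.
#' @return a `bout_set` built from ground truth.
#' @export
truth_bouts <- function(session) {
  b <- session$truth$bouts
  b$day_flag <- is_day(b$start_s, session$clock_start)
  attr(b, "clock_start") <- session$clock_start
  class(b) <- c("bout_set", "data.frame")
  b
}

#' Preprocess and re-reference a session's LFP
#'
#' 0.5-40 Hz zero-phase FIR bandpass with 50-Hz notch at 250 Hz, then
#' re-referencing against the polarity-reversal channel.
#'
#' @param session a `synthetic_session`.
#' @param reversal reversal channel; defaults to the session truth.
#' @return a `referenced_lfp`.
#' @export
session_referenced <- function(session,
                               reversal = session$truth$reversal_channel) {
  rec <- preprocess_lfp(session$lfp, fs = session$fs,
                        clock_start = session$clock_start)
  rereference(rec, reversal)
}

## Apply the 5-40 Hz featurization bandpass to referenced data.
featurize_band <- function(ref, f_lo = 5, f_hi = 40) {
  kern <- bandpass_kernel(ref$fs, f_lo, f_hi, trans_lo = 2, trans_hi = 10)
  for (ch in seq_len(nrow(ref$data))) {
    ref$data[ch, ] <- fir_zerophase(ref$data[ch, ], kern)
  }
  ref
}

#' Wake/sleep condition labels from a bout partition
#'
#' Awake residual time (presleep and probe windows excluded) is labeled
#' `awake`; early/mid/latesleep intervals are labeled `sleep`.
#'
#' @param stages a `stage_labels` data.frame.
#' @return data.frame `start_s`, `end_s`, `label`.
#' @export
labels_wake_sleep <- function(stages) {
  keep <- stages$stage %in% c("awake", "earlysleep", "midsleep", "latesleep")
  data.frame(
    start_s = stages$start_s[keep], end_s = stages$end_s[keep],
    label = ifelse(stages$stage[keep] == "awake", "awake", "sleep")
  )
}

#' Day/night sleep labels
#'
#' Sleep intervals labeled `daysleep`/`nightsleep` by bout-onset clock
#' time (lights on 8 a.m. to 8 p.m.).
#'
#' @param stages a `stage_labels` data.frame.
#' @param clock_start "HH:MM" at recording onset.
#' @return data.frame `start_s`, `end_s`, `label`.
#' @export
labels_daynight_sleep <- function(stages, clock_start) {
  keep <- stages$stage %in% c("earlysleep", "midsleep", "latesleep")
  st <- stages[keep, , drop = FALSE]
  data.frame(
    start_s = st$start_s, end_s = st$end_s,
    label = ifelse(is_day(st$bout_start, clock_start), "daysleep",
                   "nightsleep")
  )
}

#' PE-context labels (1-s epoch vocabulary)
#'
#' Labels every second awake/sleep/presleep and retags seconds inside a
#' PE burst span (padded by `pad_s`) as `awakeprob`/`sleepprob`/
#' `presleepprob`.
#'
#' @param session a `synthetic_session`.
#' @param pad_s padding around each burst span.
#' @return data.frame `start_s`, `end_s`, `label`.
#' @export
labels_pe_context <- function(session, pad_s = 0.75) {
  dur <- session$config$duration
  stage <- session$truth$stage_sec
  base <- ifelse(stage %in% c("earlysleep", "midsleep", "latesleep"), "sleep",
                 ifelse(stage == "presleep", "presleep", "awake"))
  pe <- session$truth$pe_events
  if (nrow(pe)) {
    for (b in unique(pe$burst_id)) {
      tt <- pe$time_s[pe$burst_id == b]
      a <- max(1, floor(min(tt) - pad_s) + 1)
      z <- min(dur, ceiling(max(tt) + pad_s))
      base[a:z] <- paste0(base[a:z], "prob")
    }
  }
  runs <- rle_runs(base)
  data.frame(start_s = runs$start - 1, end_s = runs$end,
             label = runs$value)
}

#' Stage-labeled spectral matrix for one fly
#'
#' Preprocess, re-reference, 5-40 Hz featurization bandpass, epoch by the
#' supplied labels, and compute per-epoch spectra.
#'
#' @param session a `synthetic_session`.
#' @param labels labels data.frame (`start_s`, `end_s`, `stage` or
#'   `label`).
#' @param epoch_s epoch length (s).
#' @param min_trials per-condition minimum (NULL = printed default).
#' @param fly_id identifier.
#' @param ref optional precomputed `referenced_lfp` (skips preprocessing).
#' @return a `spectral_matrix`.
#' @export
fly_spectra <- function(session, labels, epoch_s = 60, min_trials = NULL,
                        fly_id = "fly01", ref = NULL) {
  if (is.null(ref)) ref <- featurize_band(session_referenced(session))
  ep <- epoch_by_labels(ref, labels, epoch_s = epoch_s,
                        min_trials = min_trials, fly_id = fly_id)
  epoch_spectrum(ep)
}

#' Stage feature table for a cohort
#'
#' Builds the 2175-feature staging table across flies: truth bouts are
#' partitioned into stages, partial presleep windows are excluded, epochs
#' are cut (60 s) and featurized, and each midsleep epoch carries its
#' bout's midsleep duration (`midsleep_min`).
#'
#' @param cohort list of `synthetic_session`.
#' @param stages_of function(session) giving the `stage_labels` (defaults
#'   to the truth bout partition).
#' @param min_trials per-condition per-fly minimum (0 keeps everything).
#' @param keep stages to keep as rows.
#' @param refs optional list of precomputed featurized `referenced_lfp`
#'   (see [cohort_referenced()]), to share preprocessing across tables.
#' @return feature table data.frame (with `midsleep_min`).
#' @export
stage_feature_table <- function(cohort,
                                stages_of = function(s)
                                  segment_sleep_epochs(truth_bouts(s),
                                                       s$config$duration),
                                min_trials = 0,
                                keep = c("awake", "presleep", "earlysleep",
                                         "midsleep", "latesleep"),
                                refs = NULL) {
  spectra <- list(); metas <- list()
  for (i in seq_along(cohort)) {
    s <- cohort[[i]]
    st <- stages_of(s)
    st <- st[!st$partial & st$stage %in% keep, , drop = FALSE]
    sm <- fly_spectra(s, st, epoch_s = 60, min_trials = min_trials,
                      fly_id = names(cohort)[i] %||% sprintf("fly%02d", i),
                      ref = refs[[i]])
    # midsleep duration per epoch (minutes), NA outside midsleep
    mid <- st[st$stage == "midsleep", , drop = FALSE]
    ms_min <- rep(NA_real_, length(sm$start_s))
    for (j in seq_len(nrow(mid))) {
      inm <- sm$start_s >= mid$start_s[j] & sm$start_s < mid$end_s[j]
      ms_min[inm & sm$label == "midsleep"] <-
        (mid$end_s[j] - mid$start_s[j]) / 60
    }
    spectra[[length(spectra) + 1]] <- sm
    metas[[length(metas) + 1]] <- data.frame(midsleep_min = ms_min)
  }
  build_feature_table(spectra, meta = do.call(rbind, metas))
}

#' Minute-probe feature table for a cohort
#'
#' 60-s epochs labeled by minute offset relative to bout onset/offset
#' (see [minute_probe_labels()]), for classifier-probability probing.
#'
#' @param cohort list of `synthetic_session`.
#' @param refs optional list of precomputed featurized `referenced_lfp`.
#' @return feature table data.frame.
#' @export
probe_feature_table <- function(cohort, refs = NULL) {
  spectra <- list()
  for (i in seq_along(cohort)) {
    s <- cohort[[i]]
    st <- segment_sleep_epochs(truth_bouts(s), s$config$duration)
    pl <- minute_probe_labels(st, s$config$duration)
    if (!nrow(pl)) next
    spectra[[length(spectra) + 1]] <-
      fly_spectra(s, pl, epoch_s = 60, min_trials = 0,
                  fly_id = names(cohort)[i] %||% sprintf("fly%02d", i),
                  ref = refs[[i]])
  }
  build_feature_table(spectra)
}

#' Preprocess, re-reference and featurize every fly once
#'
#' @param cohort list of `synthetic_session`.
#' @return list of featurized `referenced_lfp`, reusable across the table
#'   builders.
#' @export
cohort_referenced <- function(cohort) {
  lapply(cohort, function(s) featurize_band(session_referenced(s)))
}

#' Memory-light cohort pipeline
#'
#' Generates flies one at a time, runs preprocessing/re-referencing once
#' per fly, computes the requested products, and discards the raw session
#' before the next fly, so large cohorts never hold all raw LFP at once.
#'
#' @param n_flies cohort size.
#' @param config shared [session_config()].
#' @param seed cohort seed (per-fly seeds are `seed + i`).
#' @param what subset of `c("contrast", "stages", "probes", "daynight")`.
#' @return list with `contrast_spectra` (per-fly `spectral_matrix` with
#'   awake/sleep labels), `stage_table`, `probe_table`, `daynight_table`
#'   (only the requested ones are non-NULL).
#' @export
cohort_pipeline <- function(n_flies, config, seed = config$seed,
                            what = c("contrast", "stages")) {
  contrast <- list()
  stage_sm <- list(); stage_meta <- list()
  probe_sm <- list(); dn_sm <- list()
  for (i in seq_len(n_flies)) {
    cfg_i <- config
    cfg_i$seed <- as.integer(seed + i)
    s <- generate_session(cfg_i, components = c("lfp", "movement"))
    fid <- sprintf("fly%02d", i)
    ref <- featurize_band(session_referenced(s))
    st <- segment_sleep_epochs(truth_bouts(s), cfg_i$duration)
    if ("contrast" %in% what) {
      contrast[[fid]] <- fly_spectra(s, labels_wake_sleep(st), epoch_s = 60,
                                     min_trials = 0, fly_id = fid, ref = ref)
    }
    if ("stages" %in% what) {
      stf <- st[!st$partial & st$stage %in%
                  c("awake", "presleep", "earlysleep", "midsleep",
                    "latesleep"), , drop = FALSE]
      sm <- fly_spectra(s, stf, epoch_s = 60, min_trials = 0,
                        fly_id = fid, ref = ref)
      mid <- stf[stf$stage == "midsleep", , drop = FALSE]
      ms_min <- rep(NA_real_, length(sm$start_s))
      for (j in seq_len(nrow(mid))) {
        inm <- sm$start_s >= mid$start_s[j] & sm$start_s < mid$end_s[j]
        ms_min[inm & sm$label == "midsleep"] <-
          (mid$end_s[j] - mid$start_s[j]) / 60
      }
      stage_sm[[fid]] <- sm
      stage_meta[[fid]] <- data.frame(midsleep_min = ms_min)
    }
    if ("probes" %in% what) {
      pl <- minute_probe_labels(st, cfg_i$duration)
      if (nrow(pl)) {
        probe_sm[[fid]] <- fly_spectra(s, pl, epoch_s = 60, min_trials = 0,
                                       fly_id = fid, ref = ref)
      }
    }
    if ("daynight" %in% what) {
      dl <- labels_daynight_sleep(st, s$clock_start)
      if (nrow(dl)) {
        dn_sm[[fid]] <- fly_spectra(s, dl, epoch_s = 60, min_trials = 0,
                                    fly_id = fid, ref = ref)
      }
    }
    rm(s, ref)
  }
  list(
    contrast_spectra = if (length(contrast)) contrast else NULL,
    stage_table = if (length(stage_sm)) {
      build_feature_table(stage_sm, meta = do.call(rbind, stage_meta))
    } else NULL,
    probe_table = if (length(probe_sm)) build_feature_table(probe_sm) else NULL,
    daynight_table = if (length(dn_sm)) build_feature_table(dn_sm) else NULL
  )
}
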