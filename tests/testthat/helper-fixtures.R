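# Shared synthetic fixtures, cached for the whole test session so the
# expensive cohorts are generated once no matter which file needs them.

fx_small_session <- function() {
  flysleeplfp:::cached("small_session", function() {
    generate_session(session_config(duration = 1800, seed = 3),
                     components = c("lfp", "movement", "pose"))
  })
}

# 13-fly cohort driving the wake/sleep cluster contrast, the 5-class
# staging table and the minute probes.
fx_acc_bundle <- function() {
  flysleeplfp:::cached("acc_bundle", function() {
    cohort_pipeline(13, session_config(duration = 3600, seed = 0),
                    seed = 20, what = c("contrast", "stages", "probes"))
  })
}

# day/night cohort: evening start so sleep falls on both sides of
# lights-off
fx_dn_bundle <- function() {
  flysleeplfp:::cached("dn_bundle", function() {
    cohort_pipeline(6, session_config(duration = 7200, clock_start = "19:00",
                                      seed = 0),
                    seed = 400, what = "daynight")
  })
}

# proboscis-extension detection across 10 pose-only flies
fx_pe_results <- function() {
  flysleeplfp:::cached("pe_results", function() {
    lapply(1:10, function(i) {
      cfg <- session_config(duration = 2700, seed = 1000 + i)
      s <- generate_session(cfg, components = c("movement", "pose"))
      tr <- filter_pose(s$pose)
      truth_t <- s$truth$pe_events$time_s
      if (length(truth_t) < 3) {
        return(list(skip = TRUE))
      }
      truth_frames <- unique(unlist(lapply(truth_t, function(t0) {
        round(t0 * s$fps) + (-6:6)
      })))
      det <- detect_pe_frames(tr, truth_frames, seed = 1)
      st <- segment_sleep_epochs(truth_bouts(s), cfg$duration)
      ev <- construct_pe_events(det$candidates, tr, st, fps = s$fps)
      list(skip = FALSE, session = s, detection = det, events = ev,
           truth_t = truth_t,
           match = match_pe_events(ev$events$time_s, truth_t))
    })
  })
}

# the five-iteration awake/midsleep probability stager on the 13-fly table
fx_stager <- function() {
  flysleeplfp:::cached("stager", function() {
    train_probability_stager(fx_acc_bundle()$stage_table, seed = 1)
  })
}
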