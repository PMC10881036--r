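#!/usr/bin/env Rscript
# Generate the demo cohort used by the downstream analysis scripts:
# six flies, one hour each, with ground-truth sleep bouts, PE events and
# antennal periodicity, plus one behavior-only fly with raw video frames.
# Writes per-fly bundles under results/sessions/.

suppressMessages(library(flysleeplfp))

dir.create("results/sessions", recursive = TRUE, showWarnings = FALSE)

cfg <- session_config(duration = 3600, seed = 1)
cohort <- generate_cohort(8, cfg, seed = 100,
                          components = c("lfp", "movement", "pose"))
for (i in seq_along(cohort)) {
  write_session(cohort[[i]], file.path("results/sessions", names(cohort)[i]))
}
saveRDS(cohort, "results/sessions/cohort.rds")

# a short frame-stack session for the image-based movement pipeline
cfg_video <- session_config(duration = 1500, fps_video = 5, seed = 4)
video_fly <- generate_session(cfg_video, components = c("movement", "frames"))
saveRDS(video_fly, "results/sessions/video_fly.rds")

truth <- do.call(rbind, lapply(seq_along(cohort), function(i) {
  b <- cohort[[i]]$truth$bouts
  data.frame(fly = names(cohort)[i], onset_s = b$start_s, offset_s = b$end_s,
             label = b$kind)
}))
write.csv(truth, "results/truth_bouts.csv", row.names = FALSE)

n_sleep <- sum(truth$label == "sleep")
message(sprintf("Simulated %d flies; %d ground-truth sleep bouts in total.",
                length(cohort), n_sleep))
message("Session bundles in results/sessions/.")
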