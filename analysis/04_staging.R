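#!/usr/bin/env Rscript
# Classifier-based staging: the awake/midsleep linear-SVM probability
# probe across minutes around sleep onset/offset, the short-vs-long
# midsleep classifier, and the multiclass random forest with permutation
# importance.

suppressMessages(library(flysleeplfp))

cohort <- readRDS("results/sessions/cohort.rds")
refs <- cohort_referenced(cohort)
tab <- stage_feature_table(cohort, refs = refs)
ptab <- probe_feature_table(cohort, refs = refs)
message(sprintf("Feature table: %d epochs x %d features.",
                nrow(tab), sum(grepl("^ch", names(tab)))))
print(table(tab$label))

## SVM probability probing of unseen epochs
m <- train_probability_stager(tab, seed = 1)
acc <- sapply(m$iterations, function(it) it$report$accuracy)
message(sprintf("Awake/midsleep SVM held-out accuracy: %s.",
                paste(round(acc, 3), collapse = " ")))
pr <- probe_unseen_epochs(m, tab, probe_labels = c("awake", "presleep",
                                                   "earlysleep", "midsleep",
                                                   "latesleep"))
pm <- probe_unseen_epochs(m, ptab)
probe_out <- rbind(pr, pm)
write.csv(probe_out, "results/svm_probe_probabilities.csv", row.names = FALSE)
message("Mean awake-class probability by label:")
print(round(tapply(probe_out$mean_prob, probe_out$label, mean), 3))

## short vs long midsleep
ms <- try(train_midsleep_duration_stager(tab, seed = 1), silent = TRUE)
if (!inherits(ms, "try-error")) {
  acc_ms <- sapply(ms$iterations, function(it) it$report$accuracy)
  message(sprintf("Short/long midsleep SVM accuracy: %s (no duration-linked spectral difference is simulated, so near-chance values are the expected outcome).",
                  paste(round(acc_ms, 2), collapse = " ")))
}

## multiclass random forest with importance
rf <- train_rf_multiclass(tab, classes = c("awake", "presleep", "earlysleep",
                                           "midsleep", "latesleep"),
                          seed = 2)
message("Per-class metrics (mean over 5 iterations):")
print(round(rf$mean_per_class, 3))
imp <- rf$importance
grid <- feature_freq_grid()
imp_df <- data.frame(channel = rep(seq_len(nrow(imp)), times = ncol(imp)),
                     freq_hz = rep(grid, each = nrow(imp)),
                     importance = as.vector(imp))
write.csv(imp_df, "results/rf_importance_map.csv", row.names = FALSE)
block <- imp[1:3, grid <= 10]
message(sprintf("Importance mass in central 5-10 Hz block: %.0f%% (block is %.1f%% of features).",
                100 * sum(pmax(block, 0)) / sum(pmax(imp, 0)),
                100 * length(block) / length(imp)))
write.csv(data.frame(class = rownames(rf$mean_per_class),
                     round(rf$mean_per_class, 4)),
          "results/rf_multiclass_metrics.csv", row.names = FALSE)
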