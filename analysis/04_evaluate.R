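#!/usr/bin/env Rscript
# Evaluate the stored classifiers on the 11 held-out test subjects: balanced
# chronological test sets (all targets + the earliest equal number of
# non-targets), per-subject accuracy/precision/recall, cohort averages, and
# pooled pairwise McNemar comparisons. Writes the results tables and, when
# ggplot2 is available, a per-subject accuracy figure.

source("analysis/00_study_settings.R")
ensure_dirs()

models <- list(sae = readRDS(file.path(MODEL_DIR, "sae.rds")),
               mlp = readRDS(file.path(MODEL_DIR, "mlp.rds")),
               lda = readRDS(file.path(MODEL_DIR, "lda.rds")))
fp <- STUDY_CONFIG$feature_params

per_subject <- list()
pooled <- list(truth = character(0), sae = character(0),
               mlp = character(0), lda = character(0))
for (i in TEST_IDX) {
  prof <- STUDY_PROFILES[[i]]
  rec <- read_container(file.path(DATA_DIR, paste0(prof$subject_id, ".rds")))
  es <- select_test_trials(extract_epochs(rec, STUDY_SIM$target_code,
                                          STUDY_SIM$nontarget_code,
                                          fp$pre_ms, fp$post_ms))
  fm <- feature_pipeline(es)
  pooled$truth <- c(pooled$truth, as.character(fm$labels))
  for (m in names(models)) {
    pred <- predict(models[[m]], fm)$class
    pooled[[m]] <- c(pooled[[m]], as.character(pred))
    mt <- metrics(confusion(fm$labels, pred))
    per_subject[[length(per_subject) + 1L]] <- data.frame(
      subject = prof$subject_id, classifier = m, n_trials = n_trials(es),
      accuracy = mt[["accuracy"]], precision = mt[["precision"]],
      recall = mt[["recall"]])
  }
}
per_subject <- do.call(rbind, per_subject)
averages <- aggregate(cbind(accuracy, precision, recall) ~ classifier,
                      per_subject, mean)

pairs <- combn(names(models), 2, simplify = FALSE)
mc <- do.call(rbind, lapply(pairs, function(pr) {
  r <- mcnemar_compare(pooled[[pr[1]]], pooled[[pr[2]]], pooled$truth)
  data.frame(classifier_a = pr[1], classifier_b = pr[2],
             b = r$b, c = r$c, p_value = r$p_value, method = r$method)
}))

write.csv(per_subject, file.path(RESULTS_DIR, "04_per_subject.csv"), row.names = FALSE)
write.csv(averages, file.path(RESULTS_DIR, "04_averages.csv"), row.names = FALSE)
write.csv(mc, file.path(RESULTS_DIR, "04_mcnemar.csv"), row.names = FALSE)

cat("Average classification performance over the 11 test subjects:\n")
print(within(averages, {accuracy <- round(accuracy, 1)
                        precision <- round(precision, 1)
                        recall <- round(recall, 1)}), row.names = FALSE)
cat("\nMcNemar paired comparisons (pooled test trials):\n")
print(within(mc, p_value <- signif(p_value, 3)), row.names = FALSE)

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  gg <- ggplot(per_subject, aes(subject, accuracy, fill = classifier)) +
    geom_col(position = "dodge") +
    geom_hline(yintercept = 50, linetype = 2) +
    labs(y = "Accuracy (%)", x = NULL,
         title = "Per-subject single-trial P300 detection accuracy") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
  ggsave(file.path(RESULTS_DIR, "04_per_subject_accuracy.pdf"), gg,
         width = 8, height = 4)
  cat(sprintf("\nFigure written to %s.\n",
              file.path(RESULTS_DIR, "04_per_subject_accuracy.pdf")))
}
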