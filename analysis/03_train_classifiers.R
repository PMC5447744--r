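#!/usr/bin/env Rscript
# Train the three classifiers on the pooled balanced training set: the
# stacked sparse autoencoder (greedy pretraining of the 209-130-100-50-20
# stack, softmax head, joint fine-tuning), the same-architecture MLP
# (backpropagation only), and shrinkage-regularized LDA. Stores the fitted
# models and reports training-set and validation-split accuracy.

source("analysis/00_study_settings.R")
ensure_dirs()

tab <- read.csv(file.path(DATA_DIR, "training_features.csv"))
labels <- factor(tab$label, levels = c("nontarget", "target"))
X <- as.matrix(tab[, setdiff(names(tab), c("label", "subject"))])
fm <- new_features(X, labels, colnames(X), subject_ids = tab$subject)

cat(sprintf("Training on %d trials x %d features\n", nrow(X), ncol(X)))

models <- list()
t0 <- Sys.time()
models$sae <- train_sae(fm, STUDY_CONFIG$sae_hyper,
                        p300sae:::derive_seed(MASTER_SEED, 6))
cat(sprintf("  SAE   (%s): %.1f s\n", architecture_string(models$sae),
            as.numeric(Sys.time() - t0, units = "secs")))
t0 <- Sys.time()
models$mlp <- train_mlp(fm, STUDY_CONFIG$sae_hyper$layer_sizes,
                        STUDY_CONFIG$mlp_iterations,
                        p300sae:::derive_seed(MASTER_SEED, 7))
cat(sprintf("  MLP   (%s): %.1f s\n", architecture_string(models$mlp),
            as.numeric(Sys.time() - t0, units = "secs")))
t0 <- Sys.time()
models$lda <- train_shrinkage_lda(fm)
cat(sprintf("  LDA   (shrinkage %.3f): %.1f s\n",
            models$lda$shrinkage_intensity,
            as.numeric(Sys.time() - t0, units = "secs")))

for (m in names(models)) {
  saveRDS(models[[m]], file.path(MODEL_DIR, paste0(m, ".rds")))
}

# training-set fit and a 20% validation split as an overfitting gauge
sp <- split_validation(fm, 0.2, p300sae:::derive_seed(MASTER_SEED, 8))
rows <- lapply(names(models), function(m) {
  acc <- function(part) {
    metrics(confusion(part$labels, predict(models[[m]], part)$class))[["accuracy"]]
  }
  data.frame(classifier = m, train_accuracy = acc(fm),
             validation_accuracy = acc(sp$validation))
})
fit_tab <- do.call(rbind, rows)
write.csv(fit_tab, file.path(RESULTS_DIR, "03_training_fit.csv"),
          row.names = FALSE)
print(fit_tab, row.names = FALSE)
cat(sprintf("\nModels stored under %s/.\n", MODEL_DIR))
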