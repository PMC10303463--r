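#!/usr/bin/env Rscript
# Train the encoder-decoder segmenter on the training split with weighted
# cross-entropy and early stopping on the validation split.

source("analysis/_common.R")

by_split <- pairs_by_split(read_pairs())
cat("training on", length(by_split$train), "images, validating on",
    length(by_split$validation), "\n")

state <- train_segmenter(by_split$train, by_split$validation,
                         CONFIG$segmenter)
saveRDS(state, file.path(STUDY_DIR, "segmenter.rds"))

cat("class weights (inverse pixel frequency):",
    round(state$class_weights, 3), "\n")
cat("best validation WCEL", round(min(state$curves$val_wcel), 4),
    "at epoch", state$best_epoch, "of", nrow(state$curves), "\n")
utils::write.csv(state$curves, "results/training_curves.csv",
                 row.names = FALSE)
cat("wrote results/training_curves.csv\n")
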