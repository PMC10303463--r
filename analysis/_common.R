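# Shared settings for the numbered analysis scripts: the demo-scale study
# (32 phantoms split 16/4/4/8, 96 x 64 training images, tiny
# encoder-decoder) with a fixed master seed. Binary intermediates accumulate
# under scratch/study; tables and figures go to results/. Each script
# reuses what the previous ones wrote.

library(steersim)

MASTER_SEED <- 1L
CONFIG <- demo_study_config(master_seed = MASTER_SEED)
STUDY_DIR <- "scratch/study"
dir.create(STUDY_DIR, recursive = TRUE, showWarnings = FALSE)

GEOMETRY <- ngt_geometry(scale = CONFIG$geometry_scale)
MATERIALS <- material_table()

read_pairs <- function() readRDS(file.path(STUDY_DIR, "pairs.rds"))
pairs_by_split <- function(pairs) {
  split(pairs, factor(vapply(pairs, function(p) p$split, character(1)),
                      levels = c("train", "validation", "calibration",
                                 "test")))
}
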