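#!/usr/bin/env Rscript
# Build the phantom cohort: compressed-breast outlines, Perlin-noise
# parenchyma at the drawn breast densities, two lesions per phantom, and
# the stratified train/validation/calibration/test split.

source("analysis/_common.R")

manifest <- build_cohort(CONFIG$cohort, MASTER_SEED,
                         out_dir = file.path(STUDY_DIR, "phantoms"))
saveRDS(manifest, file.path(STUDY_DIR, "manifest.rds"))

cat("cohort of", nrow(manifest), "phantoms\n")
cat("split sizes:\n")
print(table(manifest$split))
cat("\nCBT (mm) range:", range(manifest$cbt_mm),
    "| CND (mm) range:", range(manifest$cnd_mm), "\n")
cat("realized VBD: median", round(median(manifest$vbd), 3),
    "range", round(range(manifest$vbd), 3), "\n")
cat("lesion models drawn:\n")
print(table(c(manifest$lesion1_model, manifest$lesion2_model)))
utils::write.csv(manifest[, setdiff(names(manifest), "path")],
                 file.path("results", "cohort_manifest.csv"),
                 row.names = FALSE)
cat("\nwrote results/cohort_manifest.csv and", file.path(STUDY_DIR, "phantoms"), "\n")
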