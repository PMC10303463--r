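#!/usr/bin/env Rscript
# Simulate the low-dose central projection of every phantom (Siddon ray
# tracing, AEC-scaled exposure, Poisson noise), derive the MIP risk maps,
# and assemble the cropped/downsampled (image, risk map) training pairs.

source("analysis/_common.R")

manifest <- readRDS(file.path(STUDY_DIR, "manifest.rds"))
crop <- cohort_crop_window(manifest, GEOMETRY, CONFIG$out_dims)
cat("detector grid:", GEOMETRY$n_v, "x", GEOMETRY$n_u,
    "| crop rows:", crop$rows, "| training dims:",
    paste(crop$out_dims, collapse = " x "), "\n")

tiff_dir <- file.path(STUDY_DIR, "projections")
dir.create(tiff_dir, showWarnings = FALSE)
pairs <- vector("list", nrow(manifest))
exposures <- numeric(nrow(manifest))
for (i in seq_len(nrow(manifest))) {
  ph <- readRDS(manifest$path[i])
  expo <- aec_exposure(ph$cbt_mm, ph$vbd, CONFIG$aec_target, MATERIALS)
  exposures[i] <- expo$photons_per_pixel_air
  proj <- project(ph, GEOMETRY, expo, MATERIALS,
                  noise_seed = steersim:::derive_seed(MASTER_SEED, 5000L + i))
  write_projection_tiff(proj, file.path(
    tiff_dir, paste0(manifest$phantom_id[i], ".tif")))
  rm_p <- rescale_to_projection(compute_mip(ph), GEOMETRY,
                                origin_x = steersim:::phantom_x_offset(
                                  ph, GEOMETRY))
  write_risk_map_png(rm_p, file.path(
    tiff_dir, paste0(manifest$phantom_id[i], "_risk.png")))
  pairs[[i]] <- make_training_pair(proj, rm_p, crop,
                                   phantom_id = manifest$phantom_id[i],
                                   split = as.character(manifest$split[i]))
}
saveRDS(pairs, file.path(STUDY_DIR, "pairs.rds"))

cat("AEC photons/pixel (air): median", round(median(exposures)),
    "range", round(range(exposures)), "\n")
n_lesions <- vapply(pairs, function(p) extract_findings(p$target)$n,
                    integer(1))
cat("ground-truth lesion clusters per training pair:\n")
print(table(n_lesions))
cat("wrote", length(pairs), "pairs,", STUDY_DIR, "/projections/*.tif|png\n")
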