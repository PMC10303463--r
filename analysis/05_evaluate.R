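#!/usr/bin/env Rscript
# Evaluate the test split before and after Dirichlet calibration:
# pooled per-class ROC/AUC with operating points, Dice/Jaccard,
# classwise-ECE, finding-level TP/FP/FN, and FROC curves.

source("analysis/_common.R")

by_split <- pairs_by_split(read_pairs())
state <- readRDS(file.path(STUDY_DIR, "segmenter.rds"))
cal <- readRDS(file.path(STUDY_DIR, "calibration.rds"))

test_probs <- lapply(by_split$test, function(p) {
  predict_probabilities(state, p$image)
})
test_targets <- lapply(by_split$test, function(p) p$target)
report <- steersim:::evaluate_study(test_probs, test_targets, cal$map,
                                    CONFIG)
report$calibration_nll <- cal$nll
steersim:::write_study_report(report, "results/report")

for (arm in c("pre_calibration", "post_calibration")) {
  a <- report[[arm]]
  cat("\n====", arm, "====\n")
  cat("classwise-ECE:", round(a$classwise_ece, 4), "\n")
  tab <- merge(a$segmentation[, c("class", "dice", "jaccard")],
               a$roc, by = "class", all.x = TRUE)
  print(round(tab[, c("class", "dice", "jaccard", "auc", "tpr", "tnr",
                      "ppv", "npv")], 3))
  cat("findings from output predictions: TP",
      a$finding_counts_predicted$tp, "FP", a$finding_counts_predicted$fp,
      "FN", a$finding_counts_predicted$fn, "\n")
  cat("FROC sensitivity at 2 / 5 FP per image:",
      round(100 * a$sensitivity_at_fp, 1), "%\n")
}

# FROC overlay figure
grDevices::png("results/froc.png", width = 700, height = 550)
pre <- report$pre_calibration$froc
post <- report$post_calibration$froc
plot(pre$fp_per_image, 100 * pre$sensitivity, type = "s", col = "grey40",
     xlab = "mean FP findings per image", ylab = "TP findings (%)",
     main = "FROC before/after Dirichlet calibration", ylim = c(0, 100))
graphics::lines(post$fp_per_image, 100 * post$sensitivity, type = "s",
                col = "firebrick")
graphics::legend("bottomright", c("before DC", "after DC"),
                 col = c("grey40", "firebrick"), lty = 1)
grDevices::dev.off()
cat("\nwrote results/report/ and results/froc.png\n")
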