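#' Study configuration
#'
#' Bundles the per-stage configurations of the full study: cohort,
#' acquisition, ground-truth geometry, segmenter, calibration and
#' evaluation, plus the master seed. `demo_study_config()` is sized for a
#' single CPU (32 phantoms split 16/4/4/8, 64 x 96 training images, a tiny
#' network); `paper_scale_study_config()` reproduces the full cohort shape
#' (264 phantoms split 168/24/24/48, 360 x 600 images) and is orders of
#' magnitude more expensive - expect GPU-scale runtimes.
#'
#' @param cohort a [cohort_config()].
#' @param geometry_scale detector-element multiplier for [ngt_geometry()].
#' @param out_dims training-pair dims (rows = posteroanterior, cols =
#'   left-right).
#' @param segmenter a [segmenter_config()].
#' @param aec_target transmitted-count target of [aec_exposure()].
#' @param calibration_m reliability bins.
#' @param calibration_max_pixels subsample cap of [fit_dirichlet()].
#' @param fp_report_points FP/image points for FROC reporting.
#' @param min_finding_area smallest retained finding, pixels.
#' @param master_seed seed from which all stage seeds derive.
#' @export
study_config <- function(cohort = cohort_config(),
                         geometry_scale = 8,
                         out_dims = c(96L, 64L),
                         segmenter = segmenter_config(),
                         aec_target = 50,
                         calibration_m = 10L,
                         calibration_max_pixels = 2e5,
                         fp_report_points = c(2, 5),
                         min_finding_area = 1L,
                         master_seed = 1L) {
  structure(as.list(environment()), class = "study_config")
}

#' @rdname study_config
#' @export
demo_study_config <- function(master_seed = 1L) {
  study_config(
    cohort = cohort_config(n_phantoms = 32L, split_ratio = c(16L, 4L, 4L, 8L),
                           voxel_pitch_mm = 1.0),
    geometry_scale = 8,
    out_dims = c(96L, 64L),
    segmenter = segmenter_config(depth = 3L, base_channels = 8L,
                                 batch_size = 4L, learning_rate = 3e-4,
                                 max_epochs = 20L, patience = 6L,
                                 seed = derive_seed(master_seed, 4242L)),
    master_seed = master_seed
  )
}

#' @rdname study_config
#' @export
paper_scale_study_config <- function(master_seed = 1L) {
  warning("paper-scale configuration: 264 phantoms at 0.5 mm pitch and ",
          "600 x 360 images are far beyond desk-scale compute")
  study_config(
    cohort = cohort_config(n_phantoms = 264L,
                           split_ratio = c(168L, 24L, 24L, 48L),
                           voxel_pitch_mm = 0.5),
    geometry_scale = 4,
    out_dims = c(600L, 360L),
    segmenter = segmenter_config(depth = 4L, base_channels = 16L,
                                 batch_size = 6L, learning_rate = 3e-4,
                                 max_epochs = 250L, patience = 20L,
                                 seed = derive_seed(master_seed, 4242L)),
    master_seed = master_seed
  )
}

# content hash of a config fragment, for stage caching
config_hash <- function(...) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(list(...), f, compress = FALSE, version = 2)
  # skip the RDS header so R version strings don't perturb the hash
  unname(tools::md5sum(f))
}

stage_cached <- function(dir, name, hash, outputs) {
  key <- file.path(dir, paste0(name, ".hash"))
  file.exists(key) && identical(readLines(key, warn = FALSE), hash) &&
    all(file.exists(outputs))
}

stage_done <- function(dir, name, hash) {
  writeLines(hash, file.path(dir, paste0(name, ".hash")))
}

#' Run the full study
#'
#' Executes cohort generation, projection simulation, ground-truth
#' derivation, segmenter training, Dirichlet calibration and evaluation in
#' order, with per-stage content hashes so an unchanged rerun reuses
#' cached artifacts. The report compares segmentation and
#' finding-detection metrics before and after calibration.
#'
#' @param config a [study_config()].
#' @param out_dir artifact directory.
#' @param verbose print stage progress.
#' @return a `study_report` list (also serialized to JSON/CSV in
#'   `out_dir/report`).
#' @export
run_study <- function(config, out_dir = tempfile("study"), verbose = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  seed <- config$master_seed

  # ---- stage 1: cohort --------------------------------------------------
  h1 <- config_hash("cohort", config$cohort, seed)
  man_path <- file.path(out_dir, "manifest.rds")
  if (!stage_cached(out_dir, "cohort", h1, man_path)) {
    say("[cohort] building %d phantoms", config$cohort$n_phantoms)
    manifest <- build_cohort(config$cohort, seed,
                             file.path(out_dir, "phantoms"))
    saveRDS(manifest, man_path)
    stage_done(out_dir, "cohort", h1)
  } else say("[cohort] cached")
  manifest <- readRDS(man_path)

  # ---- stage 2+3: projections and training pairs ------------------------
  geometry <- ngt_geometry(scale = config$geometry_scale)
  materials <- material_table()
  h2 <- config_hash("pairs", h1, config$geometry_scale, config$out_dims,
                    config$aec_target)
  pairs_path <- file.path(out_dir, "pairs.rds")
  if (!stage_cached(out_dir, "pairs", h2, pairs_path)) {
    say("[projection] simulating %d central projections", nrow(manifest))
    crop <- cohort_crop_window(manifest, geometry, config$out_dims)
    pairs <- vector("list", nrow(manifest))
    for (i in seq_len(nrow(manifest))) {
      ph <- readRDS(manifest$path[i])
      exposure <- aec_exposure(ph$cbt_mm, ph$vbd, config$aec_target,
                               materials)
      proj <- project(ph, geometry, exposure, materials,
                      noise_seed = derive_seed(seed, 5000L + i))
      rm_p <- rescale_to_projection(compute_mip(ph), geometry,
                                    origin_x = phantom_x_offset(ph, geometry))
      pairs[[i]] <- make_training_pair(proj, rm_p, crop,
                                       phantom_id = manifest$phantom_id[i],
                                       split = as.character(manifest$split[i]))
    }
    saveRDS(pairs, pairs_path)
    stage_done(out_dir, "pairs", h2)
  } else say("[pairs] cached")
  pairs <- readRDS(pairs_path)

  splits <- vapply(pairs, function(p) p$split, character(1))
  by_split <- split(pairs, factor(splits, levels = SPLIT_NAMES))

  # ---- stage 4: segmenter -----------------------------------------------
  h3 <- config_hash("train", h2, config$segmenter)
  model_path <- file.path(out_dir, "segmenter.rds")
  if (!stage_cached(out_dir, "train", h3, model_path)) {
    say("[train] %d train / %d validation images",
        length(by_split$train), length(by_split$validation))
    state <- train_segmenter(by_split$train, by_split$validation,
                             config$segmenter)
    saveRDS(state, model_path)
    stage_done(out_dir, "train", h3)
  } else say("[train] cached")
  state <- readRDS(model_path)

  # ---- stage 5: calibration ---------------------------------------------
  h4 <- config_hash("calibrate", h3, config$calibration_m,
                    config$calibration_max_pixels)
  cal_path <- file.path(out_dir, "calibration.rds")
  if (!stage_cached(out_dir, "calibrate", h4, cal_path)) {
    say("[calibrate] fitting Dirichlet map on %d calibration images",
        length(by_split$calibration))
    cal_probs <- lapply(by_split$calibration, function(p) {
      predict_probabilities(state, p$image)
    })
    cal_targets <- lapply(by_split$calibration, function(p) p$target)
    cal_map <- fit_dirichlet(cal_probs, cal_targets,
                             max_pixels = config$calibration_max_pixels,
                             seed = derive_seed(seed, 777L))
    saveRDS(list(map = cal_map,
                 nll = attr(cal_map, "fit")), cal_path)
    stage_done(out_dir, "calibrate", h4)
  } else say("[calibrate] cached")
  cal <- readRDS(cal_path)

  # ---- stage 6: evaluation ----------------------------------------------
  h5 <- config_hash("evaluate", h4, config$fp_report_points,
                    config$min_finding_area)
  rep_path <- file.path(out_dir, "report.rds")
  if (!stage_cached(out_dir, "evaluate", h5, rep_path)) {
    say("[evaluate] %d test images", length(by_split$test))
    test_probs <- lapply(by_split$test, function(p) {
      predict_probabilities(state, p$image)
    })
    test_targets <- lapply(by_split$test, function(p) p$target)
    report <- evaluate_study(test_probs, test_targets, cal$map, config)
    report$calibration_nll <- cal$nll
    report$training <- list(best_epoch = state$best_epoch,
                            epochs_run = nrow(state$curves),
                            class_weights = state$class_weights)
    report$config_hash <- h5
    saveRDS(report, rep_path)
    write_study_report(report, file.path(out_dir, "report"))
    stage_done(out_dir, "evaluate", h5)
  } else say("[evaluate] cached")
  report <- readRDS(rep_path)
  class(report) <- "study_report"
  invisible(report)
}

# before/after-calibration metric battery over the test split
evaluate_study <- function(test_probs, test_targets, cal_map, config) {
  post_probs <- lapply(test_probs, function(p) apply_calibration(cal_map, p))
  arms <- list(pre = test_probs, post = post_probs)
  res <- lapply(arms, function(probs) {
    cls <- lapply(probs, class_map)
    seg <- overlap_metrics(cls, test_targets)
    rocs <- lapply(1:3, function(cid) {
      tryCatch(pooled_roc(probs, test_targets, cid),
               error = function(e) NULL)
    })
    roc_tab <- do.call(rbind, lapply(seq_along(rocs), function(i) {
      r <- rocs[[i]]
      if (is.null(r)) {
        return(data.frame(class = i, auc = NA_real_, threshold = NA_real_,
                          tpr = NA_real_, tnr = NA_real_, ppv = NA_real_,
                          npv = NA_real_))
      }
      data.frame(class = r$class_id, auc = r$auc,
                 threshold = r$operating_point$threshold,
                 tpr = r$operating_point$tpr, tnr = r$operating_point$tnr,
                 ppv = r$operating_point$ppv, npv = r$operating_point$npv)
    }))
    ece <- pooled_classwise_ece(probs, test_targets, config$calibration_m)
    fr <- froc(probs, test_targets, config$min_finding_area)
    sens <- froc_sensitivity_at(fr, config$fp_report_points)
    op3 <- roc_tab$threshold[roc_tab$class == 3]
    counts_op <- if (length(op3) == 1 && is.finite(op3)) {
      finding_counts(probs, test_targets, op3, config$min_finding_area)
    } else list(tp = NA, fp = NA, fn = NA)
    # finding identification from the output predictions (argmax class
    # maps), the primary detection readout
    tp <- fp <- fn <- 0L
    for (i in seq_along(cls)) {
      fs <- extract_findings(cls[[i]])
      ts <- extract_findings(as.integer(test_targets[[i]]) |>
                               matrix(nrow(cls[[i]])))
      m <- match_findings(fs, ts)
      tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
    }
    list(segmentation = seg, roc = roc_tab, classwise_ece = ece,
         froc = fr, sensitivity_at_fp = stats::setNames(
           sens, paste0("fp", config$fp_report_points)),
         operating_threshold_class3 = op3,
         finding_counts_at_op = counts_op,
         finding_counts_predicted = list(tp = tp, fp = fp, fn = fn))
  })
  names(res) <- c("pre_calibration", "post_calibration")
  res
}

write_study_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (arm in c("pre_calibration", "post_calibration")) {
    utils::write.csv(report[[arm]]$segmentation,
                     file.path(dir, paste0(arm, "_segmentation.csv")),
                     row.names = FALSE)
    utils::write.csv(report[[arm]]$roc,
                     file.path(dir, paste0(arm, "_roc.csv")),
                     row.names = FALSE)
    utils::write.csv(report[[arm]]$froc,
                     file.path(dir, paste0(arm, "_froc.csv")),
                     row.names = FALSE)
  }
  summ <- lapply(c("pre_calibration", "post_calibration"), function(arm) {
    a <- report[[arm]]
    list(classwise_ece = a$classwise_ece,
         sensitivity_at_fp = as.list(a$sensitivity_at_fp),
         operating_threshold_class3 = a$operating_threshold_class3,
         finding_counts_at_op = a$finding_counts_at_op,
         finding_counts_predicted = a$finding_counts_predicted,
         dice = stats::setNames(as.list(a$segmentation$dice),
                                paste0("class", a$segmentation$class)),
         auc = stats::setNames(as.list(a$roc$auc),
                               paste0("class", a$roc$class)))
  })
  names(summ) <- c("pre_calibration", "post_calibration")
  summ$calibration_nll <- report$calibration_nll
  summ$training <- report$training
  jsonlite::write_json(summ, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Deterministic miniature artifacts for tests
#'
#' @param kind one of `"phantom"`, `"projection"`, `"probmap_calibrated"`,
#'   `"probmap_miscalibrated"`, `"findings_toy"`.
#' @param seed integer seed.
#' @param n instance count for the probability-map kinds.
#' @return kind-specific artifact; `probmap_miscalibrated` carries the true
#'   miscalibration `(W_star, b_star)` and the latent calibrated
#'   probabilities as attributes.
#' @export
make_fixture <- function(kind, seed = 1L, n = 10000L) {
  switch(kind,
    phantom = {
      ph <- generate_outline(30, 50, 70, skin_mm = 2, voxel_pitch_mm = 2,
                             seed = seed)
      ph <- synthesize_parenchyma(
        ph, perlin_config(octaves = 4L, seed = derive_seed(seed, 1L)),
        target_vbd = 0.25)
      les <- make_lesion("I", 2, seed = derive_seed(seed, 2L))
      d <- dim(ph$labels)
      insert_lesion(ph, les, c(round(d[1] / 2), round(d[2] / 3),
                               round(d[3] / 2)))
    },
    projection = {
      ph <- make_fixture("phantom", seed)
      geo <- ngt_geometry(scale = 16)
      project(ph, geo, aec_exposure(ph$cbt_mm, ph$vbd), material_table(),
              noise_seed = derive_seed(seed, 3L))
    },
    probmap_calibrated = with_seed(seed, {
      a <- matrix(stats::rgamma(n * N_CLASSES, shape = 0.8), n)
      q <- a / rowSums(a)
      y <- apply(q, 1L, function(p) sample.int(N_CLASSES, 1L, prob = p)) - 1L
      list(probs = q, labels = y)
    }),
    probmap_miscalibrated = {
      base <- make_fixture("probmap_calibrated", seed, n)
      W_star <- diag(c(1.8, 1.4, 1.1, 2.2))
      b_star <- c(0.3, -0.2, 0.1, 0.6)
      mis <- apply_calibration(calibration_map(W_star, b_star), base$probs)
      structure(list(probs = mis, labels = base$labels),
                W_star = W_star, b_star = b_star,
                latent_probs = base$probs)
    },
    findings_toy = findings_toy_fixture(),
    stop("unknown fixture kind: ", kind, call. = FALSE)
  )
}

# three 40 x 40 images with hand-placed blobs and known matching outcomes
# at threshold 0.5:
#   image 1: prediction == truth            -> TP 2, FP 0, FN 0
#   image 2: one blob bridges both truths,
#            one isolated blob             -> TP 2, FP 1, FN 0
#   image 3: empty prediction              -> TP 0, FP 0, FN 2
findings_toy_fixture <- function() {
  blank <- function() matrix(0L, 40L, 40L)
  disk <- function(m, r0, c0, rad, val = 1) {
    for (r in seq_len(40)) {
      for (c in seq_len(40)) {
        if ((r - r0)^2 + (c - c0)^2 <= rad^2) m[r, c] <- val
      }
    }
    m
  }
  truth1 <- disk(disk(blank(), 10, 10, 3), 30, 30, 3)
  truth2 <- disk(disk(blank(), 10, 10, 3), 10, 30, 3)
  truth3 <- disk(disk(blank(), 20, 10, 3), 20, 30, 3)
  to_prob <- function(lesion_prob_mask) {
    p <- array(0, c(40L, 40L, N_CLASSES))
    p[, , 4L] <- lesion_prob_mask
    p[, , 1L] <- 1 - lesion_prob_mask
    structure(list(probs = p, phantom_id = NA, calibrated = FALSE),
              class = "probability_map")
  }
  pred1 <- truth1 * 0.9
  bridge <- disk(blank(), 10, 10, 3)
  for (c in 10:30) bridge[10, c] <- 1
  bridge <- disk(bridge, 10, 30, 3)
  pred2 <- (bridge | disk(blank(), 30, 10, 2)) * 0.9
  pred3 <- blank()
  truth_mat <- function(m) {
    rm <- m
    rm[rm > 0] <- RISK_LESION
    structure(list(labels = rm, grid = "toy"), class = "risk_map")
  }
  list(
    probs = list(to_prob(pred1), to_prob(pred2), to_prob(pred3 * 0.9)),
    truth = lapply(list(truth1, truth2, truth3), truth_mat),
    expected = list(
      per_image = list(c(tp = 2, fp = 0, fn = 0),
                       c(tp = 2, fp = 1, fn = 0),
                       c(tp = 0, fp = 0, fn = 2)),
      total = c(tp = 4, fp = 1, fn = 2), n_truth = 6
    )
  )
}
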