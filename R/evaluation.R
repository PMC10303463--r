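#' Pooled one-vs-rest ROC curve
#'
#' Pixels are pooled across images; the curve sweeps every distinct
#' predicted probability as a threshold (prediction positive when
#' `prob >= threshold`). AUC is the trapezoidal area; the operating point
#' is the curve point minimizing the Euclidean distance to the ideal
#' corner (FPR, TPR) = (0, 1), at which TPR/TNR/PPV/NPV are reported.
#'
#' @param prob_maps list of `probability_map`s (or one N x k matrix).
#' @param risk_maps matching list of `risk_map`s (or integer containers of
#'   classes 0..k-1).
#' @param class_id class (0-based) evaluated one-vs-rest.
#' @return a `roc_curve`: `thresholds`, `fpr`, `tpr`, `auc`,
#'   `operating_point`.
#' @export
pooled_roc <- function(prob_maps, risk_maps, class_id) {
  pl <- pooled_pixels(prob_maps, risk_maps)
  scores <- pl$probs[, class_id + 1L]
  pos <- pl$labels == class_id
  if (!any(pos) || all(pos)) {
    stop("class ", class_id, " absent (or exhaustive) in pooled labels; ",
         "ROC undefined", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- pos[ord]
  # collapse ties: cumulative counts at each distinct score
  last <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(p)[last]
  fp <- cumsum(!p)[last]
  thr <- s[last]
  P <- sum(pos)
  Nn <- sum(!pos)
  tpr <- c(0, tp / P)
  fpr <- c(0, fp / Nn)
  thr <- c(Inf, thr)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  d2 <- fpr^2 + (1 - tpr)^2
  i0 <- which.min(d2)
  tp0 <- tpr[i0] * P
  fp0 <- fpr[i0] * Nn
  fn0 <- P - tp0
  tn0 <- Nn - fp0
  op <- list(threshold = thr[i0], tpr = tpr[i0], tnr = tn0 / Nn,
             ppv = if (tp0 + fp0 > 0) tp0 / (tp0 + fp0) else NA_real_,
             npv = if (tn0 + fn0 > 0) tn0 / (tn0 + fn0) else NA_real_)
  structure(list(class_id = class_id, thresholds = thr, fpr = fpr,
                 tpr = tpr, auc = auc, operating_point = op,
                 n_pos = P, n_neg = Nn),
            class = "roc_curve")
}

# pool probability maps and labels across images
pooled_pixels <- function(prob_maps, risk_maps) {
  if (inherits(prob_maps, "probability_map") || is.matrix(prob_maps)) {
    prob_maps <- list(prob_maps)
  }
  if (!is.list(risk_maps) || inherits(risk_maps, "risk_map")) {
    risk_maps <- list(risk_maps)
  }
  P <- do.call(rbind, lapply(prob_maps, prob_matrix))
  y <- unlist(lapply(risk_maps, function(r) {
    as.integer(if (inherits(r, "risk_map")) r$labels else r)
  }))
  stopifnot(nrow(P) == length(y))
  list(probs = P, labels = y)
}

#' Hard class map from a probability map
#'
#' Per-pixel argmax; ties break toward the lower class code.
#' @param prob_map a `probability_map`.
#' @export
class_map <- function(prob_map) {
  p <- prob_matrix(prob_map)
  cls <- max.col(p, ties.method = "first") - 1L
  d <- dim(prob_map$probs)
  matrix(cls, d[1], d[2])
}

#' Pooled per-class Dice and Jaccard coefficients
#'
#' Over pooled test pixels: `Dice = 2|P.G| / (|P| + |G|)` and
#' `Jac = |P.G| / |P u G|` for each class; the two are linked by
#' `Jac = Dice / (2 - Dice)`. A class absent from both prediction and
#' truth is recorded as undefined (NA).
#'
#' @param pred_class_maps list of integer class matrices (from
#'   [class_map()]).
#' @param risk_maps matching ground-truth containers.
#' @return data.frame with columns `class`, `dice`, `jaccard`, plus the
#'   pooled intersection/size counts.
#' @export
overlap_metrics <- function(pred_class_maps, risk_maps) {
  if (!is.list(pred_class_maps)) pred_class_maps <- list(pred_class_maps)
  if (!is.list(risk_maps) || inherits(risk_maps, "risk_map")) {
    risk_maps <- list(risk_maps)
  }
  pred <- unlist(lapply(pred_class_maps, as.integer))
  truth <- unlist(lapply(risk_maps, function(r) {
    as.integer(if (inherits(r, "risk_map")) r$labels else r)
  }))
  stopifnot(length(pred) == length(truth))
  out <- lapply(0:(N_CLASSES - 1L), function(c) {
    np <- sum(pred == c)
    ng <- sum(truth == c)
    ni <- sum(pred == c & truth == c)
    if (np + ng == 0) {
      data.frame(class = c, dice = NA_real_, jaccard = NA_real_,
                 n_pred = np, n_truth = ng, n_intersect = ni)
    } else {
      dice <- 2 * ni / (np + ng)
      data.frame(class = c, dice = dice, jaccard = ni / (np + ng - ni),
                 n_pred = np, n_truth = ng, n_intersect = ni)
    }
  })
  do.call(rbind, out)
}

#' Extract suspicious findings as connected components
#'
#' Thresholds the lesion-class (class 3) probability at `threshold` (or
#' takes `label == 3` for a hard label map) and decomposes the binary mask
#' into 8-connected components; components smaller than `min_area` pixels
#' are discarded.
#'
#' @param map a `probability_map`, probability matrix for class 3, or an
#'   integer label matrix.
#' @param threshold probability threshold; ignored for label input.
#' @param min_area smallest retained component, pixels.
#' @return a `finding_set`: `label_matrix` (0 background, 1..K), `sizes`,
#'   `n` (number of findings).
#' @export
extract_findings <- function(map, threshold = NULL, min_area = 1L) {
  if (inherits(map, "probability_map")) {
    if (is.null(threshold)) {
      stop("threshold required for probability input", call. = FALSE)
    }
    mask <- map$probs[, , RISK_LESION + 1L] >= threshold
  } else if (inherits(map, "risk_map")) {
    mask <- map$labels == RISK_LESION
  } else if (is.matrix(map) && is.numeric(map) && !is.null(threshold)) {
    mask <- map >= threshold
  } else {
    mask <- map == RISK_LESION
  }
  lab <- cpp_label8(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_area)
  if (length(keep) < length(sizes)) {
    relab <- integer(length(sizes))
    relab[keep] <- seq_along(keep)
    lab[lab > 0L] <- relab[lab[lab > 0L]]
    sizes <- sizes[keep]
  }
  structure(list(label_matrix = lab, sizes = sizes, n = length(sizes)),
            class = "finding_set")
}

#' Match predicted findings against ground-truth findings
#'
#' Per the lesion-identification rules: a truth cluster is a true positive
#' when at least one predicted lesion pixel overlaps it, else a false
#' negative; a predicted component overlapping no truth cluster counts as
#' one false positive; a predicted component overlapping one or more truth
#' clusters generates no FP. Consequently TP + FN equals the number of
#' truth clusters.
#'
#' @param predicted,truth `finding_set`s on the same grid.
#' @return list with `tp`, `fp`, `fn` counts and per-finding status
#'   vectors.
#' @export
match_findings <- function(predicted, truth) {
  if (!identical(dim(predicted$label_matrix), dim(truth$label_matrix))) {
    stop("finding sets are on different grids", call. = FALSE)
  }
  pl <- predicted$label_matrix
  tl <- truth$label_matrix
  both <- pl > 0L & tl > 0L
  truth_hit <- rep(FALSE, truth$n)
  pred_hit <- rep(FALSE, predicted$n)
  if (any(both)) {
    pairs <- unique(cbind(pl[both], tl[both]))
    pred_hit[pairs[, 1L]] <- TRUE
    truth_hit[pairs[, 2L]] <- TRUE
  }
  tp <- sum(truth_hit)
  fn <- sum(!truth_hit)
  fp <- sum(!pred_hit)
  list(tp = tp, fp = fp, fn = fn,
       truth_status = ifelse(truth_hit, "TP", "FN"),
       predicted_status = ifelse(pred_hit, "TP", "FP"))
}

#' Free-response ROC over a test set
#'
#' Thresholds the lesion-class probability from 1.00 down to 0.00 in 0.01
#' steps; at each threshold findings are extracted per image, matched
#' against the ground truth, and pooled. Sensitivity is the TP fraction of
#' all ground-truth findings and FP/image the mean false-positive finding
#' count.
#'
#' @param prob_maps list of `probability_map`s.
#' @param risk_maps matching list of ground-truth `risk_map`s.
#' @param min_area passed to [extract_findings()].
#' @return a `froc_curve` data.frame: `threshold`, `sensitivity`,
#'   `fp_per_image`, `tp`, `fp`, `fn`.
#' @export
froc <- function(prob_maps, risk_maps, min_area = 1L) {
  if (inherits(prob_maps, "probability_map")) prob_maps <- list(prob_maps)
  if (inherits(risk_maps, "risk_map")) risk_maps <- list(risk_maps)
  stopifnot(length(prob_maps) == length(risk_maps))
  truth_sets <- lapply(risk_maps, extract_findings)
  n_truth <- sum(vapply(truth_sets, function(t) t$n, numeric(1)))
  if (n_truth == 0) {
    stop("no ground-truth findings in the set; FROC undefined",
         call. = FALSE)
  }
  thresholds <- seq(1.00, 0.00, by = -0.01)
  n_img <- length(prob_maps)
  rows <- lapply(thresholds, function(th) {
    tp <- fp <- fn <- 0L
    for (i in seq_len(n_img)) {
      fs <- extract_findings(prob_maps[[i]], th, min_area)
      m <- match_findings(fs, truth_sets[[i]])
      tp <- tp + m$tp
      fp <- fp + m$fp
      fn <- fn + m$fn
    }
    data.frame(threshold = th, sensitivity = tp / n_truth,
               fp_per_image = fp / n_img, tp = tp, fp = fp, fn = fn)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_truth") <- n_truth
  attr(out, "n_images") <- n_img
  class(out) <- c("froc_curve", class(out))
  out
}

#' Sensitivity at given FP/image rates
#'
#' Linear interpolation on the empirical FROC curve (the reporting points,
#' e.g. 2 and 5 FP/image, rarely coincide with the 0.01 threshold grid).
#' @param froc_curve from [froc()].
#' @param fp_rates numeric vector of FP/image points.
#' @export
froc_sensitivity_at <- function(froc_curve, fp_rates = c(2, 5)) {
  # the 0.00 endpoint saturates the mask (one all-covering component:
  # sensitivity 1 at 0 FP by the matching rules) and is excluded from the
  # read-off
  froc_curve <- froc_curve[froc_curve$threshold > 0, , drop = FALSE]
  o <- order(froc_curve$fp_per_image, froc_curve$sensitivity)
  x <- froc_curve$fp_per_image[o]
  # best sensitivity attainable within each FP budget (non-decreasing)
  y <- cummax(froc_curve$sensitivity[o])
  keep <- !duplicated(x, fromLast = TRUE)
  x <- x[keep]
  y <- y[keep]
  vapply(fp_rates, function(r) {
    if (r <= x[1]) return(y[1])
    if (r >= x[length(x)]) return(y[length(y)])
    stats::approx(x, y, xout = r)$y
  }, numeric(1))
}

#' Count findings at a fixed threshold over a set
#' @param prob_maps,risk_maps as in [froc()].
#' @param threshold probability threshold for class 3.
#' @param min_area passed to [extract_findings()].
#' @export
finding_counts <- function(prob_maps, risk_maps, threshold, min_area = 1L) {
  if (inherits(prob_maps, "probability_map")) prob_maps <- list(prob_maps)
  if (inherits(risk_maps, "risk_map")) risk_maps <- list(risk_maps)
  tp <- fp <- fn <- 0L
  for (i in seq_along(prob_maps)) {
    fs <- extract_findings(prob_maps[[i]], threshold, min_area)
    ts <- extract_findings(risk_maps[[i]])
    m <- match_findings(fs, ts)
    tp <- tp + m$tp
    fp <- fp + m$fp
    fn <- fn + m$fn
  }
  list(tp = tp, fp = fp, fn = fn)
}
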