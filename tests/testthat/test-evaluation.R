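test_that("pooled ROC handles perfect separation and matches pair counting", {
  # perfect separation
  y <- c(rep(3L, 5), rep(1L, 5))
  p <- matrix(0, 10, 4)
  p[, 4] <- rep(c(1, 0), each = 5)
  p[, 2] <- 1 - p[, 4]
  r <- pooled_roc(p, y, 3)
  expect_equal(r$auc, 1)
  expect_equal(r$operating_point$tpr, 1)
  expect_equal(r$operating_point$tnr, 1)
  # 6-pixel worked case + random cases against the Mann-Whitney oracle
  for (seed in 1:6) {
    n <- if (seed == 1) 6 else 200
    scores <- with_seed(seed, round(runif(n), 2))
    pos <- with_seed(seed + 100, runif(n) > 0.6)
    if (!any(pos) || all(pos)) pos[1:2] <- c(TRUE, FALSE)
    pm <- matrix(0, n, 4)
    pm[, 4] <- scores
    r <- pooled_roc(pm, ifelse(pos, 3L, 0L), 3)
    expect_equal(r$auc, mann_whitney_auc(scores, pos), tolerance = 1e-12)
  }
  expect_error(pooled_roc(p, rep(1L, 10), 3), "absent")
})

test_that("label-independent probabilities give chance AUC", {
  n <- 1e5
  scores <- with_seed(42L, runif(n))
  labels <- with_seed(43L, sample(c(0L, 3L), n, replace = TRUE))
  pm <- matrix(0, n, 4)
  pm[, 4] <- scores
  r <- pooled_roc(pm, labels, 3)
  expect_lt(abs(r$auc - 0.5), 0.01)
})

test_that("pooled AUC agrees with pROC on a moderate sample", {
  n <- 5000
  scores <- with_seed(7L, runif(n))
  labels <- with_seed(8L, rbinom(n, 1, clamp(scores, 0.05, 0.95)))
  pm <- matrix(0, n, 4)
  pm[, 4] <- scores
  ours <- pooled_roc(pm, ifelse(labels == 1, 3L, 0L), 3)$auc
  ref <- suppressMessages(as.numeric(pROC::auc(labels, scores)))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("Dice and Jaccard follow their definitions and identity", {
  # |P| = 30, |G| = 50, |P & G| = 20 -> Dice 0.5, Jac 1/3
  pred <- rep(0L, 1000)
  truth <- rep(0L, 1000)
  pred[1:30] <- 2L
  truth[11:60] <- 2L
  m <- overlap_metrics(list(matrix(pred, 40)), list(matrix(truth, 40)))
  expect_equal(m$dice[m$class == 2], 0.5)
  expect_equal(m$jaccard[m$class == 2], 1 / 3)
  # identity and zero cases
  ident <- overlap_metrics(list(matrix(truth, 40)), list(matrix(truth, 40)))
  expect_equal(ident$dice[ident$class == 0], 1)
  expect_equal(ident$jaccard[ident$class == 2], 1)
  disj <- overlap_metrics(list(matrix(c(rep(3L, 10), rep(0L, 90)), 10)),
                          list(matrix(c(rep(0L, 90), rep(3L, 10)), 10)))
  expect_equal(disj$dice[disj$class == 3], 0)
  # Jac = Dice / (2 - Dice) wherever defined
  ok <- !is.na(m$dice)
  expect_equal(m$jaccard[ok], m$dice[ok] / (2 - m$dice[ok]),
               tolerance = 1e-12)
})

test_that("finding extraction matches a flood-fill oracle", {
  # two disjoint blobs
  mk <- matrix(0, 20, 20)
  mk[2:4, 2:4] <- 1
  mk[10:12, 15:17] <- 1
  fs <- extract_findings(mk, threshold = 0.5)
  expect_identical(fs$n, 2L)
  # diagonal touching merges under 8-connectivity
  dg <- matrix(0, 5, 5)
  dg[1, 1] <- 1
  dg[2, 2] <- 1
  expect_identical(extract_findings(dg, 0.5)$n, 1L)
  expect_identical(flood_components(dg > 0, eight = FALSE)$n, 2L)
  # random masks, exact agreement with the oracle
  for (seed in 1:5) {
    m <- with_seed(seed, matrix(runif(100 * 100) < 0.25, 100, 100))
    fs <- extract_findings(m * 1, 0.5)
    expect_identical(fs$n, flood_components(m)$n)
  }
  # min_area filtering drops single-pixel specks
  sp <- matrix(0, 10, 10)
  sp[1, 1] <- 1
  sp[5:7, 5:7] <- 1
  expect_identical(extract_findings(sp, 0.5, min_area = 2L)$n, 1L)
})

test_that("finding matching follows the per-truth-cluster rules", {
  fx <- make_fixture("findings_toy")
  for (i in 1:3) {
    pred <- extract_findings(fx$probs[[i]], 0.5)
    truth <- extract_findings(fx$truth[[i]])
    m <- match_findings(pred, truth)
    exp_i <- fx$expected$per_image[[i]]
    expect_equal(c(tp = m$tp, fp = m$fp, fn = m$fn), exp_i,
                 label = paste("image", i))
    expect_identical(m$tp + m$fn, as.integer(truth$n))
  }
  # identity and empty-prediction cases
  t1 <- extract_findings(fx$truth[[1]])
  self <- match_findings(t1, t1)
  expect_identical(c(self$tp, self$fp, self$fn), c(2L, 0L, 0L))
})

test_that("FROC sweeps 101 thresholds with conservation and monotonicity", {
  fx <- make_fixture("findings_toy")
  fr <- froc(fx$probs, fx$truth)
  expect_identical(nrow(fr), 101L)
  expect_true(all(fr$tp + fr$fn == fx$expected$n_truth))
  # monotone in decreasing threshold (thresholds are stored decreasing);
  # the degenerate threshold 0 is excluded for FP/image, where the mask
  # saturates and every component merges with the truth
  expect_true(all(diff(fr$sensitivity) >= -1e-12))
  pos <- fr$threshold > 0
  expect_true(all(diff(fr$fp_per_image[pos]) >= -1e-12))
  # hand-checked values at threshold 0.5: TP 4 of 6, FP 1 over 3 images
  row <- fr[abs(fr$threshold - 0.5) < 1e-9, ]
  expect_equal(row$sensitivity, 4 / 6, tolerance = 1e-12)
  expect_equal(row$fp_per_image, 1 / 3, tolerance = 1e-12)
  # brute-force oracle over the full sweep
  for (th in c(0.3, 0.7, 0.95)) {
    tp <- fp <- 0
    for (i in 1:3) {
      pm <- fx$probs[[i]]$probs[, , 4]
      cc <- flood_components(pm >= th)
      tm <- fx$truth[[i]]$labels == 3L
      tt <- flood_components(tm)
      for (k in seq_len(tt$n)) {
        if (any(pm[tt$labels == k] >= th)) tp <- tp + 1
      }
      for (k in seq_len(cc$n)) {
        if (!any(tm[cc$labels == k])) fp <- fp + 1
      }
    }
    row <- fr[abs(fr$threshold - th) < 1e-9, ]
    expect_equal(row$tp, tp)
    expect_equal(row$fp, fp)
  }
  # the sensitivity read-off is non-decreasing in the FP budget and reads
  # off the non-degenerate (threshold > 0) part of the curve
  s_at <- froc_sensitivity_at(fr, c(0.1, 0.5, 2, 5))
  expect_true(all(diff(s_at) >= -1e-12))
  sub <- fr[fr$threshold > 0, ]
  expect_equal(unname(s_at[3]), max(sub$sensitivity[sub$fp_per_image <= 2]),
               tolerance = 1e-12)
})

test_that("perfect probability maps reach full sensitivity at zero FP", {
  fx <- make_fixture("findings_toy")
  perfect <- lapply(fx$truth, function(t) {
    p <- array(0, c(dim(t$labels), 4))
    p[, , 4] <- (t$labels == 3L) * 1
    p[, , 1] <- 1 - p[, , 4]
    structure(list(probs = p, calibrated = FALSE), class = "probability_map")
  })
  fr <- froc(perfect, fx$truth)
  mid <- fr$threshold > 0 & fr$threshold < 1
  expect_true(all(fr$sensitivity[mid] == 1))
  expect_true(all(fr$fp_per_image[mid] == 0))
  expect_equal(froc_sensitivity_at(fr, c(2, 5)), c(1, 1))
})

test_that("FROC is undefined without ground-truth findings", {
  fx <- make_fixture("findings_toy")
  empty <- lapply(fx$truth, function(t) {
    t$labels[, ] <- 0L
    t
  })
  expect_error(froc(fx$probs, empty), "undefined")
})
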