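test_that("weighted cross-entropy matches closed forms and hand arithmetic", {
  # perfect one-hot predictions give (numerically) zero loss
  tgt <- c(0L, 1L, 2L, 3L)
  p <- diag(4)[tgt + 1L, ]
  expect_lte(weighted_cross_entropy(p, tgt), -log(1 - 1e-12) + 1e-15)
  # uniform predictions with unit weights give ln 4
  pu <- matrix(0.25, 8, 4)
  expect_equal(weighted_cross_entropy(pu, rep(0:3, 2)), log(4),
               tolerance = 1e-12)
  # 3-pixel toy case with weights (1, 1, 1, 10)
  probs <- rbind(c(0.7, 0.1, 0.1, 0.1),
                 c(0.2, 0.5, 0.2, 0.1),
                 c(0.05, 0.05, 0.1, 0.8))
  tgt3 <- c(0L, 1L, 3L)
  w <- c(1, 1, 1, 10)
  hand <- -(1 * log(0.7) + 1 * log(0.5) + 10 * log(0.8)) / 3
  expect_equal(weighted_cross_entropy(probs, tgt3, w), hand,
               tolerance = 1e-12)
  expect_error(weighted_cross_entropy(probs, c(0L, 1L)), "mismatch")
})

test_that("compiled im2col/col2im agree with the pure-R reference", {
  H <- 7L; W <- 5L; C <- 3L
  x <- with_seed(2L, matrix(rnorm(H * W * C), H * W, C))
  a <- steersim:::im2col3(x, H, W)
  b <- steersim:::im2col3_r(x, H, W)
  expect_equal(a, b, tolerance = 1e-15)
  d <- with_seed(3L, matrix(rnorm(H * W * 9 * C), H * W, 9 * C))
  expect_equal(steersim:::col2im3(d, H, W), steersim:::col2im3_r(d, H, W),
               tolerance = 1e-15)
})

test_that("backpropagation matches numeric gradients", {
  H <- 8L; W <- 8L
  cfg <- segmenter_config(depth = 2L, base_channels = 2L, seed = 9L)
  params <- steersim:::with_seed(3L, steersim:::init_params(cfg))
  x <- with_seed(4L, matrix(rnorm(H * W), H * W, 1L))
  tgt <- with_seed(5L, sample(0:3, H * W, replace = TRUE))
  cw <- c(1, 2, 1, 3)
  loss_of <- function(p) {
    fw <- steersim:::segnet_forward(p, x, H, W)
    weighted_cross_entropy(fw$probs, tgt, cw)
  }
  fwd <- steersim:::segnet_forward(params, x, H, W, keep_cache = TRUE)
  gr <- steersim:::segnet_backward(params, fwd, tgt, cw)
  eps <- 1e-6
  paths <- list(
    list(get = function(p) p$enc[[1]]$c1$W,
         set = function(p, v) { p$enc[[1]]$c1$W <- v; p },
         g = gr$enc[[1]]$c1$W),
    list(get = function(p) p$enc[[2]]$c2$W,
         set = function(p, v) { p$enc[[2]]$c2$W <- v; p },
         g = gr$enc[[2]]$c2$W),
    list(get = function(p) p$dec[[1]]$c1$W,
         set = function(p, v) { p$dec[[1]]$c1$W <- v; p },
         g = gr$dec[[1]]$c1$W),
    list(get = function(p) p$final$W,
         set = function(p, v) { p$final$W <- v; p },
         g = gr$final$W),
    list(get = function(p) p$enc[[1]]$c2$b,
         set = function(p, v) { p$enc[[1]]$c2$b <- v; p },
         g = gr$enc[[1]]$c2$b)
  )
  for (pp in paths) {
    v <- pp$get(params)
    for (i in with_seed(7L, sample(length(v), min(3, length(v))))) {
      vp <- v; vp[i] <- vp[i] + eps
      vm <- v; vm[i] <- vm[i] - eps
      num <- (loss_of(pp$set(params, vp)) - loss_of(pp$set(params, vm))) /
        (2 * eps)
      expect_lt(abs(num - pp$g[i]), 1e-6 + 1e-4 * abs(num))
    }
  }
})

test_that("predicted probability maps are normalized and deterministic", {
  pairs <- toy_pairs(1:4, H = 16L, W = 16L)
  cfg <- segmenter_config(depth = 2L, base_channels = 4L, batch_size = 2L,
                          max_epochs = 2L, patience = 2L, seed = 3L)
  st <- train_segmenter(pairs[1:3], pairs[4], cfg)
  pm <- predict_probabilities(st, pairs[[1]]$image)
  expect_lt(max(abs(apply(pm$probs, c(1, 2), sum) - 1)), 1e-5)
  expect_true(all(pm$probs > 0 & pm$probs < 1))
  expect_false(pm$calibrated)
  pm2 <- predict_probabilities(st, pairs[[1]]$image)
  expect_identical(pm$probs, pm2$probs)
  expect_error(predict_probabilities(st, matrix(0, 8, 8)), "incompatible")
})

test_that("training reduces the loss and retraining is deterministic", {
  pairs <- toy_pairs(1:6, H = 16L, W = 16L)
  cfg <- segmenter_config(depth = 2L, base_channels = 4L, batch_size = 2L,
                          learning_rate = 3e-3, max_epochs = 8L,
                          patience = 8L, seed = 11L)
  st <- train_segmenter(pairs[1:4], pairs[5:6], cfg)
  expect_lt(utils::tail(st$curves$train_wcel, 1), st$curves$train_wcel[1])
  st2 <- train_segmenter(pairs[1:4], pairs[5:6], cfg)
  expect_identical(st$curves, st2$curves)
})

test_that("early stopping halts within patience of the best epoch", {
  pairs <- toy_pairs(1:4, H = 16L, W = 16L)
  cfg <- segmenter_config(depth = 2L, base_channels = 2L, batch_size = 4L,
                          learning_rate = 0.2,  # deliberately unstable
                          max_epochs = 60L, patience = 3L, seed = 2L)
  st <- train_segmenter(pairs[1:3], pairs[4], cfg)
  ran <- nrow(st$curves)
  if (ran < cfg$max_epochs) {
    expect_lte(ran, st$best_epoch + cfg$patience)
  }
  # class weights default to inverse pixel frequency, normalized to mean 1
  expect_equal(mean(st$class_weights), 1, tolerance = 1e-12)
  expect_gt(st$class_weights[4], st$class_weights[2])  # lesion pixels rare
})

test_that("a tiny segmenter learns a separable toy cohort", {
  # lesions rendered dark on a piecewise-constant background; held-out
  # pixel accuracy must exceed 0.9 within a few CPU minutes
  pairs <- toy_pairs(1:10)
  cfg <- segmenter_config(depth = 3L, base_channels = 8L, batch_size = 4L,
                          learning_rate = 3e-3, max_epochs = 15L,
                          patience = 10L, seed = 5L)
  st <- train_segmenter(pairs[1:8], pairs[9:10], cfg)
  held <- toy_pairs(11:12)
  acc <- vapply(held, function(p) {
    mean(class_map(predict_probabilities(st, p$image)) == p$target)
  }, numeric(1))
  expect_gt(min(acc), 0.9)
})

test_that("the pixel-logistic baseline separates the toy cohort too", {
  pairs <- toy_pairs(1:6)
  st <- fit_pixel_baseline(pairs[1:4], epochs = 120L, seed = 2L)
  held <- toy_pairs(7)[[1]]
  pm <- predict_probabilities_baseline(st, held$image)
  expect_lt(max(abs(apply(pm$probs, c(1, 2), sum) - 1)), 1e-6)
  expect_gt(mean(class_map(pm) == held$target), 0.8)
})
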