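#' Segmenter configuration
#'
#' A U-Net-style 2D encoder-decoder with skip connections: `depth` levels,
#' `base_channels` feature maps at the top level (doubled per level), two
#' 3x3 convolution + ReLU blocks per level, 2x2 max pooling, nearest-
#' neighbor upsampling, and a 1x1 softmax head over the four risk classes.
#' Trained with Adam on the weighted cross-entropy loss with early
#' stopping on validation loss.
#'
#' @param depth number of resolution levels (input dims must be divisible
#'   by `2^(depth-1)`).
#' @param base_channels feature maps at the finest level.
#' @param batch_size images per Adam step.
#' @param learning_rate Adam step size.
#' @param max_epochs training epoch cap.
#' @param patience epochs without validation improvement before stopping.
#' @param class_weights 4-vector of loss weights, or `NULL` for inverse
#'   pixel frequency on the training split (normalized to mean 1).
#' @param seed RNG seed for initialization and shuffling.
#' @export
segmenter_config <- function(depth = 3L, base_channels = 8L, batch_size = 6L,
                             learning_rate = 3e-4, max_epochs = 250L,
                             patience = 20L, class_weights = NULL,
                             seed = 1L) {
  stopifnot(depth >= 1, base_channels >= 1, batch_size >= 1,
            learning_rate > 0, max_epochs >= 1, patience >= 1)
  if (!is.null(class_weights)) stopifnot(length(class_weights) == 4,
                                         all(class_weights > 0))
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 class_weights = class_weights,
                 seed = as.integer(seed)),
            class = "segmenter_config")
}

N_CLASSES <- 4L

#' Weighted cross-entropy loss
#'
#' `-(1/Npix) * sum_i weight[target_i] * log p_i[target_i]`, with
#' probabilities clamped at 1e-12 so one-hot predictions stay finite.
#'
#' @param probs `H x W x 4` array (or `N x 4` matrix) of class
#'   probabilities.
#' @param target integer matrix/vector of true classes 0..3, matching
#'   `probs` spatially.
#' @param class_weights positive 4-vector.
#' @export
weighted_cross_entropy <- function(probs, target,
                                   class_weights = rep(1, N_CLASSES)) {
  n <- length(target)
  if (length(probs) != n * N_CLASSES) {
    stop("probs and target have mismatched shapes", call. = FALSE)
  }
  p <- matrix(probs, nrow = n)
  t1 <- as.integer(target) + 1L
  pt <- clamp(p[cbind(seq_len(n), t1)], 1e-12, 1)
  mean(class_weights[t1] * -log(pt))
}

# ---- network parameters -------------------------------------------------

init_params <- function(cfg, in_channels = 1L) {
  D <- cfg$depth
  FC <- cfg$base_channels * 2^(seq_len(D) - 1L)
  he <- function(fan_in, n_out) {
    matrix(stats::rnorm(fan_in * n_out, sd = sqrt(2 / fan_in)), fan_in, n_out)
  }
  conv <- function(cin, cout) list(W = he(9L * cin, cout), b = numeric(cout))
  enc <- vector("list", D)
  cin <- in_channels
  for (i in seq_len(D)) {
    enc[[i]] <- list(c1 = conv(cin, FC[i]), c2 = conv(FC[i], FC[i]))
    cin <- FC[i]
  }
  dec <- if (D > 1) {
    lapply(seq_len(D - 1L), function(i) {
      list(c1 = conv(FC[i + 1L] + FC[i], FC[i]), c2 = conv(FC[i], FC[i]))
    })
  } else list()
  final <- list(W = matrix(stats::rnorm(FC[1] * N_CLASSES,
                                        sd = sqrt(2 / FC[1])),
                           FC[1], N_CLASSES),
                b = numeric(N_CLASSES))
  list(enc = enc, dec = dec, final = final, channels = FC)
}

# forward pass over a stacked batch of B images; returns per-pixel
# probabilities and (optionally) caches
segnet_forward <- function(params, x_mat, H, W, keep_cache = FALSE, B = 1L) {
  D <- length(params$enc)
  caches <- list(enc = vector("list", D), pool = vector("list", D),
                 dec = vector("list", max(D - 1L, 0L)))
  skips <- vector("list", D)
  dims <- matrix(0L, D, 2L)
  cur <- x_mat
  h <- H; w <- W
  for (i in seq_len(D)) {
    dims[i, ] <- c(h, w)
    f1 <- conv_relu_fwd(cur, params$enc[[i]]$c1$W, params$enc[[i]]$c1$b,
                        h, w, B)
    f2 <- conv_relu_fwd(f1$a, params$enc[[i]]$c2$W, params$enc[[i]]$c2$b,
                        h, w, B)
    skips[[i]] <- f2$a
    if (keep_cache) caches$enc[[i]] <- list(f1 = f1, f2 = f2)
    if (i < D) {
      pl <- maxpool2_fwd(f2$a, h, w, B)
      if (keep_cache) caches$pool[[i]] <- pl
      cur <- pl$a
      h <- h %/% 2L
      w <- w %/% 2L
    } else {
      cur <- f2$a
    }
  }
  for (i in rev(seq_len(D - 1L))) {
    up <- upsample2_fwd(cur, h, w, B)
    h <- h * 2L
    w <- w * 2L
    cat_a <- cbind(up, skips[[i]])
    g1 <- conv_relu_fwd(cat_a, params$dec[[i]]$c1$W, params$dec[[i]]$c1$b,
                        h, w, B)
    g2 <- conv_relu_fwd(g1$a, params$dec[[i]]$c2$W, params$dec[[i]]$c2$b,
                        h, w, B)
    if (keep_cache) {
      caches$dec[[i]] <- list(g1 = g1, g2 = g2, up_ch = ncol(up))
    }
    cur <- g2$a
  }
  logits <- cur %*% params$final$W
  logits <- logits + rep(params$final$b, each = nrow(logits))
  probs <- softmax_rows(logits)
  if (!keep_cache) return(list(probs = probs))
  list(probs = probs, caches = caches, skips = skips, dims = dims,
       head_in = cur, B = B)
}

# backward pass for the WCEL objective; target is 0..3 per pixel
segnet_backward <- function(params, fwd, target, class_weights) {
  D <- length(params$enc)
  B <- fwd$B %||% 1L
  n <- length(target)
  t1 <- as.integer(target) + 1L
  wt <- class_weights[t1]
  dlog <- fwd$probs * wt
  dlog[cbind(seq_len(n), t1)] <- dlog[cbind(seq_len(n), t1)] - wt
  dlog <- dlog / n

  g <- list(enc = vector("list", D), dec = vector("list", max(D - 1L, 0L)),
            final = NULL)
  g$final <- list(W = crossprod(fwd$head_in, dlog), b = colSums(dlog))
  da <- dlog %*% t(params$final$W)

  dims <- fwd$dims
  for (i in seq_len(D - 1L)) {
    h <- dims[i, 1L]; w <- dims[i, 2L]
    cc <- fwd$caches$dec[[i]]
    b2 <- conv_relu_bwd(da, cc$g2, params$dec[[i]]$c2$W, h, w, B)
    b1 <- conv_relu_bwd(b2$dx, cc$g1, params$dec[[i]]$c1$W, h, w, B)
    g$dec[[i]] <- list(c1 = list(W = b1$dW, b = b1$db),
                       c2 = list(W = b2$dW, b = b2$db))
    dup <- b1$dx[, seq_len(cc$up_ch), drop = FALSE]
    dskip <- b1$dx[, -seq_len(cc$up_ch), drop = FALSE]
    # stash the skip gradient; the encoder pass below adds it in
    attr(g$dec[[i]], "dskip") <- dskip
    da <- upsample2_bwd(dup, h %/% 2L, w %/% 2L, B)
  }
  # da now flows into the bottom encoder level; walk encoders bottom-up
  for (i in rev(seq_len(D))) {
    h <- dims[i, 1L]; w <- dims[i, 2L]
    if (i < D) {
      da <- maxpool2_bwd(da, fwd$caches$pool[[i]])
      da <- da + attr(g$dec[[i]], "dskip")
    }
    cc <- fwd$caches$enc[[i]]
    b2 <- conv_relu_bwd(da, cc$f2, params$enc[[i]]$c2$W, h, w, B)
    b1 <- conv_relu_bwd(b2$dx, cc$f1, params$enc[[i]]$c1$W, h, w, B)
    g$enc[[i]] <- list(c1 = list(W = b1$dW, b = b1$db),
                       c2 = list(W = b2$dW, b = b2$db))
    da <- b1$dx
  }
  g
}

# ---- Adam ---------------------------------------------------------------

# walk two parallel nested param structures applying f(leaf_a, leaf_b)
param_walk <- function(a, b, f) {
  if (is.list(a) && !is.null(a$W)) return(f(a, b))
  out <- a
  for (nm in seq_along(a)) {
    if (is.list(a[[nm]])) out[[nm]] <- param_walk(a[[nm]], b[[nm]], f)
  }
  out
}

adam_init <- function(params) {
  zero <- function(p, q) list(W = p$W * 0, b = p$b * 0)
  list(m = param_walk(params, params, zero),
       v = param_walk(params, params, zero), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  state$m <- param_walk(state$m, grads, function(m, gr) {
    list(W = beta1 * m$W + (1 - beta1) * gr$W,
         b = beta1 * m$b + (1 - beta1) * gr$b)
  })
  state$v <- param_walk(state$v, grads, function(v, gr) {
    list(W = beta2 * v$W + (1 - beta2) * gr$W^2,
         b = beta2 * v$b + (1 - beta2) * gr$b^2)
  })
  c1 <- 1 - beta1^t
  c2 <- 1 - beta2^t
  params2 <- params
  upd <- function(p, mv) {
    list(W = p$W - lr * (mv$m$W / c1) / (sqrt(mv$v$W / c2) + eps),
         b = p$b - lr * (mv$m$b / c1) / (sqrt(mv$v$b / c2) + eps))
  }
  params2$enc <- lapply(seq_along(params$enc), function(i) {
    list(c1 = upd(params$enc[[i]]$c1,
                  list(m = state$m$enc[[i]]$c1, v = state$v$enc[[i]]$c1)),
         c2 = upd(params$enc[[i]]$c2,
                  list(m = state$m$enc[[i]]$c2, v = state$v$enc[[i]]$c2)))
  })
  params2$dec <- lapply(seq_along(params$dec), function(i) {
    list(c1 = upd(params$dec[[i]]$c1,
                  list(m = state$m$dec[[i]]$c1, v = state$v$dec[[i]]$c1)),
         c2 = upd(params$dec[[i]]$c2,
                  list(m = state$m$dec[[i]]$c2, v = state$v$dec[[i]]$c2)))
  })
  params2$final <- upd(params$final,
                       list(m = state$m$final, v = state$v$final))
  list(params = params2, state = state)
}

# ---- training -----------------------------------------------------------

# per-image input normalization: log counts, zero mean, unit variance
standardize_image <- function(img) {
  x <- log1p(pmax(img, 0))
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) s <- 1
  (x - mean(x)) / s
}

inverse_frequency_weights <- function(targets) {
  cnt <- pmax(tabulate(unlist(targets) + 1L, nbins = N_CLASSES), 1)
  w <- sum(cnt) / cnt
  w / mean(w)
}

#' Train the encoder-decoder segmenter
#'
#' Minimizes the weighted cross-entropy loss with Adam; images are
#' log-transformed and standardized per image. Early stopping monitors the
#' validation loss with the configured patience and the best-validation
#' parameters are returned. Fully deterministic given `config$seed`.
#'
#' @param train_pairs,val_pairs lists of `training_pair` objects on a
#'   common grid.
#' @param config a [segmenter_config()].
#' @return a `segmenter_state` with the weights, loss curves, the epoch of
#'   the best validation loss, and the class weights used.
#' @export
train_segmenter <- function(train_pairs, val_pairs, config) {
  stopifnot(length(train_pairs) >= 1, length(val_pairs) >= 1)
  H <- nrow(train_pairs[[1]]$image)
  W <- ncol(train_pairs[[1]]$image)
  if (H %% 2^(config$depth - 1L) != 0 || W %% 2^(config$depth - 1L) != 0) {
    stop("image dims must be divisible by 2^(depth-1)", call. = FALSE)
  }
  xs <- lapply(train_pairs, function(p) {
    m <- standardize_image(p$image)
    dim(m) <- c(H * W, 1L)
    m
  })
  ts <- lapply(train_pairs, function(p) as.integer(p$target))
  xv <- lapply(val_pairs, function(p) {
    m <- standardize_image(p$image)
    dim(m) <- c(H * W, 1L)
    m
  })
  tv <- lapply(val_pairs, function(p) as.integer(p$target))
  cw <- config$class_weights %||% inverse_frequency_weights(ts)

  params <- with_seed(config$seed, init_params(config))
  opt <- adam_init(params)
  best <- list(loss = Inf, params = params, epoch = 0L)
  curves <- data.frame(epoch = integer(), train_wcel = numeric(),
                       val_wcel = numeric())
  stale <- 0L
  n <- length(xs)
  for (epoch in seq_len(config$max_epochs)) {
    ord <- with_seed(derive_seed(config$seed, epoch), sample.int(n))
    ep_loss <- 0
    bstarts <- seq(1L, n, by = config$batch_size)
    for (bs in bstarts) {
      ids <- ord[bs:min(bs + config$batch_size - 1L, n)]
      acc <- NULL
      bloss <- 0
      # per-image accumulation: at these activation sizes one image's
      # working set stays cache-resident, which beats stacking the batch
      # into larger (memory-bound) GEMMs
      for (id in ids) {
        fwd <- segnet_forward(params, xs[[id]], H, W, keep_cache = TRUE)
        bloss <- bloss + weighted_cross_entropy(fwd$probs, ts[[id]], cw)
        gr <- segnet_backward(params, fwd, ts[[id]], cw)
        acc <- if (is.null(acc)) gr else param_walk(acc, gr, function(a, b) {
          list(W = a$W + b$W, b = a$b + b$b)
        })
      }
      k <- length(ids)
      acc <- param_walk(acc, acc, function(a, b) list(W = a$W / k,
                                                      b = a$b / k))
      st <- adam_step(params, acc, opt, config$learning_rate)
      params <- st$params
      opt <- st$state
      ep_loss <- ep_loss + bloss
    }
    val_loss <- mean(vapply(seq_along(xv), function(i) {
      fw <- segnet_forward(params, xv[[i]], H, W)
      weighted_cross_entropy(fw$probs, tv[[i]], cw)
    }, numeric(1)))
    curves <- rbind(curves, data.frame(epoch = epoch,
                                       train_wcel = ep_loss / n,
                                       val_wcel = val_loss))
    if (!is.finite(val_loss)) {
      stop("non-finite validation loss at epoch ", epoch, call. = FALSE)
    }
    if (val_loss < best$loss - 1e-9) {
      best <- list(loss = val_loss, params = params, epoch = epoch)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= config$patience) break
    }
  }
  structure(list(params = best$params, config = config,
                 class_weights = cw, curves = curves,
                 best_epoch = best$epoch, H = H, W = W),
            class = "segmenter_state")
}

#' Predict per-pixel class probabilities
#'
#' @param state a `segmenter_state` from [train_segmenter()].
#' @param image a projection image matrix on the training grid.
#' @return a `probability_map`: `probs` (H x W x 4, rows sum to 1),
#'   `calibrated = FALSE`.
#' @export
predict_probabilities <- function(state, image) {
  H <- nrow(image)
  W <- ncol(image)
  if (H != state$H || W != state$W) {
    stop("image dims incompatible with the trained network", call. = FALSE)
  }
  x <- standardize_image(image)
  dim(x) <- c(H * W, 1L)
  fwd <- segnet_forward(state$params, x, H, W)
  probs <- fwd$probs
  dim(probs) <- c(H, W, N_CLASSES)
  structure(list(probs = probs, phantom_id = NA_character_,
                 calibrated = FALSE),
            class = "probability_map")
}

#' Per-pixel multinomial-logistic baseline segmenter
#'
#' A deterministic, fast fallback for exercising the downstream
#' calibration/evaluation stages: softmax regression on simple per-pixel
#' features (standardized intensity, 3x3 and 9x9 local means, normalized
#' row position), trained by Adam on the weighted cross-entropy.
#'
#' @param train_pairs list of `training_pair` objects.
#' @param epochs gradient steps over the full pixel set.
#' @param learning_rate Adam step size.
#' @param seed RNG seed.
#' @return a `pixel_baseline_state` usable with
#'   [predict_probabilities_baseline()].
#' @export
fit_pixel_baseline <- function(train_pairs, epochs = 150L,
                               learning_rate = 0.05, seed = 1L) {
  feats <- lapply(train_pairs, function(p) baseline_features(p$image))
  X <- do.call(rbind, feats)
  y <- unlist(lapply(train_pairs, function(p) as.integer(p$target)))
  cw <- inverse_frequency_weights(list(y))
  k <- N_CLASSES
  Wm <- with_seed(seed, matrix(stats::rnorm(ncol(X) * k, sd = 0.01),
                               ncol(X), k))
  b <- numeric(k)
  m <- list(W = Wm * 0, b = b * 0)
  v <- list(W = Wm * 0, b = b * 0)
  n <- nrow(X)
  t1 <- y + 1L
  wt <- cw[t1]
  for (it in seq_len(epochs)) {
    p <- softmax_rows(X %*% Wm + rep(b, each = n))
    dz <- p * wt
    dz[cbind(seq_len(n), t1)] <- dz[cbind(seq_len(n), t1)] - wt
    dz <- dz / n
    gW <- crossprod(X, dz)
    gb <- colSums(dz)
    m$W <- 0.9 * m$W + 0.1 * gW; v$W <- 0.999 * v$W + 0.001 * gW^2
    m$b <- 0.9 * m$b + 0.1 * gb; v$b <- 0.999 * v$b + 0.001 * gb^2
    c1 <- 1 - 0.9^it; c2 <- 1 - 0.999^it
    Wm <- Wm - learning_rate * (m$W / c1) / (sqrt(v$W / c2) + 1e-8)
    b <- b - learning_rate * (m$b / c1) / (sqrt(v$b / c2) + 1e-8)
  }
  structure(list(W = Wm, b = b, class_weights = cw),
            class = "pixel_baseline_state")
}

#' @rdname fit_pixel_baseline
#' @param state a `pixel_baseline_state`.
#' @param image image matrix.
#' @export
predict_probabilities_baseline <- function(state, image) {
  X <- baseline_features(image)
  p <- softmax_rows(X %*% state$W + rep(state$b, each = nrow(X)))
  dim(p) <- c(nrow(image), ncol(image), N_CLASSES)
  structure(list(probs = p, phantom_id = NA_character_, calibrated = FALSE),
            class = "probability_map")
}

baseline_features <- function(image) {
  x <- standardize_image(image)
  box <- function(m, r) {
    # separable box mean with edge padding
    k <- 2L * r + 1L
    cs <- function(v) {
      n <- length(v)
      vp <- c(rep(v[1], r), v, rep(v[n], r))
      (cumsum(vp)[k:(n + k - 1L)] -
          c(0, cumsum(vp))[1:n]) / k
    }
    m1 <- apply(m, 2L, cs)
    t(apply(t(m1), 2L, cs))
  }
  rowpos <- matrix(seq_len(nrow(x)) / nrow(x), nrow(x), ncol(x))
  cbind(1, as.vector(x), as.vector(box(x, 1L)), as.vector(box(x, 4L)),
        as.vector(rowpos))
}
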