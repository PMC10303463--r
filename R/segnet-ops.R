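# Low-level differentiable ops for the encoder-decoder segmenter.
# Activations travel as (H*W*B) x C matrices: column-major spatial order
# (row index fastest) with the B batch images in contiguous row blocks,
# interchangeable with (H, W, B, C) arrays via dim<-.

# 3x3 im2col with zero padding; column blocks are offset-major:
# columns (o-1)*C + (1:C) hold offset o of all channels
im2col3 <- function(x, H, W, B = 1L) {
  if (!is.matrix(x)) dim(x) <- c(H * W * B, length(x) / (H * W * B))
  cpp_im2col3(x, H, W, B)
}

# pure-R reference for a single image (parity-tested against the
# compiled path)
im2col3_r <- function(x, H, W) {
  C <- length(x) / (H * W)
  dim(x) <- c(H, W, C)
  xp <- array(0, c(H + 2L, W + 2L, C))
  xp[2:(H + 1L), 2:(W + 1L), ] <- x
  cols <- matrix(0, H * W, 9L * C)
  o <- 0L
  for (dx in 0:2) {
    for (dy in 0:2) {
      o <- o + 1L
      cols[, ((o - 1L) * C + 1L):(o * C)] <-
        xp[(1:H) + dy, (1:W) + dx, , drop = FALSE]
    }
  }
  cols
}

# adjoint of im2col3: scatter-add column blocks back to the padded grid
col2im3 <- function(dcols, H, W, B = 1L) {
  cpp_col2im3(dcols, H, W, B)
}

col2im3_r <- function(dcols, H, W) {
  C <- ncol(dcols) / 9L
  dxp <- array(0, c(H + 2L, W + 2L, C))
  o <- 0L
  for (dx in 0:2) {
    for (dy in 0:2) {
      o <- o + 1L
      blk <- dcols[, ((o - 1L) * C + 1L):(o * C), drop = FALSE]
      dim(blk) <- c(H, W, C)
      dxp[(1:H) + dy, (1:W) + dx, ] <- dxp[(1:H) + dy, (1:W) + dx, ,
                                           drop = FALSE] + blk
    }
  }
  out <- dxp[2:(H + 1L), 2:(W + 1L), , drop = FALSE]
  dim(out) <- c(H * W, C)
  out
}

# 3x3 conv + ReLU; returns activation and the backprop cache
conv_relu_fwd <- function(x, W, b, H, Wd, B = 1L) {
  cols <- im2col3(x, H, Wd, B)
  z <- cols %*% W
  z <- z + rep(b, each = nrow(z))
  mask <- z > 0
  storage.mode(mask) <- "double"
  list(a = z * mask, cols = cols, mask = mask)
}

conv_relu_bwd <- function(da, cache, W, H, Wd, B = 1L) {
  dz <- da * cache$mask
  list(dW = crossprod(cache$cols, dz),
       db = colSums(dz),
       dx = col2im3(dz %*% t(W), H, Wd, B))
}

# 2x2 max pooling; gradient routes to the first position attaining the max
maxpool2_fwd <- function(x, H, W, B = 1L) {
  C <- length(x) / (H * W * B)
  dim(x) <- c(H, W, B * C)  # batch folded into the trailing dim
  H2 <- H %/% 2L
  W2 <- W %/% 2L
  s <- list(x[seq(1L, H, 2L), seq(1L, W, 2L), , drop = FALSE],
            x[seq(2L, H, 2L), seq(1L, W, 2L), , drop = FALSE],
            x[seq(1L, H, 2L), seq(2L, W, 2L), , drop = FALSE],
            x[seq(2L, H, 2L), seq(2L, W, 2L), , drop = FALSE])
  p <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
  taken <- array(FALSE, dim(p))
  masks <- vector("list", 4L)
  for (k in 1:4) {
    m <- (s[[k]] == p) & !taken
    taken <- taken | m
    masks[[k]] <- m
  }
  out <- p
  dim(out) <- c(H2 * W2 * B, C)
  list(a = out, masks = masks, H = H, W = W, B = B, C = C)
}

maxpool2_bwd <- function(dp, cache) {
  H <- cache$H; W <- cache$W; B <- cache$B; C <- cache$C
  dim(dp) <- c(H %/% 2L, W %/% 2L, B * C)
  dx <- array(0, c(H, W, B * C))
  ri <- list(seq(1L, H, 2L), seq(2L, H, 2L), seq(1L, H, 2L), seq(2L, H, 2L))
  ci <- list(seq(1L, W, 2L), seq(1L, W, 2L), seq(2L, W, 2L), seq(2L, W, 2L))
  for (k in 1:4) {
    dx[ri[[k]], ci[[k]], ] <- dp * cache$masks[[k]]
  }
  dim(dx) <- c(H * W * B, C)
  dx
}

# nearest-neighbor 2x upsampling
upsample2_fwd <- function(x, H, W, B = 1L) {
  C <- length(x) / (H * W * B)
  dim(x) <- c(H, W, B * C)
  u <- x[rep(seq_len(H), each = 2L), rep(seq_len(W), each = 2L), ,
         drop = FALSE]
  dim(u) <- c(4L * H * W * B, C)
  u
}

upsample2_bwd <- function(du, H, W, B = 1L) {
  # H, W are the *input* (coarse) dims
  C <- length(du) / (4L * H * W * B)
  dim(du) <- c(2L * H, 2L * W, B * C)
  dx <- du[seq(1L, 2L * H, 2L), seq(1L, 2L * W, 2L), , drop = FALSE] +
    du[seq(2L, 2L * H, 2L), seq(1L, 2L * W, 2L), , drop = FALSE] +
    du[seq(1L, 2L * H, 2L), seq(2L, 2L * W, 2L), , drop = FALSE] +
    du[seq(2L, 2L * H, 2L), seq(2L, 2L * W, 2L), , drop = FALSE]
  dim(dx) <- c(H * W * B, C)
  dx
}

softmax_rows <- function(z) {
  mx <- do.call(pmax, lapply(seq_len(ncol(z)), function(j) z[, j]))
  e <- exp(z - mx)
  e / rowSums(e)
}
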