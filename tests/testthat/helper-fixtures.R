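# shared miniature objects; everything is generated in code at test time

tiny_phantom <- function(seed = 2L) make_fixture("phantom", seed)

tiny_geometry <- function(scale = 16) ngt_geometry(scale = scale)

# small parenchyma-bearing phantom without lesions
bare_phantom <- function(seed = 5L, vbd = 0.3, pitch = 2) {
  ph <- generate_outline(30, 50, 70, skin_mm = 2, voxel_pitch_mm = pitch,
                         seed = seed)
  synthesize_parenchyma(ph, perlin_config(octaves = 3L, seed = seed),
                        target_vbd = vbd)
}

# 3D 26-connectivity component count (oracle for lesion connectivity)
n_components_3d <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nxt <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      co <- arrayInd(v, d)
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        q <- co + c(dx, dy, dz)
        if (any(q < 1L) || any(q > d)) next
        qi <- q[1] + d[1] * ((q[2] - 1) + d[2] * (q[3] - 1))
        if (mask[qi] && lab[qi] == 0L) {
          lab[qi] <- nxt
          queue <- c(queue, qi)
        }
      }
    }
  }
  nxt
}

# 2D flood-fill component count with selectable connectivity (oracle)
flood_components <- function(mask, eight = TRUE) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nbr <- if (eight) {
    cbind(rep(-1:1, 3), rep(-1:1, each = 3))
  } else {
    rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  }
  nbr <- nbr[!(nbr[, 1] == 0 & nbr[, 2] == 0), , drop = FALSE]
  k <- 0L
  for (c0 in seq_len(nc)) for (r0 in seq_len(nr)) {
    if (!mask[r0, c0] || lab[r0, c0]) next
    k <- k + 1L
    stack <- list(c(r0, c0))
    lab[r0, c0] <- k
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (j in seq_len(nrow(nbr))) {
        q <- p + nbr[j, ]
        if (q[1] < 1 || q[1] > nr || q[2] < 1 || q[2] > nc) next
        if (mask[q[1], q[2]] && !lab[q[1], q[2]]) {
          lab[q[1], q[2]] <- k
          stack[[length(stack) + 1L]] <- q
        }
      }
    }
  }
  list(n = k, labels = lab)
}

# exhaustive Mann-Whitney AUC with tie correction (oracle)
mann_whitney_auc <- function(scores, pos) {
  sp <- scores[pos]
  sn <- scores[!pos]
  tot <- 0
  for (a in sp) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
  tot / (length(sp) * length(sn))
}

# tiny deterministic training pairs with separable classes
toy_pairs <- function(seeds, H = 48L, W = 32L, lesion_signal = 60) {
  lapply(seeds, function(seed) {
    with_seed(seed, {
      tgt <- matrix(1L, H, W)
      tgt[, seq_len(max(1L, W %/% 4L))] <- 0L
      tgt[seq_len(H %/% 3L), (W %/% 4L + 1L):W] <- 2L
      r0 <- sample((H %/% 2L):(H - 6L), 1)
      c0 <- sample((W %/% 2L):(W - 6L), 1)
      for (r in (r0 - 3):(r0 + 3)) {
        for (c in (c0 - 3):(c0 + 3)) {
          if ((r - r0)^2 + (c - c0)^2 <= 9) tgt[r, c] <- 3L
        }
      }
      sig <- c(1000, 400, 150, lesion_signal)
      img <- matrix(stats::rpois(H * W, sig[tgt + 1L]), H, W)
      structure(list(image = img, target = tgt,
                     phantom_id = sprintf("toy%d", seed), split = "train"),
                class = "training_pair")
    })
  })
}
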