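#' Soft-tissue lesion models
#'
#' Four lesion size models spanning the clinically reported soft-tissue
#' finding range: model I is a 7 x 7 x 7 mm ellipsoid with density weight
#' w = 0.20; models II-IV are spiculated, with nominal bounding boxes
#' 9 x 8 x 3, 10 x 14 x 4, and 15 x 15 x 4 mm and w = 0.35. Spiculated
#' masks are built as an ellipsoidal core (60% of the nominal semi-axes)
#' with seeded radial spicules - the six axis directions plus 2-10 random
#' ones - tapering out to the nominal bounding ellipsoid, so the mask's
#' bounding box matches the nominal dimensions within one voxel and the
#' mask is a single connected component.
#'
#' @param model_id one of `"I"`, `"II"`, `"III"`, `"IV"`.
#' @param voxel_pitch_mm isotropic voxel pitch of the target phantom, mm.
#' @param seed integer seed for the spicule directions.
#' @return a `lesion_model`: list with `model_id`, `shape`, `dims_mm`, `w`,
#'   `mask` (3D logical array) and `seed`.
#' @export
make_lesion <- function(model_id, voxel_pitch_mm = 0.5, seed = 1L) {
  spec <- switch(as.character(model_id),
    I   = list(shape = "ellipsoidal", dims = c(7, 7, 7), w = 0.20),
    II  = list(shape = "spiculated", dims = c(9, 8, 3), w = 0.35),
    III = list(shape = "spiculated", dims = c(10, 14, 4), w = 0.35),
    IV  = list(shape = "spiculated", dims = c(15, 15, 4), w = 0.35),
    stop("unknown lesion model_id: ", model_id, call. = FALSE)
  )
  p <- voxel_pitch_mm
  n <- pmax(as.integer(ceiling(spec$dims / p)), 1L)
  # voxel center coordinates relative to the box center, normalized so the
  # nominal bounding ellipsoid is |q| = 1
  ax <- lapply(1:3, function(a) {
    ((seq_len(n[a]) - 0.5) * p - spec$dims[a] / 2) / (spec$dims[a] / 2)
  })
  qx <- array(ax[[1L]], dim = n)
  qy <- aperm(array(ax[[2L]], dim = n[c(2, 1, 3)]), c(2, 1, 3))
  qz <- aperm(array(ax[[3L]], dim = n[c(3, 2, 1)]), c(3, 2, 1))
  r2 <- qx^2 + qy^2 + qz^2

  if (spec$shape == "ellipsoidal") {
    mask <- r2 <= 1
  } else {
    core <- 0.6
    mask <- r2 <= core^2
    ndir <- with_seed(seed, sample(8:16, 1L))
    dirs <- rbind(diag(3), -diag(3))
    extra <- ndir - nrow(dirs)
    if (extra > 0) {
      rnd <- with_seed(derive_seed(seed, 1L),
                       matrix(stats::rnorm(3L * extra), ncol = 3L))
      dirs <- rbind(dirs, rnd / sqrt(rowSums(rnd^2)))
    }
    r <- sqrt(r2)
    shell <- r > core & r <= 1
    if (any(shell)) {
      ux <- qx[shell] / r[shell]
      uy <- qy[shell] / r[shell]
      uz <- qz[shell] / r[shell]
      rs <- r[shell]
      # cone half-angle tapers from ~25 deg at the core to ~7 deg at the tip
      half <- 0.45 * (1 - 0.7 * (rs - core) / (1 - core))
      hit <- rep(FALSE, length(rs))
      for (i in seq_len(nrow(dirs))) {
        cosang <- ux * dirs[i, 1] + uy * dirs[i, 2] + uz * dirs[i, 3]
        hit <- hit | cosang >= cos(half)
      }
      sm <- mask
      sm[shell] <- hit
      mask <- mask | sm
    }
    # rasterize each spicule's center line so every spicule stays connected
    # to the core at coarse voxel pitch
    tstep <- p / (2 * max(spec$dims / 2))
    ts <- seq(0, 1, by = tstep)
    for (i in seq_len(nrow(dirs))) {
      pos <- outer(ts, dirs[i, ])              # normalized coords
      for (a in 1:3) pos[, a] <- pos[, a] * spec$dims[a] / 2 + spec$dims[a] / 2
      ivx <- clamp(floor(pos / p) + 1, 1, matrix(n, nrow(pos), 3, byrow = TRUE))
      mask[cbind(ivx[, 1], ivx[, 2], ivx[, 3])] <- TRUE
    }
  }
  structure(list(model_id = as.character(model_id), shape = spec$shape,
                 dims_mm = spec$dims, w = spec$w, mask = mask,
                 seed = as.integer(seed)),
            class = "lesion_model")
}

#' Insert a lesion into a phantom by voxel addition
#'
#' Voxels covered by the lesion mask, centered at `center_voxel`, are
#' relabelled lesion and carry the model's density weight `w`; the
#' pre-insertion label of each covered voxel is retained so projection can
#' mix the lesion attenuation with the underlying tissue. All other voxels
#' are untouched. The placement must lie fully inside the interior
#' (adipose/dense) and must not overlap an existing lesion.
#'
#' @param phantom a `voxel_phantom` with synthesized parenchyma.
#' @param lesion a `lesion_model`.
#' @param center_voxel integer 3-vector (x, y, z voxel indices, 1-based) of
#'   the lesion bounding-box center.
#' @return the phantom with the lesion embedded and recorded in
#'   `phantom$lesions`.
#' @export
insert_lesion <- function(phantom, lesion, center_voxel) {
  d <- dim(phantom$labels)
  m <- dim(lesion$mask)
  off <- as.integer(center_voxel) - as.integer(floor(m / 2))
  lo <- off + 1L
  hi <- off + m
  if (any(lo < 1L) || any(hi > d)) {
    stop("lesion placement outside the phantom volume", call. = FALSE)
  }
  sub <- phantom$labels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  covered <- lesion$mask
  labs <- sub[covered]
  if (any(labs == LBL_LESION)) {
    stop("lesion placement overlaps an existing lesion", call. = FALSE)
  }
  if (any(labs < LBL_ADIPOSE)) {
    stop("lesion placement straddles skin or background", call. = FALSE)
  }
  # linear indices of covered voxels in the full volume
  mi <- which(covered, arr.ind = TRUE)
  vi <- (off[1] + mi[, 1L]) +
    as.numeric(d[1]) * ((off[2] + mi[, 2L] - 1L) +
                          as.numeric(d[2]) * (off[3] + mi[, 3L] - 1L))
  vi <- as.integer(vi)
  underlying <- phantom$labels[vi]
  phantom$labels[vi] <- LBL_LESION
  phantom$lesions[[length(phantom$lesions) + 1L]] <- list(
    model_id = lesion$model_id, shape = lesion$shape, w = lesion$w,
    dims_mm = lesion$dims_mm, seed = lesion$seed,
    center_voxel = as.integer(center_voxel),
    voxel_idx = vi, underlying = underlying
  )
  phantom
}
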