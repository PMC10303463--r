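# voxel label codes, ordered so that a per-ray maximum ranks
# lesion > dense > adipose > skin > background
LBL_BACKGROUND <- 0L
LBL_SKIN <- 1L
LBL_ADIPOSE <- 2L
LBL_DENSE <- 3L
LBL_LESION <- 4L

#' Generate a compressed-breast outline phantom
#'
#' Builds the voxel container for one breast under mammographic compression:
#' flat compression surfaces separated by the compressed breast thickness
#' (CBT), a super-elliptical axial profile reaching from the chest wall to
#' the chest-wall-to-nipple distance (CND), and a closed skin shell. The
#' interior is provisionally labelled adipose; parenchyma is synthesized by
#' [synthesize_parenchyma()].
#'
#' Coordinates: voxel array dims are (x = left-right, y = posteroanterior,
#' z = craniocaudal/compression axis); all geometry is in mm from the
#' chest-wall corner of the phantom, with the chest wall at y = 0 and the
#' lower compression surface at z = 0.
#'
#' @param cbt_mm compressed breast thickness, mm (typical range 30-70).
#' @param cnd_mm chest-wall-to-nipple distance, mm (typical range 50-110).
#' @param width_mm left-right extent at the chest wall, mm.
#' @param skin_mm skin shell thickness, mm.
#' @param voxel_pitch_mm isotropic voxel pitch, mm.
#' @param seed integer; stored for downstream stages (the outline itself is
#'   deterministic).
#' @param axial_exponent super-ellipse exponent of the axial profile.
#' @return a `voxel_phantom` object.
#' @export
generate_outline <- function(cbt_mm, cnd_mm, width_mm, skin_mm = 1.5,
                             voxel_pitch_mm = 0.5, seed = 1L,
                             axial_exponent = 2.5) {
  if (cbt_mm <= 0 || cnd_mm <= 0 || width_mm <= 0 || skin_mm <= 0 ||
      voxel_pitch_mm <= 0) {
    stop("phantom dimensions and pitch must be positive", call. = FALSE)
  }
  if (cbt_mm < 30 || cbt_mm > 70) {
    warning("cbt_mm outside the typical compressed range 30-70 mm")
  }
  if (cnd_mm < 50 || cnd_mm > 110) {
    warning("cnd_mm outside the typical range 50-110 mm")
  }
  p <- voxel_pitch_mm
  nx <- as.integer(ceiling(width_mm / p))
  ny <- as.integer(ceiling(cnd_mm / p)) + 4L  # small background apron
  nz <- as.integer(ceiling(cbt_mm / p))

  xc <- (seq_len(nx) - 0.5) * p
  yc <- (seq_len(ny) - 0.5) * p
  zc <- (seq_len(nz) - 0.5) * p
  cx <- width_mm / 2
  a <- width_mm / 2
  b <- cnd_mm
  e <- axial_exponent

  inside_axial <- function(shrink) {
    aa <- max(a - shrink, 1e-6)
    bb <- max(b - shrink, 1e-6)
    r <- outer((abs(xc - cx) / aa)^e, (yc / bb)^e, `+`)
    r <= 1 & outer(rep(TRUE, nx), yc >= 0)
  }
  out2d <- inside_axial(0)          # nx x ny, inside the outline
  int2d <- inside_axial(skin_mm)    # inside the shrunken outline

  labels <- array(LBL_BACKGROUND, dim = c(nx, ny, nz))
  zin <- zc > skin_mm & zc < cbt_mm - skin_mm
  yin <- yc >= skin_mm  # close the shell at the chest wall
  int2d <- int2d & matrix(yin, nx, ny, byrow = TRUE)
  for (k in seq_len(nz)) {
    sl <- matrix(LBL_BACKGROUND, nx, ny)
    sl[out2d] <- LBL_SKIN
    if (zin[k]) sl[int2d] <- LBL_ADIPOSE
    labels[, , k] <- sl
  }

  structure(list(
    labels = labels,
    lesion_weight = NULL,  # materialized sparsely via `lesions`
    voxel_pitch_mm = p,
    cbt_mm = cbt_mm, cnd_mm = cnd_mm, width_mm = width_mm,
    skin_mm = skin_mm,
    origin_mm = c(0, 0, 0),
    seed = as.integer(seed),
    vbd = NA_real_,
    perlin = NULL,
    lesions = list()
  ), class = "voxel_phantom")
}

#' @export
print.voxel_phantom <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf(
    "voxel_phantom: %d x %d x %d voxels @ %.3g mm (CBT %.1f, CND %.1f mm)\n",
    d[1], d[2], d[3], x$voxel_pitch_mm, x$cbt_mm, x$cnd_mm))
  cat(sprintf("  vbd: %s; lesions: %d\n",
              ifelse(is.na(x$vbd), "unset", sprintf("%.3f", x$vbd)),
              length(x$lesions)))
  invisible(x)
}

#' Per-voxel lesion density weight as a dense array
#'
#' The weight `w` (proportion of dense tissue added per lesion voxel) is
#' stored sparsely on the phantom; this expands it to a full 3D array,
#' nonzero exactly where the label is lesion.
#' @param phantom a `voxel_phantom`.
#' @export
lesion_weight_array <- function(phantom) {
  w <- array(0, dim = dim(phantom$labels))
  for (les in phantom$lesions) w[les$voxel_idx] <- les$w
  w
}

# indices (linear) of interior voxels: adipose/dense/lesion
interior_idx <- function(phantom) {
  which(phantom$labels >= LBL_ADIPOSE)
}

#' Synthesize Perlin-noise parenchyma inside a phantom
#'
#' Evaluates octave-summed gradient-lattice noise at every interior voxel
#' and thresholds it at the quantile matching the requested volumetric
#' breast density (VBD): voxels above the threshold become dense, the rest
#' adipose, so the realized dense fraction equals `target_vbd` up to
#' quantile granularity.
#'
#' @param phantom a `voxel_phantom` with interior voxels.
#' @param perlin_cfg a [perlin_config()]; its
#'   `density_threshold_quantile` is overridden to `1 - target_vbd` when
#'   `target_vbd` is given.
#' @param target_vbd desired dense fraction among interior voxels, in (0,1).
#'   Defaults to `1 - perlin_cfg$density_threshold_quantile`.
#' @return the phantom with interior voxels relabelled and `vbd` recorded.
#' @export
synthesize_parenchyma <- function(phantom, perlin_cfg,
                                  target_vbd = NULL) {
  if (is.null(target_vbd)) {
    target_vbd <- 1 - perlin_cfg$density_threshold_quantile
  }
  if (!is.numeric(target_vbd) || target_vbd <= 0 || target_vbd >= 1) {
    stop("target_vbd must lie strictly between 0 and 1", call. = FALSE)
  }
  idx <- interior_idx(phantom)
  if (length(idx) == 0L) stop("phantom has no interior voxels", call. = FALSE)
  d <- dim(phantom$labels)
  co <- arrayInd(idx, d)
  p <- phantom$voxel_pitch_mm
  noise <- perlin_fractal((co[, 1L] - 0.5) * p, (co[, 2L] - 0.5) * p,
                          (co[, 3L] - 0.5) * p, perlin_cfg)
  thr <- stats::quantile(noise, probs = 1 - target_vbd, names = FALSE,
                         type = 7)
  dense <- noise > thr
  lab <- phantom$labels
  lab[idx] <- ifelse(dense, LBL_DENSE, LBL_ADIPOSE)
  phantom$labels <- lab
  phantom$vbd <- mean(dense)
  phantom$perlin <- perlin_cfg
  phantom
}
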