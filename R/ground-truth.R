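# risk classes of the ground-truth maps
RISK_BACKGROUND <- 0L  # background or skin
RISK_ADIPOSE <- 1L     # predominantly adipose
RISK_DENSE <- 2L       # predominantly dense
RISK_LESION <- 3L      # lesion

#' Label maximum intensity projection (MIP) risk map
#'
#' Projects the 5-code label volume orthographically along the craniocaudal
#' (compression) axis, keeping per column the label with the highest
#' numerical value, then folds the result to the four risk classes:
#' background and skin to class 0, adipose to 1, dense to 2, lesion to 3.
#' Because the label codes are ordered by risk, the per-column maximum is
#' exactly the highest-risk tissue crossed by each ray.
#'
#' @param phantom a `voxel_phantom`.
#' @return a `risk_map` on the phantom grid: `labels` matrix with rows =
#'   posteroanterior (y), cols = left-right (x), plus alignment metadata.
#' @export
compute_mip <- function(phantom) {
  lab <- phantom$labels
  d <- dim(lab)
  mx <- lab[, , 1L]
  for (k in seq_len(d[3])[-1L]) mx <- pmax(mx, lab[, , k])
  fold <- c(RISK_BACKGROUND, RISK_BACKGROUND, RISK_ADIPOSE, RISK_DENSE,
            RISK_LESION)
  folded <- matrix(fold[mx + 1L], nrow = d[1])
  structure(list(labels = t(folded),  # rows = y (PA), cols = x (LR)
                 grid = "phantom",
                 pitch = phantom$voxel_pitch_mm,
                 dims = d, cbt_mm = phantom$cbt_mm, cnd_mm = phantom$cnd_mm,
                 origin_x = NA_real_),
            class = "risk_map")
}

#' Rescale a phantom-grid risk map to the detector pixel grid
#'
#' Accounts for the central-projection magnification of the phantom
#' mid-plane (CBT/2 above the breast support): each detector pixel center
#' is backprojected along its ray to the mid-plane and assigned the
#' nearest phantom column's class (nearest neighbor, so no new classes are
#' created). Pixels whose rays miss the phantom get class 0.
#'
#' @param risk_map a phantom-grid `risk_map` from [compute_mip()].
#' @param geometry an [ngt_geometry()].
#' @param origin_x x offset (mm) of the phantom on the detector; defaults
#'   to centered placement as used by [project()].
#' @return a `risk_map` on the projection grid (`n_v` x `n_u`).
#' @export
rescale_to_projection <- function(risk_map, geometry, origin_x = NULL) {
  stopifnot(identical(risk_map$grid, "phantom"))
  if (is.null(origin_x)) {
    width_mm <- risk_map$dims[1] * risk_map$pitch
    origin_x <- (geometry$detector_size_mm[1] - width_mm) / 2
  }
  pc <- detector_pixel_centers(geometry)
  src <- geometry$source_position_mm
  z_mid <- risk_map$cbt_mm / 2
  tt <- (src[3] - z_mid) / (src[3] - pc$z)  # fraction source -> detector
  px <- src[1] + tt * (pc$x - src[1])       # mid-plane x per detector col
  py <- src[2] + tt * (pc$y - src[2])       # mid-plane y per detector row
  ix <- floor((px - origin_x) / risk_map$pitch) + 1
  iy <- floor((py - 0) / risk_map$pitch) + 1
  lab_src <- risk_map$labels  # rows = y, cols = x
  out <- matrix(RISK_BACKGROUND, geometry$n_v, geometry$n_u)
  okx <- ix >= 1 & ix <= risk_map$dims[1]
  oky <- iy >= 1 & iy <= risk_map$dims[2]
  if (any(okx) && any(oky)) {
    out[oky, okx] <- lab_src[iy[oky], ix[okx]]
  }
  structure(list(labels = out, grid = "projection",
                 pitch = geometry$detector_element_mm[1],
                 dims = c(geometry$n_v, geometry$n_u),
                 cbt_mm = risk_map$cbt_mm, cnd_mm = risk_map$cnd_mm,
                 origin_x = origin_x, magnification = 1 / tt),
            class = "risk_map")
}

#' Cohort-wide crop window for training pairs
#'
#' The crop keeps detector rows from the chest wall out to the largest
#' projected (magnified) posteroanterior breast extent over the cohort,
#' removing background rows on the nipple side.
#'
#' @param manifest a `cohort_manifest`.
#' @param geometry an [ngt_geometry()].
#' @param out_dims output (rows, cols) after downsampling.
#' @export
cohort_crop_window <- function(manifest, geometry, out_dims = c(96L, 64L)) {
  src <- geometry$source_position_mm
  det_z <- -geometry$air_gap_mm
  mag <- (src[3] - det_z) / (src[3] - manifest$cbt_mm / 2)
  extent <- max((manifest$cnd_mm + 1) * mag)  # +1 mm guard ring
  n_rows <- min(geometry$n_v,
                as.integer(ceiling(extent / geometry$detector_element_mm[2])))
  list(rows = n_rows, cols = geometry$n_u, out_dims = as.integer(out_dims))
}

# block-average downsampling (non-integer factors partition the source
# rows/cols into nearly equal contiguous blocks); an axis that must grow
# falls back to nearest-neighbor replication
downsample_mean <- function(mat, out_dims) {
  shrink_axis <- function(m, out_n) {
    b <- round(seq(0, nrow(m), length.out = out_n + 1))
    g <- rep(seq_len(out_n), times = diff(b))
    rowsum(m, g) / as.vector(diff(b))
  }
  grow_axis <- function(m, out_n) {
    m[ceiling((seq_len(out_n) - 0.5) * nrow(m) / out_n), , drop = FALSE]
  }
  ax <- function(m, out_n) {
    if (nrow(m) >= out_n) shrink_axis(m, out_n) else grow_axis(m, out_n)
  }
  t(ax(t(ax(mat, out_dims[1])), out_dims[2]))
}

downsample_nn <- function(mat, out_dims) {
  ri <- ceiling((seq_len(out_dims[1]) - 0.5) * nrow(mat) / out_dims[1])
  ci <- ceiling((seq_len(out_dims[2]) - 0.5) * ncol(mat) / out_dims[2])
  mat[ri, ci, drop = FALSE]
}

#' Build an aligned (image, risk map) training pair
#'
#' Applies the identical crop window to the projection and its risk map,
#' then downsamples the image by block averaging and the labels by nearest
#' neighbor to the configured output dimensions.
#'
#' @param projection a `projection_image`.
#' @param risk_map a projection-grid `risk_map`.
#' @param crop_cfg from [cohort_crop_window()].
#' @param phantom_id,split carried into the pair.
#' @return a `training_pair`: `image` (matrix), `target` (integer matrix of
#'   classes 0..3), `phantom_id`, `split`.
#' @export
make_training_pair <- function(projection, risk_map, crop_cfg,
                               phantom_id = NA_character_,
                               split = NA_character_) {
  if (!identical(dim(projection$pixels), dim(risk_map$labels))) {
    stop("projection and risk map are on different grids", call. = FALSE)
  }
  rows <- seq_len(crop_cfg$rows)
  cols <- seq_len(crop_cfg$cols)
  img <- downsample_mean(projection$pixels[rows, cols, drop = FALSE],
                         crop_cfg$out_dims)
  tgt <- downsample_nn(risk_map$labels[rows, cols, drop = FALSE],
                       crop_cfg$out_dims)
  structure(list(image = img, target = tgt,
                 phantom_id = phantom_id, split = split,
                 crop_cfg = crop_cfg),
            class = "training_pair")
}

#' Write a risk map as a palette-coded PNG
#' @param risk_map a `risk_map`.
#' @param path output path.
#' @export
write_risk_map_png <- function(risk_map, path) {
  img <- risk_map$labels / 3
  png::writePNG(img, path)
  invisible(path)
}
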