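#' Acquisition geometry of the central tomosynthesis projection
#'
#' The prototype next-generation tomosynthesis (NGT) geometry: a stationary
#' a-Se detector of 239.36 x 304.64 mm with 0.085 x 0.085 mm elements and a
#' source-image distance of 738.01 mm. For the central projection the
#' source sits on the normal through the midpoint of the chest-wall
#' detector edge. `scale` coarsens the detector element (and shrinks the
#' pixel grid accordingly) so desk-scale studies stay tractable; the
#' physical detector extent is unchanged.
#'
#' The global frame matches the phantom frame: x left-right, y
#' posteroanterior (chest wall at y = 0), z craniocaudal with the breast
#' support at z = 0 and the detector plane at z = -air_gap_mm.
#'
#' @param scale multiplier on the 0.085 mm detector element.
#' @param air_gap_mm breast-support-to-detector distance, mm.
#' @param source_position_mm optional explicit source position; default is
#'   the central projection.
#' @export
ngt_geometry <- function(scale = 1, air_gap_mm = 20,
                         source_position_mm = NULL) {
  det_size <- c(239.36, 304.64)          # width (x), height (y)
  elem <- c(0.085, 0.085) * scale
  n_u <- as.integer(round(det_size[1] / elem[1]))
  n_v <- as.integer(round(det_size[2] / elem[2]))
  sid <- 738.01
  src <- source_position_mm %||% c(det_size[1] / 2, 0, sid - air_gap_mm)
  structure(list(
    source_position_mm = src,
    source_image_distance_mm = sid,
    detector_size_mm = det_size,
    detector_element_mm = elem,
    detector_offset_mm = c(0, 0),
    air_gap_mm = air_gap_mm,
    n_u = n_u, n_v = n_v
  ), class = "acquisition_geometry")
}

# detector pixel center coordinates (mm) in the global frame
detector_pixel_centers <- function(geometry) {
  list(
    x = geometry$detector_offset_mm[1] +
      (seq_len(geometry$n_u) - 0.5) * geometry$detector_element_mm[1],
    y = geometry$detector_offset_mm[2] +
      (seq_len(geometry$n_v) - 0.5) * geometry$detector_element_mm[2],
    z = -geometry$air_gap_mm
  )
}

# x offset centering the phantom on the detector
phantom_x_offset <- function(phantom, geometry) {
  (geometry$detector_size_mm[1] - phantom$width_mm) / 2
}

#' Linear attenuation coefficients of the phantom materials
#'
#' Monoenergetic table (mm^-1) at a 20 keV effective energy, in the style
#' of the ICRU Report 44 soft-tissue data. Air is treated as
#' non-attenuating at these path lengths, so unobstructed detector pixels
#' read exactly the unattenuated fluence.
#'
#' @param effective_energy_keV recorded for provenance (single-energy table).
#' @param air,skin,adipose,dense coefficients in mm^-1.
#' @export
material_table <- function(effective_energy_keV = 20, air = 0,
                           skin = 0.075, adipose = 0.047, dense = 0.0802) {
  stopifnot(air < adipose, adipose < skin, skin <= dense, air >= 0)
  structure(list(effective_energy_keV = effective_energy_keV,
                 mu = c(air = air, skin = skin, adipose = adipose,
                        dense = dense)),
            class = "material_table")
}

#' Automatic-exposure-control-like exposure settings
#'
#' Scales the unattenuated photon count per detector element so the mean
#' transmitted count behind the breast center stays near a fixed target,
#' emulating clinical automatic exposure control: counts grow
#' exponentially with compressed thickness and glandularity,
#' `photons = target * exp(mu_eff(vbd) * cbt)` with
#' `mu_eff = (1 - vbd) mu_adipose + vbd mu_dense`.
#'
#' @param cbt_mm compressed breast thickness, mm.
#' @param vbd volumetric breast density in \[0, 1\].
#' @param target_count transmitted-count target behind the breast (the
#'   low-dose regime of a scout projection).
#' @param materials a [material_table()].
#' @export
aec_exposure <- function(cbt_mm, vbd, target_count = 50,
                         materials = material_table()) {
  stopifnot(cbt_mm > 0, vbd >= 0, vbd <= 1)
  mu_eff <- (1 - vbd) * materials$mu[["adipose"]] + vbd * materials$mu[["dense"]]
  structure(list(
    photons_per_pixel_air = target_count * exp(mu_eff * cbt_mm),
    effective_energy_keV = materials$effective_energy_keV,
    target_count = target_count
  ), class = "exposure_settings")
}

# per-voxel linear attenuation; lesion voxels mix the underlying tissue
# with dense tissue through the lesion density weight w
mu_volume <- function(phantom, materials) {
  lut <- c(materials$mu[["air"]], materials$mu[["skin"]],
           materials$mu[["adipose"]], materials$mu[["dense"]],
           materials$mu[["dense"]])  # placeholder; lesions overwritten below
  mu <- array(lut[phantom$labels + 1L], dim = dim(phantom$labels))
  for (les in phantom$lesions) {
    mu_under <- lut[pmax(les$underlying, LBL_ADIPOSE) + 1L]
    mu[les$voxel_idx] <- (1 - les$w) * mu_under +
      les$w * materials$mu[["dense"]]
  }
  mu
}

#' Exact ray path through a phantom (Siddon traversal)
#'
#' Returns the voxels crossed by the segment from the source to one
#' detector pixel center, with exact slab-intersection lengths; the lengths
#' sum to the chord length of the segment inside the phantom bounding box.
#'
#' @param geometry an [ngt_geometry()].
#' @param pixel_index integer 2-vector (row v, column u) of the detector
#'   pixel, 1-based.
#' @param phantom a `voxel_phantom`.
#' @return data.frame with voxel indices `ix`, `iy`, `iz` (1-based) and
#'   `length_mm`; zero rows when the ray misses the volume.
#' @export
siddon_raypath <- function(geometry, pixel_index, phantom) {
  stopifnot(pixel_index[1] >= 1, pixel_index[1] <= geometry$n_v,
            pixel_index[2] >= 1, pixel_index[2] <= geometry$n_u)
  pc <- detector_pixel_centers(geometry)
  dst <- c(pc$x[pixel_index[2]], pc$y[pixel_index[1]], pc$z)
  origin <- c(phantom_x_offset(phantom, geometry), 0, 0)
  res <- cpp_siddon_path(geometry$source_position_mm, dst, origin,
                         phantom$voxel_pitch_mm, dim(phantom$labels))
  as.data.frame(res)
}

#' Simulate one projection of a phantom
#'
#' Beer-Lambert transmission imaging: for every detector pixel the line
#' integral `L = sum mu * length` is accumulated by Siddon traversal from
#' the source to the pixel center, the mean signal is
#' `photons_per_pixel_air * exp(-L)`, and (optionally) Poisson quantum
#' noise is drawn with a fixed seed. Lesion voxels attenuate as
#' `(1 - w) mu_underlying + w mu_dense`.
#'
#' @param phantom a `voxel_phantom`.
#' @param geometry an [ngt_geometry()].
#' @param exposure an [aec_exposure()].
#' @param materials a [material_table()].
#' @param noise_seed integer seed for Poisson noise, or `NULL` for the
#'   noiseless mean image.
#' @return a `projection_image`: list with `pixels` (matrix, rows =
#'   posteroanterior v, cols = left-right u), `mean_pixels`, `geometry`,
#'   `exposure`, `noise_seed`, `phantom_id`.
#' @export
project <- function(phantom, geometry, exposure, materials = material_table(),
                    noise_seed = NULL) {
  mu <- mu_volume(phantom, materials)
  pc <- detector_pixel_centers(geometry)
  origin <- c(phantom_x_offset(phantom, geometry), 0, 0)
  L <- cpp_project_lines(mu, origin, phantom$voxel_pitch_mm,
                         geometry$source_position_mm, pc$x, pc$y, pc$z)
  mean_img <- exposure$photons_per_pixel_air * exp(-L)
  pixels <- if (is.null(noise_seed)) {
    mean_img
  } else {
    matrix(with_seed(noise_seed, stats::rpois(length(mean_img), mean_img)),
           nrow = nrow(mean_img))
  }
  structure(list(pixels = pixels, mean_pixels = mean_img,
                 geometry = geometry, exposure = exposure,
                 noise_seed = noise_seed,
                 phantom_meta = phantom_alignment_meta(phantom, geometry),
                 phantom_id = attr(phantom, "phantom_id") %||% NA_character_),
            class = "projection_image")
}

# the alignment facts ground-truth rescaling needs
phantom_alignment_meta <- function(phantom, geometry) {
  list(origin_x = phantom_x_offset(phantom, geometry), origin_y = 0,
       pitch = phantom$voxel_pitch_mm, dims = dim(phantom$labels),
       cbt_mm = phantom$cbt_mm, cnd_mm = phantom$cnd_mm)
}

#' Write a projection as a 16-bit grayscale TIFF with a JSON sidecar
#'
#' Counts are stored as `pixels / max_count` in the TIFF's unit range;
#' `max_count` and the acquisition parameters go to the sidecar.
#' @param proj a `projection_image`.
#' @param path output TIFF path (sidecar gets extension .json).
#' @export
write_projection_tiff <- function(proj, path) {
  mx <- max(proj$pixels, 1)
  img <- clamp(proj$pixels / mx, 0, 1)
  tiff::writeTIFF(img, path, bits.per.sample = 16L)
  side <- list(max_count = mx,
               photons_per_pixel_air = proj$exposure$photons_per_pixel_air,
               effective_energy_keV = proj$exposure$effective_energy_keV,
               noise_seed = proj$noise_seed,
               n_u = proj$geometry$n_u, n_v = proj$geometry$n_v,
               detector_element_mm = proj$geometry$detector_element_mm,
               source_position_mm = proj$geometry$source_position_mm)
  jsonlite::write_json(side, paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
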