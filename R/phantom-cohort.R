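#' Cohort configuration
#'
#' Parameter grids and sizes for a phantom cohort. Each phantom draws its
#' compressed breast thickness (CBT), chest-wall-to-nipple distance (CND)
#' and target volumetric breast density (VBD) uniformly from the grids;
#' breast width is tied to CND (`width_factor * cnd`, capped to the
#' detector). Two lesions per phantom are drawn from `lesion_models`.
#'
#' @param n_phantoms cohort size.
#' @param split_ratio integer 4-vector of train/validation/calibration/test
#'   proportions (taken relative to its sum).
#' @param cbt_grid_mm,cnd_grid_mm,vbd_grid candidate values sampled per
#'   phantom.
#' @param width_factor breast LR width as a multiple of CND.
#' @param max_width_mm cap on breast width, mm.
#' @param voxel_pitch_mm,skin_mm phantom discretization and skin thickness.
#' @param perlin a [perlin_config()] used as template (per-phantom seeds are
#'   derived from the master seed).
#' @param lesion_models character vector of model ids sampled per lesion.
#' @param max_place_tries placement retries per lesion before the phantom is
#'   recorded as failed.
#' @export
cohort_config <- function(n_phantoms = 32L,
                          split_ratio = c(16L, 4L, 4L, 8L),
                          cbt_grid_mm = seq(30, 70, by = 10),
                          cnd_grid_mm = seq(50, 110, by = 10),
                          vbd_grid = c(0.1, 0.2, 0.35, 0.5),
                          width_factor = 1.5,
                          max_width_mm = 220,
                          voxel_pitch_mm = 1.0,
                          skin_mm = 1.5,
                          perlin = perlin_config(),
                          lesion_models = c("I", "II", "III", "IV"),
                          max_place_tries = 60L) {
  stopifnot(n_phantoms >= 1, length(split_ratio) == 4, all(split_ratio > 0))
  structure(as.list(environment()), class = "cohort_config")
}

SPLIT_NAMES <- c("train", "validation", "calibration", "test")

#' Build a seeded phantom cohort with a stratified split manifest
#'
#' Generates `n_phantoms` compressed-breast phantoms (outline, Perlin
#' parenchyma at the drawn VBD, two non-overlapping lesions at random
#' posteroanterior/left-right positions centered craniocaudally), persists
#' each volume, and assigns train/validation/calibration/test splits
#' stratified by VBD tercile, lesion shape combination and CBT tercile.
#' Within each stratum, split quotas are apportioned by largest remainder
#' with a running carry, so each stratum is within one record of
#' proportionality and the global split sizes match the configured ratio
#' exactly.
#'
#' @param cohort_cfg a [cohort_config()].
#' @param master_seed integer; every random draw derives from it.
#' @param out_dir directory for persisted phantom volumes (RDS) and the
#'   manifest (CSV + JSON config echo). Created if missing.
#' @return a `cohort_manifest` data.frame (one row per phantom) with the
#'   configuration attached as attributes.
#' @export
build_cohort <- function(cohort_cfg, master_seed, out_dir = tempfile("cohort")) {
  cfg <- cohort_cfg
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", cfg$n_phantoms)
  for (i in seq_len(cfg$n_phantoms)) {
    seed_i <- derive_seed(master_seed, i)
    ph <- with_seed(seed_i, generate_phantom_record(cfg, seed_i, i))
    if (is.null(ph)) {
      rows[[i]] <- NULL
      next
    }
    path <- file.path(out_dir, sprintf("phantom_%03d.rds", i))
    saveRDS(ph$phantom, path)
    ph$record$path <- path
    rows[[i]] <- ph$record
  }
  ok <- !vapply(rows, is.null, logical(1))
  if (!all(ok)) {
    warning(sum(!ok), " phantom(s) failed lesion placement and were dropped")
  }
  manifest <- do.call(rbind, rows[ok])
  manifest$split <- assign_stratified_split(manifest, cfg$split_ratio,
                                            derive_seed(master_seed, 999991L))
  attr(manifest, "cohort_cfg") <- cfg
  attr(manifest, "master_seed") <- master_seed
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(master_seed = master_seed,
         config = cfg[setdiff(names(cfg), "perlin")],
         perlin = unclass(cfg$perlin)),
    file.path(out_dir, "manifest_config.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  class(manifest) <- c("cohort_manifest", class(manifest))
  manifest
}

# generate one phantom + manifest record; assumes the RNG is already seeded
generate_phantom_record <- function(cfg, seed_i, i) {
  pick <- function(v) v[sample.int(length(v), 1L)]
  cbt <- pick(cfg$cbt_grid_mm)
  cnd <- pick(cfg$cnd_grid_mm)
  vbd <- pick(cfg$vbd_grid)
  width <- min(cfg$width_factor * cnd, cfg$max_width_mm)
  ph <- generate_outline(cbt, cnd, width, cfg$skin_mm, cfg$voxel_pitch_mm,
                         seed = seed_i)
  pcfg <- cfg$perlin
  pcfg$seed <- derive_seed(seed_i, 1L)
  pcfg$density_threshold_quantile <- 1 - vbd
  ph <- synthesize_parenchyma(ph, pcfg, target_vbd = vbd)

  centers <- list()
  radii <- numeric(0)
  les_info <- list()
  for (j in 1:2) {
    model <- cfg$lesion_models[sample.int(length(cfg$lesion_models), 1L)]
    les <- make_lesion(model, cfg$voxel_pitch_mm,
                       seed = derive_seed(seed_i, 10L + j))
    placed <- FALSE
    d <- dim(ph$labels)
    zc <- as.integer(round(d[3] / 2))  # craniocaudal center
    rad <- sqrt(sum(les$dims_mm^2)) / 2
    for (try in seq_len(cfg$max_place_tries)) {
      cxy <- c(sample.int(d[1], 1L), sample.int(d[2], 1L))
      cen <- c(cxy, zc)
      if (length(centers) > 0) {
        sep <- sqrt(sum(((cen - centers[[1]]) * cfg$voxel_pitch_mm)^2))
        if (sep < rad + radii[1]) next
      }
      ph2 <- tryCatch(insert_lesion(ph, les, cen), error = function(e) NULL)
      if (!is.null(ph2)) {
        ph <- ph2
        centers[[j]] <- cen
        radii[j] <- rad
        les_info[[j]] <- list(model = model, shape = les$shape, w = les$w,
                              center = cen)
        placed <- TRUE
        break
      }
    }
    if (!placed) return(NULL)  # per-phantom failure; cohort continues
  }
  rec <- data.frame(
    phantom_id = sprintf("ph%03d", i),
    seed = seed_i, cbt_mm = cbt, cnd_mm = cnd, width_mm = width,
    target_vbd = vbd, vbd = ph$vbd, perlin_seed = pcfg$seed,
    lesion1_model = les_info[[1]]$model, lesion1_shape = les_info[[1]]$shape,
    lesion1_w = les_info[[1]]$w,
    lesion1_cx = centers[[1]][1], lesion1_cy = centers[[1]][2],
    lesion1_cz = centers[[1]][3],
    lesion2_model = les_info[[2]]$model, lesion2_shape = les_info[[2]]$shape,
    lesion2_w = les_info[[2]]$w,
    lesion2_cx = centers[[2]][1], lesion2_cy = centers[[2]][2],
    lesion2_cz = centers[[2]][3],
    stringsAsFactors = FALSE
  )
  list(phantom = ph, record = rec)
}

#' Regenerate a phantom from its manifest record
#'
#' Rebuilding from the recorded seeds is bit-identical to the persisted
#' volume (full reproducibility of the cohort from the manifest).
#' @param manifest a `cohort_manifest`.
#' @param phantom_id id of the record to regenerate.
#' @export
regenerate_phantom <- function(manifest, phantom_id) {
  cfg <- attr(manifest, "cohort_cfg")
  rec <- manifest[manifest$phantom_id == phantom_id, ]
  if (nrow(rec) != 1) stop("unknown phantom_id: ", phantom_id, call. = FALSE)
  i <- as.integer(sub("^ph", "", phantom_id))
  out <- with_seed(rec$seed, generate_phantom_record(cfg, rec$seed, i))
  out$phantom
}

# terciles as integer strata (1..3); degenerate spread collapses gracefully
tercile_of <- function(x) {
  q <- stats::quantile(x, c(1 / 3, 2 / 3), names = FALSE, type = 7)
  findInterval(x, unique(q)) + 1L
}

# controlled-rounding split apportionment: per-stratum largest remainder
# (every stratum within one record of proportionality), then single-record
# swaps between strata to restore the exact global quotas without pushing
# any stratum past the one-record band
assign_stratified_split <- function(manifest, ratio, seed) {
  frac <- ratio / sum(ratio)
  n <- nrow(manifest)
  shape_pair <- apply(cbind(manifest$lesion1_shape, manifest$lesion2_shape),
                      1L, function(s) paste(sort(s), collapse = "+"))
  strata <- paste(tercile_of(manifest$vbd), shape_pair,
                  tercile_of(manifest$cbt_mm), sep = "|")
  sts <- unique(strata)
  n_t <- vapply(sts, function(s) sum(strata == s), integer(1))

  lr <- function(ideal, total) {
    base <- floor(ideal)
    short <- total - sum(base)
    if (short > 0) {
      add <- order(ideal - base, decreasing = TRUE)[seq_len(short)]
      base[add] <- base[add] + 1
    }
    base
  }
  quota <- lr(n * frac, n)                    # exact global sizes
  ideal <- outer(n_t, frac)                   # strata x splits
  take <- t(vapply(seq_along(sts),
                   function(t) lr(ideal[t, ], n_t[t]), numeric(4)))
  # repair pass: move single records between over- and under-quota splits,
  # choosing strata where the move stays within the one-record band
  deficit <- quota - colSums(take)
  guard <- 0L
  while (any(deficit > 0) && guard < 10000L) {
    guard <- guard + 1L
    s_plus <- which(deficit > 0)[1L]
    s_minus <- which(deficit < 0)[1L]
    cand <- which(take[, s_plus] < ceiling(ideal[, s_plus]) &
                    take[, s_minus] > floor(ideal[, s_minus]) &
                    take[, s_minus] > 0)
    if (length(cand) == 0) {
      cand <- which(take[, s_minus] > 0)  # fallback: feasibility first
    }
    t0 <- cand[1L]
    take[t0, s_plus] <- take[t0, s_plus] + 1
    take[t0, s_minus] <- take[t0, s_minus] - 1
    deficit <- quota - colSums(take)
  }
  split <- character(n)
  for (t in seq_along(sts)) {
    idx <- which(strata == sts[t])
    idx <- idx[with_seed(derive_seed(seed, t), sample.int(length(idx)))]
    split[idx] <- rep(SPLIT_NAMES, times = take[t, ])
  }
  factor(split, levels = SPLIT_NAMES)
}
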