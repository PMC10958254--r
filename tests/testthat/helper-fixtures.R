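# Fixtures built in code: tiny volumes, rendered discs and small cohort
# configurations shared across test files.

# A rasterized disc on an isotropic grid (pixel centres at (i-0.5)*px mm).
disc_raster <- function(shape, px_mm, center_mm, radius_mm) {
  y <- (seq_len(shape[1]) - 0.5) * px_mm
  x <- (seq_len(shape[2]) - 0.5) * px_mm
  outer((y - center_mm[2])^2, (x - center_mm[1])^2, `+`) <= radius_mm^2
}

# Render a mask with an exact pixel count (closest sublevel set of the
# distance to a centre point): lets tests pin an area precisely.
disc_exact_px <- function(shape, center_px, n_px) {
  d2 <- outer((seq_len(shape[1]) - center_px[1])^2,
              (seq_len(shape[2]) - center_px[2])^2, `+`)
  m <- matrix(FALSE, shape[1], shape[2])
  m[order(as.vector(d2))[seq_len(n_px)]] <- TRUE
  m
}

make_meta <- function(eye_id = "E1", arm = "SHAM", visit_month = 0,
                      laterality = "OD", n_bscans = 25,
                      ascan_spacing_mm = 0.01, field_mm = c(3, 3),
                      fovea_xy_mm = field_mm / 2, acquisition_id = NULL) {
  volume_meta(eye_id = eye_id, arm = arm, visit_month = visit_month,
              laterality = laterality, n_bscans = n_bscans,
              ascan_spacing_mm = ascan_spacing_mm,
              bscan_spacing_mm = field_mm[2] / n_bscans,
              fovea_xy_mm = fovea_xy_mm, field_extent_mm = field_mm,
              acquisition_id = acquisition_id)
}

# A volume whose B-scans are all-zero except listed (bscan, ascan) voxels.
make_volume <- function(meta, feature = "RPE_LOSS", n_axial = 8,
                        n_ascan = 30, voxels = NULL) {
  masks <- replicate(meta$n_bscans, matrix(FALSE, n_axial, n_ascan),
                     simplify = FALSE)
  if (!is.null(voxels)) {
    for (i in seq_len(nrow(voxels))) {
      masks[[voxels[i, 1]]][max(1, n_axial %/% 2), voxels[i, 2]] <- TRUE
    }
  }
  segmentation_volume(meta, feature, masks)
}

make_group <- function(meta, n_axial = 8, n_ascan = 30,
                       voxels = list(NULL, NULL, NULL)) {
  volume_group(
    make_volume(meta, "RPE_LOSS", n_axial, n_ascan, voxels[[1]]),
    make_volume(meta, "PRD", n_axial, n_ascan, voxels[[2]]),
    make_volume(meta, "HTR", n_axial, n_ascan, voxels[[3]])
  )
}

# Small, fast cohort configuration: 3.2 mm field at 0.02 mm/px. The ETDRS
# grid does not fit in this field, so it is only for volume/feature-level
# tests.
tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(
    n_per_arm = c(SHAM = 1), visit_months = c(0, 12),
    grid_px = c(160, 160), px_mm = 0.02, n_bscans = 25, n_axial_px = 8,
    baseline_area_mean_mm2 = 0.8, baseline_area_sd_mm2 = 0.3,
    baseline_area_range_mm2 = c(0.8, 0.8), seed_region_mm = 0.4,
    prd_halo_mm = 0.1, fovea_jitter_mm = 0.02, rng_seed = 11L
  )
  defaults[names(args)] <- args
  do.call(cohort_config, defaults)
}

# Random en-face map set for set-algebra tests.
random_constituents <- function(shape, p = 0.4, px = 0.01) {
  maps <- lapply(c(RPE_LOSS = 1, PRD = 2, HTR = 3), function(i) {
    matrix(runif(prod(shape)) < p, shape[1], shape[2])
  })
  enface_maps(maps, px_spacing_mm = c(px, px),
              fovea_px = (shape + 1) / 2)
}

# Brute-force per-pixel boolean oracle for the composite definitions.
brute_force_composites <- function(rpe, prd, htr, disc) {
  nr <- nrow(rpe); nc <- ncol(rpe)
  rora <- iso <- intact <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      rora[i, j] <- rpe[i, j] && prd[i, j] && htr[i, j]
      iso[i, j] <- prd[i, j] && !rpe[i, j] && !htr[i, j]
      intact[i, j] <- disc[i, j] && !(rpe[i, j] || prd[i, j] || htr[i, j])
    }
  }
  list(RORA = rora, PRD_ISOLATED = iso, INTACT_MACULA = intact)
}
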