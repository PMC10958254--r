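# Synthetic trial cohort: per-eye GA natural history rendered as
# segmentation volumes with known ground truth.
#
# The lesion model: k seed points (multifocal), grown by Euclidean distance
# transform so that sqrt(total RPE-loss area) is affine in time,
# sqrt(A_t) = b + m * t/12, with m = arm multiplier x sham growth x a
# per-eye lognormal factor. PRD is the RPE-loss region dilated by a halo
# (so isolated PRD is the halo annulus, i.e. photoreceptor degeneration
# spatially leading RPE loss); hypertransmission equals RPE loss up to
# boundary noise. The recorded fovea is jittered per visit to emulate
# imperfect fovea localisation.

#' Configure a synthetic GA cohort
#'
#' Defaults encode the emulated trial conditions: arm sizes 71/61/65
#' (PM/PEOM/SHAM), sham square-root growth 0.277 mm/year with arm
#' multipliers 0.55 (PM) and 0.73 (PEOM), baseline RORA area gamma with
#' mean 7.0 and SD 3.39 mm^2, truncated-geometric seed counts with mean
#' about 3.1 (max 12), and between-eye growth variability plus per-visit
#' measurement noise calibrated so the SD profile of sqrt-area change
#' matches 0.15/0.21/0.26 mm at months 6/12/18 in the sham arm.
#'
#' @param n_per_arm Named integer vector of eyes per arm
#'   (`c(PM=, PEOM=, SHAM=)`); entries may be 0.
#' @param visit_months Ascending integer visit months, first must be 0.
#' @param grid_px En-face truth raster size `c(rows, cols)`. The default
#'   620 px at 0.01 mm/px gives a 6.2 mm field: 0.1 mm of margin around the
#'   6 mm ETDRS disc so that fovea-localisation jitter cannot push the grid
#'   off the raster.
#' @param px_mm Isotropic truth-raster pixel pitch, mm.
#' @param n_bscans B-scans per rendered volume.
#' @param n_axial_px Axial rows per rendered B-scan (binary occupancy band).
#' @param sham_sqrt_growth_mm_per_year Mean sqrt-area growth in the sham arm.
#' @param arm_effect Named multipliers in (0, 1]; `SHAM` must be 1.
#' @param growth_sd_frac Between-eye SD of the growth rate as a fraction of
#'   the arm mean (lognormal, mean-preserving).
#' @param measurement_sd_mm Per-visit SD of measured sqrt-area in the
#'   analytic table path ([simulate_growth_table()]); the rendered rasters
#'   themselves follow the affine law without visit noise.
#' @param focality_mean,focality_max Mean and cap of the truncated-geometric
#'   seed-count distribution.
#' @param baseline_area_mean_mm2,baseline_area_sd_mm2 Gamma moments of
#'   baseline RPE-loss area.
#' @param baseline_area_range_mm2 Hard clamp on sampled baseline areas.
#' @param prd_halo_mm Width of the PRD halo around RPE loss.
#' @param htr_agreement Probability that an RPE-loss boundary pixel is also
#'   hypertransmission (interior pixels always are).
#' @param fovea_jitter_mm SD of the recorded-fovea jitter per axis and visit.
#' @param min_seed_sep_mm Minimum pairwise seed separation.
#' @param seed_region_mm Seeds are placed within this radius of the fovea.
#' @param rng_seed Root seed; all randomness is derived from it via
#'   per-eye sub-seeds, so results do not depend on iteration order.
#'
#' @return A `cohort_config` object.
#' @export
cohort_config <- function(n_per_arm = c(PM = 71, PEOM = 61, SHAM = 65),
                          visit_months = c(0, 2, 6, 12, 18),
                          grid_px = c(620, 620),
                          px_mm = 0.01,
                          n_bscans = 49,
                          n_axial_px = 32,
                          sham_sqrt_growth_mm_per_year = 0.277,
                          arm_effect = c(PM = 0.55, PEOM = 0.73, SHAM = 1),
                          growth_sd_frac = 0.6,
                          measurement_sd_mm = 0.09,
                          focality_mean = 3.14,
                          focality_max = 12,
                          baseline_area_mean_mm2 = 7.0,
                          baseline_area_sd_mm2 = 3.39,
                          baseline_area_range_mm2 = c(1.0, 17.0),
                          prd_halo_mm = 0.25,
                          htr_agreement = 0.95,
                          fovea_jitter_mm = 0.05,
                          min_seed_sep_mm = 0.3,
                          seed_region_mm = 1.6,
                          rng_seed = 1L) {
  stopifnot(
    all(names(n_per_arm) %in% .ARMS), all(n_per_arm >= 0),
    length(visit_months) >= 1, visit_months[1] == 0,
    !is.unsorted(visit_months, strictly = TRUE),
    length(grid_px) == 2, all(grid_px >= 50), px_mm > 0,
    n_bscans >= 1, n_axial_px >= 4,
    sham_sqrt_growth_mm_per_year > 0,
    all(arm_effect > 0), all(arm_effect <= 1),
    growth_sd_frac >= 0, measurement_sd_mm >= 0,
    focality_mean >= 1, focality_max >= 1,
    baseline_area_mean_mm2 > 0, baseline_area_sd_mm2 > 0,
    prd_halo_mm >= 0, htr_agreement >= 0, htr_agreement <= 1,
    fovea_jitter_mm >= 0, min_seed_sep_mm >= 0, seed_region_mm > 0
  )
  if (!is.na(arm_effect["SHAM"]) && arm_effect[["SHAM"]] != 1) {
    stop("arm_effect['SHAM'] must be 1", call. = FALSE)
  }
  structure(as.list(environment()), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(
    "<cohort_config> n=%s; visits %s; %dx%d px @ %.3g mm; sham growth %.3g mm/yr\n",
    paste(sprintf("%s:%d", names(x$n_per_arm), x$n_per_arm), collapse = " "),
    paste(x$visit_months, collapse = ","), x$grid_px[1], x$grid_px[2],
    x$px_mm, x$sham_sqrt_growth_mm_per_year))
  invisible(x)
}

# --- latent per-eye parameters -------------------------------------------

# Truncated-geometric seed count with given untruncated mean.
.sample_focality <- function(mean_k, max_k) {
  p <- 1 / mean_k
  repeat {
    k <- 1L + rgeom(1L, p)
    if (k <= max_k) return(k)
  }
}

.sample_seed_points <- function(k, center_mm, region_mm, min_sep_mm) {
  pts <- matrix(numeric(0), 0, 2)
  tries <- 0L
  while (nrow(pts) < k) {
    tries <- tries + 1L
    if (tries > 10000L) {
      stop("could not place ", k, " seeds >= ", min_sep_mm, " mm apart",
           call. = FALSE)
    }
    r <- region_mm * sqrt(runif(1))
    a <- runif(1, 0, 2 * pi)
    cand <- center_mm + r * c(cos(a), sin(a))
    if (nrow(pts) == 0L ||
        all(sqrt(rowSums((pts - matrix(cand, nrow(pts), 2,
                                       byrow = TRUE))^2)) >= min_sep_mm)) {
      pts <- rbind(pts, cand)
    }
  }
  unname(pts)
}

# Latent natural-history parameters for every eye, deterministic in the
# root seed and independent of processing order.
.sample_cohort_params <- function(config) {
  arms <- rep(names(config$n_per_arm), times = config$n_per_arm)
  n <- length(arms)
  out <- vector("list", n)
  if (n == 0L) return(out)
  seeds <- .split_seeds(config$rng_seed, n)
  sdlog <- sqrt(log(1 + config$growth_sd_frac^2))
  sh <- (config$baseline_area_mean_mm2 / config$baseline_area_sd_mm2)^2
  rate <- sh / config$baseline_area_mean_mm2
  center <- config$grid_px * config$px_mm / 2
  for (i in seq_len(n)) {
    old <- .save_rng()
    set.seed(seeds[i])
    arm <- arms[i]
    k <- .sample_focality(config$focality_mean, config$focality_max)
    a0 <- min(max(rgamma(1L, shape = sh, rate = rate),
                  config$baseline_area_range_mm2[1]),
              config$baseline_area_range_mm2[2])
    growth <- config$arm_effect[[arm]] * config$sham_sqrt_growth_mm_per_year *
      exp(rnorm(1L, -sdlog^2 / 2, sdlog))
    pts <- .sample_seed_points(k, rev(center), config$seed_region_mm,
                               config$min_seed_sep_mm)
    lat <- if (runif(1) < 0.5) "OD" else "OS"
    # truncated at +-2 SD: emulates QC rejection of gross fovea
    # mislocalisation, and keeps the 6 mm grid on the default raster
    jv <- rnorm(2L * length(config$visit_months), 0, config$fovea_jitter_mm)
    jit <- matrix(pmin(pmax(jv, -2 * config$fovea_jitter_mm),
                       2 * config$fovea_jitter_mm), ncol = 2)
    meas <- rnorm(length(config$visit_months), 0, config$measurement_sd_mm)
    .restore_rng(old)
    out[[i]] <- list(
      eye_id = sprintf("%s%03d", arm, sum(arms[seq_len(i)] == arm)),
      arm = arm, laterality = lat, n_seeds = k,
      baseline_sqrt_area_mm = sqrt(a0),
      growth_mm_per_year = growth,
      seed_xy_mm = pts,        # columns: x (fast axis), y (slow axis)
      fovea_jitter = jit,      # one row per visit: (dx, dy)
      sqrt_meas_noise = meas   # per-visit measurement noise (table path)
    )
  }
  out
}

# --- rendering ------------------------------------------------------------

# Distance (mm) of every truth pixel to the nearest seed point.
.seed_distance_mm <- function(grid_px, px_mm, seed_xy_mm) {
  seedmask <- matrix(1, grid_px[1], grid_px[2])
  rows <- pmin(pmax(round(seed_xy_mm[, 2] / px_mm + 0.5), 1), grid_px[1])
  cols <- pmin(pmax(round(seed_xy_mm[, 1] / px_mm + 0.5), 1), grid_px[2])
  seedmask[cbind(rows, cols)] <- 0
  as.matrix(EBImage::distmap(seedmask)) * px_mm
}

# Smallest sublevel set of the distance map holding exactly `npx` pixels
# (ties broken by pixel index: deterministic).
.grow_to_area <- function(dist_mm, npx) {
  mask <- matrix(FALSE, nrow(dist_mm), ncol(dist_mm))
  if (npx <= 0L) return(mask)
  if (npx >= length(dist_mm)) stop("lesion does not fit in the field")
  mask[order(as.vector(dist_mm))[seq_len(npx)]] <- TRUE
  mask
}

.dilate_mm <- function(mask, halo_mm, px_mm) {
  if (halo_mm <= 0 || !any(mask)) return(mask)
  d <- as.matrix(EBImage::distmap(1 - mask)) * px_mm
  mask | (d <= halo_mm)
}

# Render the three constituent truth rasters of one eye-visit.
.render_truth_maps <- function(dist_mm, target_sqrt_mm, px_mm, prd_halo_mm,
                               htr_agreement) {
  npx <- round(target_sqrt_mm^2 / px_mm^2)
  rpe <- .grow_to_area(dist_mm, npx)
  prd <- .dilate_mm(rpe, prd_halo_mm, px_mm)
  htr <- rpe
  if (htr_agreement < 1 && any(rpe)) {
    bnd <- which(.boundary4(rpe))
    drop <- bnd[runif(length(bnd)) > htr_agreement]
    htr[drop] <- FALSE
  }
  list(RPE_LOSS = rpe, PRD = prd, HTR = htr)
}

# Slice an en-face truth raster into per-B-scan masks: equal-height bands,
# an A-scan is positive iff any truth pixel of its band is positive.
.slice_to_bscans <- function(truth, n_bscans, n_axial_px) {
  h <- nrow(truth)
  breaks <- floor(seq_len(n_bscans) * h / n_bscans)
  starts <- c(1L, head(breaks, -1L) + 1L)
  ax <- max(2L, round(n_axial_px / 4)):min(n_axial_px, round(3 * n_axial_px / 4))
  lapply(seq_len(n_bscans), function(b) {
    rows <- starts[b]:breaks[b]
    pos <- if (length(rows) > 1L) apply(truth[rows, , drop = FALSE], 2, any)
           else truth[rows, ]
    m <- matrix(FALSE, n_axial_px, ncol(truth))
    m[ax, pos] <- TRUE
    m
  })
}

.disc_mask <- function(grid_px, px_mm, center_xy_mm, radius_mm) {
  x <- (seq_len(grid_px[2]) - 0.5) * px_mm
  y <- (seq_len(grid_px[1]) - 0.5) * px_mm
  outer((y - center_xy_mm[2])^2, (x - center_xy_mm[1])^2, `+`) < radius_mm^2
}

# --- the simulator --------------------------------------------------------

#' Simulate a synthetic GA trial cohort
#'
#' For each eye, seed points are sampled, and at each visit the RPE-loss
#' region is grown from the seeds by distance-transform dilation until
#' sqrt(area) equals `baseline + effect x sham growth x t/12` exactly (up to
#' one pixel of area). PRD is the RPE-loss region dilated by
#' `prd_halo_mm`; hypertransmission keeps each RPE-loss boundary pixel with
#' probability `htr_agreement`. The truth rasters are sliced into B-scan
#' masks and wrapped as [segmentation_volume()] groups.
#'
#' @param config A [cohort_config()].
#' @param keep_volumes Keep the rendered volume groups (set `FALSE` to
#'   collect ground truth only, which is much lighter).
#' @param keep_truth_maps Also keep the full-resolution en-face truth
#'   rasters of every eye-visit.
#' @return A `ga_cohort` list with elements `groups` (named
#'   `"<eye>_m<visit>"`), `truth` (see [cohort_truth]), `config`, and
#'   optionally `truth_maps`.
#' @export
simulate_cohort <- function(config, keep_volumes = TRUE,
                            keep_truth_maps = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  eyes <- .sample_cohort_params(config)
  field_mm <- config$grid_px * config$px_mm
  field_area <- prod(field_mm)
  fovea_true <- rev(field_mm) / 2   # (x, y)
  groups <- list()
  truth_maps <- list()
  area_rows <- list()
  visit_rows <- list()
  eye_rows <- list()
  for (ep in eyes) {
    max_sqrt <- ep$baseline_sqrt_area_mm + ep$growth_mm_per_year *
      max(config$visit_months) / 12
    if (max_sqrt^2 > field_area) {
      stop("eye ", ep$eye_id, ": requested lesion area ",
           signif(max_sqrt^2, 4), " mm^2 exceeds the ",
           signif(field_mm[2], 3), "x", signif(field_mm[1], 3), " mm field",
           call. = FALSE)
    }
    dist_mm <- .seed_distance_mm(config$grid_px, config$px_mm, ep$seed_xy_mm)
    eye_rows[[ep$eye_id]] <- data.frame(
      eye_id = ep$eye_id, arm = ep$arm, laterality = ep$laterality,
      n_seeds = ep$n_seeds,
      baseline_sqrt_area_mm = ep$baseline_sqrt_area_mm,
      growth_mm_per_year = ep$growth_mm_per_year
    )
    old <- .save_rng()
    set.seed(.split_seeds(sum(utf8ToInt(ep$eye_id)) + config$rng_seed, 1L))
    for (vi in seq_along(config$visit_months)) {
      t <- config$visit_months[vi]
      target_sqrt <- ep$baseline_sqrt_area_mm + ep$growth_mm_per_year * t / 12
      maps <- .render_truth_maps(dist_mm, target_sqrt, config$px_mm,
                                 config$prd_halo_mm, config$htr_agreement)
      rora <- maps$RPE_LOSS & maps$PRD & maps$HTR
      prd_iso <- maps$PRD & !maps$RPE_LOSS & !maps$HTR
      disc <- .disc_mask(config$grid_px, config$px_mm, fovea_true, 3)
      intact <- disc & !(maps$RPE_LOSS | maps$PRD | maps$HTR)
      px2 <- config$px_mm^2
      areas <- c(
        RPE_LOSS = sum(maps$RPE_LOSS), PRD = sum(maps$PRD),
        HTR = sum(maps$HTR), RORA = sum(rora),
        PRD_ISOLATED = sum(prd_iso), INTACT_MACULA = sum(intact)
      ) * px2
      key <- sprintf("%s_m%02d", ep$eye_id, t)
      area_rows[[key]] <- data.frame(
        eye_id = ep$eye_id, arm = ep$arm, visit_month = t,
        feature = names(areas), area_mm2 = as.numeric(areas),
        row.names = NULL
      )
      fov_rec <- fovea_true + ep$fovea_jitter[vi, ]
      visit_rows[[key]] <- data.frame(
        eye_id = ep$eye_id, visit_month = t,
        focality = .count_components(rora),
        target_sqrt_area_mm = target_sqrt,
        fovea_true_x_mm = fovea_true[1], fovea_true_y_mm = fovea_true[2],
        fovea_rec_x_mm = fov_rec[1], fovea_rec_y_mm = fov_rec[2]
      )
      if (keep_truth_maps) {
        truth_maps[[key]] <- list(RPE_LOSS = maps$RPE_LOSS, PRD = maps$PRD,
                                  HTR = maps$HTR, RORA = rora,
                                  PRD_ISOLATED = prd_iso,
                                  INTACT_MACULA = intact)
      }
      if (keep_volumes) {
        meta <- volume_meta(
          eye_id = ep$eye_id, arm = ep$arm, visit_month = t,
          laterality = ep$laterality, n_bscans = config$n_bscans,
          ascan_spacing_mm = config$px_mm,
          bscan_spacing_mm = field_mm[1] / config$n_bscans,
          fovea_xy_mm = fov_rec, field_extent_mm = rev(field_mm)
        )
        vols <- lapply(maps, .slice_to_bscans, config$n_bscans,
                       config$n_axial_px)
        groups[[key]] <- volume_group(
          segmentation_volume(meta, "RPE_LOSS", vols$RPE_LOSS),
          segmentation_volume(meta, "PRD", vols$PRD),
          segmentation_volume(meta, "HTR", vols$HTR)
        )
      }
    }
    .restore_rng(old)
  }
  truth <- structure(list(
    eyes = .rbind_rows(eye_rows),
    visits = .rbind_rows(visit_rows),
    areas = .rbind_rows(area_rows)
  ), class = "cohort_truth")
  structure(list(groups = groups, truth = truth, config = config,
                 truth_maps = if (keep_truth_maps) truth_maps),
            class = "ga_cohort")
}

#' @export
print.ga_cohort <- function(x, ...) {
  cat(sprintf("<ga_cohort> %d eyes, %d rendered eye-visits\n",
              nrow(x$truth$eyes), length(x$groups)))
  invisible(x)
}

#' Ground truth tables of a simulated cohort
#'
#' `simulate_cohort()` returns a `cohort_truth` object with three data
#' frames: `eyes` (arm, laterality, seed count, baseline sqrt-area, true
#' growth rate), `visits` (true focality, target sqrt-area, true and
#' recorded fovea) and `areas` (true area of all six features per
#' eye-visit, measured on the rendered truth rasters).
#'
#' @name cohort_truth
NULL

#' Analytic growth table without raster rendering
#'
#' Produces the long endpoint table directly from the latent natural
#' history: measured `sqrt(area)` at visit `t` is
#' `baseline + growth x t/12 + e_t` with `e_t ~ N(0, measurement_sd_mm)`
#' emulating segmentation variability. The same per-eye latent draws as
#' [simulate_cohort()] (identical root seed gives identical eyes). Used for
#' statistical calibration studies where rendering rasters would be wasteful.
#'
#' @param config A [cohort_config()].
#' @param feature Feature label for the rows (the latent trajectory is the
#'   RORA lesion).
#' @return A long table as described in [as_long_table()].
#' @export
simulate_growth_table <- function(config, feature = "RORA") {
  stopifnot(inherits(config, "cohort_config"))
  eyes <- .sample_cohort_params(config)
  if (length(eyes) == 0L) {
    return(as_long_table(data.frame(eye_id = character(), arm = character(),
                                    visit_month = integer(),
                                    feature = character(),
                                    area_mm2 = numeric())))
  }
  rows <- lapply(eyes, function(ep) {
    s <- pmax(0, ep$baseline_sqrt_area_mm +
                ep$growth_mm_per_year * config$visit_months / 12 +
                ep$sqrt_meas_noise)
    data.frame(eye_id = ep$eye_id, arm = ep$arm,
               visit_month = config$visit_months, feature = feature,
               area_mm2 = s^2)
  })
  as_long_table(do.call(rbind, rows))
}

# --- on-disk cohort -------------------------------------------------------

#' Write a simulated cohort in the package's on-disk dialect
#'
#' Volumes go to `<acquisition>_<FEATURE>.tif` (+ sidecars), ground truth to
#' three CSV files, the configuration to `config.yaml`, and a
#' `manifest.json` lists every file with its MD5 checksum.
#'
#' @param cohort A `ga_cohort` from [simulate_cohort()].
#' @param out_dir Output directory (created if needed).
#' @param overwrite Overwrite an existing manifest.
#' @return Path to the manifest, invisibly.
#' @export
write_cohort <- function(cohort, out_dir, overwrite = FALSE) {
  stopifnot(inherits(cohort, "ga_cohort"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(out_dir, "manifest.json")
  if (file.exists(manifest_path) && !overwrite) {
    stop("manifest already exists at ", manifest_path,
         " (use overwrite = TRUE)", call. = FALSE)
  }
  files <- character(0)
  for (key in names(cohort$groups)) {
    g <- cohort$groups[[key]]
    for (f in .CONSTITUENTS) {
      p <- file.path(out_dir, sprintf("%s_%s.tif", key, f))
      write_volume(g[[f]], p)
      files <- c(files, p, .sidecar_path(p))
    }
  }
  tr <- cohort$truth
  for (nm in c("eyes", "visits", "areas")) {
    p <- file.path(out_dir, sprintf("truth_%s.csv", nm))
    write.csv(tr[[nm]], p, row.names = FALSE)
    files <- c(files, p)
  }
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(lapply(unclass(cohort$config), function(v)
    if (is.numeric(v) || is.character(v)) v else as.character(v)), cfg_path)
  files <- c(files, cfg_path)
  entries <- data.frame(
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    stringsAsFactors = FALSE
  )
  jsonlite::write_json(
    list(n_volumes = length(cohort$groups) * length(.CONSTITUENTS),
         files = entries),
    manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(manifest_path)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory containing `manifest.json`.
#' @param verify Recompute and check every file checksum.
#' @return A `ga_cohort` (without truth rasters).
#' @export
read_cohort <- function(dir, verify = TRUE) {
  manifest_path <- file.path(dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    stop("no manifest.json in ", dir, call. = FALSE)
  }
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  if (verify && length(man$files)) {
    paths <- file.path(dir, man$files$file)
    missing <- !file.exists(paths)
    if (any(missing)) {
      stop("manifest lists missing files: ",
           paste(man$files$file[missing], collapse = ", "), call. = FALSE)
    }
    got <- unname(tools::md5sum(paths))
    bad <- got != man$files$md5
    if (any(bad)) {
      stop("checksum mismatch for: ",
           paste(man$files$file[bad], collapse = ", "), call. = FALSE)
    }
  }
  tifs <- list.files(dir, pattern = "_(RPE_LOSS|PRD|HTR)\\.tif$",
                     full.names = TRUE)
  keys <- unique(sub("_(RPE_LOSS|PRD|HTR)\\.tif$", "", basename(tifs)))
  groups <- lapply(keys, function(key) {
    vols <- lapply(.CONSTITUENTS, function(f) {
      read_volume(file.path(dir, sprintf("%s_%s.tif", key, f)))
    })
    volume_group(vols[[1]], vols[[2]], vols[[3]])
  })
  names(groups) <- keys
  truth <- structure(lapply(c(eyes = "eyes", visits = "visits",
                              areas = "areas"), function(nm) {
    p <- file.path(dir, sprintf("truth_%s.csv", nm))
    if (file.exists(p)) read.csv(p) else data.frame()
  }), class = "cohort_truth")
  structure(list(groups = groups, truth = truth, config = NULL,
                 truth_maps = NULL), class = "ga_cohort")
}
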