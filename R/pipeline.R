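# End-to-end quantification: volumes -> en-face maps -> composites ->
# areas, ETDRS region metrics and lesion morphometrics.
#
# Feature areas in the long table are computed at the native en-face
# resolution (anisotropic B-scan grid) for the constituents and the
# pixelwise composites; the intact macula needs the ETDRS disc and is
# measured on the isotropic raster.

#' Quantify one eye-visit volume group
#'
#' @param group A [volume_group()].
#' @param px_iso Isotropic pitch for ETDRS/morphology rasters, mm.
#' @param min_lesion_mm2 Noise-speck threshold for [lesion_morphology()].
#' @return A list with `areas` (feature areas, mm^2), `regions`
#'   (per-region data frame from [region_metrics()]), `morphology`
#'   (RORA [lesion_morphology()]), and the isotropic `maps`.
#' @export
quantify_eye_visit <- function(group, px_iso = 0.01, min_lesion_mm2 = 0.05) {
  ef <- project_to_enface(group)
  # native-grid composites (pixelwise; no resampling in the primary areas)
  native <- ef
  native$maps$RORA <- ef$maps$RPE_LOSS & ef$maps$PRD & ef$maps$HTR
  native$maps$PRD_ISOLATED <- ef$maps$PRD & !ef$maps$RPE_LOSS & !ef$maps$HTR
  iso <- enface_resample(ef, px_iso)
  grid <- build_etdrs_grid(dim(iso$maps[[1]]), px_iso, iso$fovea_px,
                           iso$laterality)
  comp <- derive_composites(iso, grid)
  areas <- c(
    vapply(c(.CONSTITUENTS, "RORA", "PRD_ISOLATED"), function(f)
      feature_area(native, feature = f), 0),
    INTACT_MACULA = feature_area(comp, feature = "INTACT_MACULA")
  )
  list(
    eye_id = ef$eye_id, visit_month = ef$visit_month, areas = areas,
    regions = region_metrics(comp, grid),
    morphology = lesion_morphology(comp, min_lesion_mm2 = min_lesion_mm2),
    maps = comp
  )
}

#' Quantify a whole cohort
#'
#' Runs [quantify_eye_visit()] on every rendered eye-visit of a
#' [simulate_cohort()] result (or a cohort read with [read_cohort()]) and
#' assembles the analysis tables.
#'
#' @param cohort A `ga_cohort` with rendered volume groups.
#' @inheritParams quantify_eye_visit
#' @return A list with `long_table` (endpoint table, see
#'   [as_long_table()]), `regions` (per eye-visit region metrics) and
#'   `morphology` (per eye-visit focality/perimeter).
#' @export
quantify_cohort <- function(cohort, px_iso = 0.01, min_lesion_mm2 = 0.05) {
  stopifnot(inherits(cohort, "ga_cohort"))
  if (length(cohort$groups) == 0L) {
    stop("cohort has no rendered volume groups", call. = FALSE)
  }
  arm_of <- function(g) g$RPE_LOSS$meta$arm
  area_rows <- list(); region_rows <- list(); morph_rows <- list()
  for (key in names(cohort$groups)) {
    g <- cohort$groups[[key]]
    q <- quantify_eye_visit(g, px_iso, min_lesion_mm2)
    area_rows[[key]] <- data.frame(
      eye_id = q$eye_id, arm = arm_of(g), visit_month = q$visit_month,
      feature = names(q$areas), area_mm2 = as.numeric(q$areas),
      row.names = NULL)
    rg <- q$regions
    rg$eye_id <- q$eye_id; rg$visit_month <- q$visit_month
    region_rows[[key]] <- rg
    morph_rows[[key]] <- data.frame(
      eye_id = q$eye_id, arm = arm_of(g), visit_month = q$visit_month,
      focality = q$morphology$focality,
      perimeter_mm = q$morphology$perimeter_mm,
      total_area_mm2 = q$morphology$total_area_mm2)
  }
  list(long_table = as_long_table(.rbind_rows(area_rows)),
       regions = .rbind_rows(region_rows),
       morphology = .rbind_rows(morph_rows))
}
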