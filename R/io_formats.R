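# Reading and writing segmentation volumes: multi-page TIFF (one page per
# B-scan, 8-bit 0/255) plus a JSON sidecar `<stem>.meta.json` holding the
# acquisition metadata.
#
# Coordinate convention (used everywhere downstream): raster row 0 of the
# en-face plane is the superior-most B-scan; within a B-scan, column 0 is
# the temporal edge for OD and the nasal edge for OS. Physical positions in
# mm are measured from the volume's superior-temporal corner; fovea_xy_mm is
# (x = fast axis, y = slow axis) in that frame.

#' Construct acquisition metadata for a segmentation volume
#'
#' @param eye_id Opaque eye identifier.
#' @param arm Treatment arm, one of `"PM"`, `"PEOM"`, `"SHAM"`.
#' @param visit_month Integer visit month, `>= 0`.
#' @param laterality `"OD"` (right) or `"OS"` (left).
#' @param n_bscans Number of B-scans in the volume. Volumes with fewer than
#'   25 B-scans are retained but flagged as not accepted for analysis
#'   (`accepted = FALSE`), mirroring the eligibility rule of a 6x6x2 mm
#'   macular cube with at least 25 B-scans.
#' @param ascan_spacing_mm Lateral spacing between A-scans (fast axis), mm.
#' @param bscan_spacing_mm Spacing between B-scans (slow axis), mm.
#' @param fovea_xy_mm Fovea position `c(x, y)` in mm, volume coordinates.
#' @param field_extent_mm En-face field extent `c(fast, slow)` in mm
#'   (nominally `c(6, 6)`).
#' @param acquisition_id Identifier of the acquisition; used as the
#'   deterministic tie-break when several same-size volumes exist for one
#'   eye-visit. Defaults to `"<eye_id>_m<visit_month>"`.
#'
#' @return A `volume_meta` object (named list).
#' @export
volume_meta <- function(eye_id, arm, visit_month, laterality, n_bscans,
                        ascan_spacing_mm, bscan_spacing_mm, fovea_xy_mm,
                        field_extent_mm = c(6, 6), acquisition_id = NULL) {
  arm <- match.arg(arm, .ARMS)
  laterality <- match.arg(laterality, .LATERALITIES)
  visit_month <- as.integer(visit_month)
  n_bscans <- as.integer(n_bscans)
  stopifnot(
    length(eye_id) == 1L, nzchar(eye_id),
    visit_month >= 0L, n_bscans >= 1L,
    ascan_spacing_mm > 0, bscan_spacing_mm > 0,
    length(fovea_xy_mm) == 2L, is.finite(fovea_xy_mm),
    length(field_extent_mm) == 2L, all(field_extent_mm > 0)
  )
  slow_span <- (n_bscans - 1L) * bscan_spacing_mm
  if (n_bscans > 1L &&
      abs(slow_span - field_extent_mm[2]) > 0.1 * field_extent_mm[2] &&
      abs(n_bscans * bscan_spacing_mm - field_extent_mm[2]) >
        0.1 * field_extent_mm[2]) {
    stop("(n_bscans - 1) * bscan_spacing_mm = ", signif(slow_span, 4),
         " mm is not within 10% of the slow-axis field extent ",
         field_extent_mm[2], " mm", call. = FALSE)
  }
  structure(list(
    eye_id = as.character(eye_id), arm = arm, visit_month = visit_month,
    laterality = laterality, n_bscans = n_bscans,
    ascan_spacing_mm = ascan_spacing_mm, bscan_spacing_mm = bscan_spacing_mm,
    fovea_xy_mm = as.numeric(fovea_xy_mm),
    field_extent_mm = as.numeric(field_extent_mm),
    acquisition_id = acquisition_id %||%
      sprintf("%s_m%02d", eye_id, visit_month),
    accepted = n_bscans >= 25L
  ), class = "volume_meta")
}

#' Construct a segmentation volume for one feature of one eye-visit
#'
#' @param meta A [volume_meta()] object.
#' @param feature One of `"RPE_LOSS"`, `"PRD"`, `"HTR"`.
#' @param masks List of binary matrices (axial x lateral), one per B-scan,
#'   ordered superior to inferior. All must share one shape; the stack length
#'   must equal `meta$n_bscans`.
#'
#' @return A `segmentation_volume` object.
#' @export
segmentation_volume <- function(meta, feature, masks) {
  stopifnot(inherits(meta, "volume_meta"))
  feature <- match.arg(feature, .CONSTITUENTS)
  if (length(masks) != meta$n_bscans) {
    stop("mask stack has ", length(masks), " B-scans but meta declares ",
         meta$n_bscans, call. = FALSE)
  }
  masks <- lapply(seq_along(masks), function(i) {
    .as_binary_matrix(masks[[i]], sprintf("B-scan %d", i))
  })
  if (length(masks)) {
    d0 <- dim(masks[[1]])
    for (i in seq_along(masks)) .check_same_dim(masks[[i]], masks[[1]],
                                                sprintf("B-scans 1 and %d", i))
    if (d0[2] < 1L) stop("B-scans must have at least one A-scan column")
  }
  structure(list(meta = meta, feature = feature, masks = masks),
            class = "segmentation_volume")
}

#' @export
print.segmentation_volume <- function(x, ...) {
  cat(sprintf("<segmentation_volume> %s %s month %d: %d B-scans of %s px\n",
              x$meta$eye_id, x$feature, x$meta$visit_month, x$meta$n_bscans,
              paste(dim(x$masks[[1]]), collapse = "x")))
  invisible(x)
}

.sidecar_path <- function(path) {
  paste0(sub("\\.tiff?$", "", path, ignore.case = TRUE), ".meta.json")
}

#' Write a segmentation volume as multi-page TIFF plus JSON sidecar
#'
#' Pages are 8-bit with values 0/255; the sidecar `<stem>.meta.json` carries
#' the [volume_meta()] fields and the feature code.
#'
#' @param vol A [segmentation_volume()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "segmentation_volume"))
  pages <- lapply(vol$masks, function(m) {
    storage.mode(m) <- "double"
    m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "deflate")
  meta <- unclass(vol$meta)
  meta$feature <- vol$feature
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a segmentation volume written by [write_volume()]
#'
#' @param path Path to the multi-page TIFF; the sidecar
#'   `<stem>.meta.json` must exist alongside it.
#' @return A [segmentation_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sidecar <- .sidecar_path(path)
  if (!file.exists(sidecar)) {
    stop("missing metadata sidecar: ", sidecar, call. = FALSE)
  }
  meta_raw <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  feature <- meta_raw$feature
  if (is.null(feature)) stop("sidecar lacks a feature field: ", sidecar)
  meta <- volume_meta(
    eye_id = meta_raw$eye_id, arm = meta_raw$arm,
    visit_month = meta_raw$visit_month, laterality = meta_raw$laterality,
    n_bscans = meta_raw$n_bscans,
    ascan_spacing_mm = meta_raw$ascan_spacing_mm,
    bscan_spacing_mm = meta_raw$bscan_spacing_mm,
    fovea_xy_mm = meta_raw$fovea_xy_mm,
    field_extent_mm = meta_raw$field_extent_mm,
    acquisition_id = meta_raw$acquisition_id
  )
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != meta$n_bscans) {
    stop("page count mismatch in ", path, ": TIFF has ", length(pages),
         " pages, sidecar declares n_bscans = ", meta$n_bscans, call. = FALSE)
  }
  masks <- lapply(seq_along(pages), function(i) {
    p <- pages[[i]]
    if (length(dim(p)) == 3L) p <- p[, , 1]
    v <- unique(as.vector(p))
    if (!all(v %in% c(0, 1))) {
      stop("non-binary pixel values on page ", i, " of ", path, call. = FALSE)
    }
    p > 0.5
  })
  segmentation_volume(meta, feature, masks)
}

#' Bundle the three feature volumes of one acquisition
#'
#' @param rpe_loss,prd,htr [segmentation_volume()] objects for the RPE-loss,
#'   PRD and hypertransmission features of a single acquisition. All three
#'   must share the acquisition metadata.
#' @return A named `volume_group` list.
#' @export
volume_group <- function(rpe_loss, prd, htr) {
  vols <- list(RPE_LOSS = rpe_loss, PRD = prd, HTR = htr)
  for (f in .CONSTITUENTS) {
    v <- vols[[f]]
    stopifnot(inherits(v, "segmentation_volume"))
    if (v$feature != f) {
      stop("volume passed as ", f, " is segmented for ", v$feature,
           call. = FALSE)
    }
  }
  .check_group_meta(vols)
  structure(vols, class = "volume_group")
}

.check_group_meta <- function(vols) {
  ref <- unclass(vols[[1]]$meta)
  for (f in names(vols)[-1]) {
    m <- unclass(vols[[f]]$meta)
    for (fld in names(ref)) {
      if (!isTRUE(all.equal(ref[[fld]], m[[fld]]))) {
        stop("feature volumes disagree on metadata field '", fld, "' (",
             names(vols)[1], " vs ", f, ")", call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

#' Select the analysis volume among repeat acquisitions of one eye-visit
#'
#' When an eye-visit has several acquisitions, the group with the highest
#' number of B-scans is analysed. Groups with fewer than 25 B-scans are
#' excluded (and reported via a message). Ties on `n_bscans` are broken by
#' the lexicographically smallest acquisition identifier, making the choice
#' independent of input order.
#'
#' @param candidates List of `volume_group` objects for one eye-visit.
#' @return The selected `volume_group`.
#' @export
select_analysis_volume <- function(candidates) {
  if (length(candidates) == 0L) {
    stop("no candidate volume groups supplied", call. = FALSE)
  }
  stopifnot(all(vapply(candidates, inherits, TRUE, "volume_group")))
  nb <- vapply(candidates, function(g) g$RPE_LOSS$meta$n_bscans, 1L)
  acq <- vapply(candidates, function(g) g$RPE_LOSS$meta$acquisition_id, "")
  ok <- nb >= 25L
  if (any(!ok)) {
    message("excluding ", sum(!ok), " volume group(s) with < 25 B-scans: ",
            paste(acq[!ok], collapse = ", "))
  }
  if (!any(ok)) {
    stop("all candidate groups have fewer than 25 B-scans", call. = FALSE)
  }
  keep <- which(ok)
  best <- keep[nb[keep] == max(nb[keep])]
  best <- best[order(acq[best])][1]
  candidates[[best]]
}
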