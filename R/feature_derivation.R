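# Per-A-scan en-face reduction and composite-feature set algebra.
#
# RORA            = RPE_LOSS & PRD & HTR
# PRD_ISOLATED    = PRD & !RPE_LOSS & !HTR
# INTACT_MACULA   = ETDRS 6 mm disc & none of the three constituents
#
# The en-face native resolution is the B-scan grid (rows = B-scans, columns
# = A-scans); areas on that grid use the anisotropic pixel spacing directly,
# avoiding interpolation in the primary endpoint. Isotropic resampling
# (nearest-neighbour) is applied only where morphology or ETDRS masks
# require it.

#' Construct an en-face map set
#'
#' @param maps Named list of binary matrices sharing one shape; names from
#'   [ga_features()].
#' @param px_spacing_mm Pixel spacing `c(row, col)` in mm (row = slow/B-scan
#'   axis, col = fast/A-scan axis).
#' @param fovea_px Fovea position `c(row, col)` in 1-based pixel
#'   coordinates (pixel centres at integers).
#' @param eye_id,visit_month,laterality Identifying metadata.
#' @return An `enface_maps` object.
#' @export
enface_maps <- function(maps, px_spacing_mm, fovea_px, eye_id = "eye",
                        visit_month = 0L, laterality = "OD") {
  stopifnot(is.list(maps), length(maps) >= 1,
            all(names(maps) %in% .ALL_FEATURES),
            length(px_spacing_mm) == 2, all(px_spacing_mm > 0),
            length(fovea_px) == 2)
  maps <- lapply(maps, .as_binary_matrix)
  for (i in seq_along(maps)) .check_same_dim(maps[[i]], maps[[1]])
  structure(list(maps = maps, px_spacing_mm = as.numeric(px_spacing_mm),
                 fovea_px = as.numeric(fovea_px),
                 eye_id = eye_id, visit_month = as.integer(visit_month),
                 laterality = match.arg(laterality, .LATERALITIES)),
            class = "enface_maps")
}

#' @export
print.enface_maps <- function(x, ...) {
  cat(sprintf("<enface_maps> %s month %d: %s px @ %.4gx%.4g mm [%s]\n",
              x$eye_id, x$visit_month,
              paste(dim(x$maps[[1]]), collapse = "x"),
              x$px_spacing_mm[1], x$px_spacing_mm[2],
              paste(names(x$maps), collapse = ", ")))
  invisible(x)
}

#' Project a volume group to en-face constituent maps
#'
#' One en-face row per B-scan, one column per A-scan; an en-face pixel is
#' true iff any voxel of that A-scan's mask column is true. Row spacing is
#' the B-scan spacing, column spacing the A-scan spacing.
#'
#' @param group A [volume_group()] whose three volumes share metadata.
#' @return An `enface_maps` set with the three constituent features.
#' @export
project_to_enface <- function(group) {
  stopifnot(inherits(group, "volume_group"))
  .check_group_meta(group)
  meta <- group$RPE_LOSS$meta
  maps <- lapply(group, function(vol) {
    do.call(rbind, lapply(vol$masks, function(m) {
      .colAny(m)
    }))
  })
  fovea_px <- c(meta$fovea_xy_mm[2] / meta$bscan_spacing_mm + 0.5,
                meta$fovea_xy_mm[1] / meta$ascan_spacing_mm + 0.5)
  enface_maps(maps,
              px_spacing_mm = c(meta$bscan_spacing_mm, meta$ascan_spacing_mm),
              fovea_px = fovea_px, eye_id = meta$eye_id,
              visit_month = meta$visit_month, laterality = meta$laterality)
}

# any() per column, vectorised
.colAny <- function(m) colSums(m) > 0L

#' Resample an en-face map set to an isotropic raster
#'
#' Nearest-neighbour resampling, used before ETDRS mask construction and
#' lesion morphology. Each output pixel takes the value of the source pixel
#' whose band contains its centre, so per-band areas are preserved up to
#' boundary rounding.
#'
#' @param maps An `enface_maps` set.
#' @param px_mm Target isotropic pixel pitch in mm.
#' @return A resampled `enface_maps` set.
#' @export
enface_resample <- function(maps, px_mm = 0.01) {
  stopifnot(inherits(maps, "enface_maps"), px_mm > 0)
  d <- dim(maps$maps[[1]])
  extent <- d * maps$px_spacing_mm
  out_dim <- pmax(1L, round(extent / px_mm))
  src_row <- pmin(d[1], pmax(1L, ceiling(
    ((seq_len(out_dim[1]) - 0.5) * px_mm) / maps$px_spacing_mm[1])))
  src_col <- pmin(d[2], pmax(1L, ceiling(
    ((seq_len(out_dim[2]) - 0.5) * px_mm) / maps$px_spacing_mm[2])))
  new_maps <- lapply(maps$maps, function(m) m[src_row, src_col, drop = FALSE])
  fov_mm <- (maps$fovea_px - 0.5) * maps$px_spacing_mm
  enface_maps(new_maps, px_spacing_mm = c(px_mm, px_mm),
              fovea_px = fov_mm / px_mm + 0.5, eye_id = maps$eye_id,
              visit_month = maps$visit_month, laterality = maps$laterality)
}

#' Derive composite feature maps from the constituents
#'
#' @param constituents An `enface_maps` set holding `RPE_LOSS`, `PRD` and
#'   `HTR`, on the same raster as `grid`.
#' @param grid An [build_etdrs_grid()] result; its 6 mm disc defines the
#'   support of the intact macula.
#' @return The input set extended with `RORA`, `PRD_ISOLATED` and
#'   `INTACT_MACULA`.
#' @export
derive_composites <- function(constituents, grid) {
  stopifnot(inherits(constituents, "enface_maps"),
            inherits(grid, "etdrs_grid"))
  m <- constituents$maps
  if (!all(.CONSTITUENTS %in% names(m))) {
    stop("constituent maps must include ",
         paste(.CONSTITUENTS, collapse = ", "), call. = FALSE)
  }
  .check_same_dim(m$RPE_LOSS, grid$disc_mask, "feature map and ETDRS grid")
  out <- constituents
  out$maps$RORA <- m$RPE_LOSS & m$PRD & m$HTR
  out$maps$PRD_ISOLATED <- m$PRD & !m$RPE_LOSS & !m$HTR
  out$maps$INTACT_MACULA <- grid$disc_mask & !(m$RPE_LOSS | m$PRD | m$HTR)
  out
}

#' Area of a binary en-face feature map
#'
#' @param map Binary matrix, or an `enface_maps` set (then `feature`
#'   selects the map and the set's spacing is used).
#' @param px_spacing_mm Pixel spacing `c(row, col)` in mm (scalar accepted
#'   for isotropic rasters).
#' @param feature Feature name when `map` is an `enface_maps` set.
#' @return Area in mm^2.
#' @export
feature_area <- function(map, px_spacing_mm = NULL, feature = NULL) {
  if (inherits(map, "enface_maps")) {
    px_spacing_mm <- map$px_spacing_mm
    map <- map$maps[[feature %||% stop("feature required")]]
  }
  stopifnot(!is.null(px_spacing_mm))
  if (length(px_spacing_mm) == 1L) px_spacing_mm <- rep(px_spacing_mm, 2)
  map <- .as_binary_matrix(map)
  sum(map) * prod(px_spacing_mm)
}
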