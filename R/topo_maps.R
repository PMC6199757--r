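#' Topographic thickness map
#'
#' A masked 2-D grid of layer thickness (voxel units) over the lateral scan
#' field, for one of the three layers: total retina (`TR` = BM - ILM),
#' neurosensory retina (`NSR` = RPE - ILM) or RPE-drusen complex
#' (`RPEDC` = BM - RPE).
#'
#' @param values numeric matrix of thickness (voxels), finite and >= 0
#'   wherever `mask` is `TRUE`.
#' @param layer one of `"TR"`, `"NSR"`, `"RPEDC"`.
#' @param spacing_x_mm,spacing_y_mm,fovea_xy,case_id,label geometry and
#'   identity, as in [layer_boundaries()].
#' @param mask logical validity matrix, same shape as `values`.
#' @return An object of class `thickness_map`.
#' @export
thickness_map <- function(values, layer, spacing_x_mm, spacing_y_mm,
                          fovea_xy, case_id = "case", label = "UNKNOWN",
                          mask = NULL) {
  values <- as.matrix(values)
  layer <- match.arg(layer, c("TR", "NSR", "RPEDC"))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(values), ncol(values))
  stopifnot(identical(dim(mask), dim(values)))
  v <- values[mask]
  if (length(v) && (any(!is.finite(v)) || any(v < 0)))
    stop(sprintf("negative or non-finite thickness inside the %s mask", layer),
         call. = FALSE)
  structure(list(values = values, mask = mask, layer = layer,
                 spacing_x_mm = spacing_x_mm, spacing_y_mm = spacing_y_mm,
                 fovea_xy = as.numeric(fovea_xy),
                 case_id = as.character(case_id), label = label),
            class = "thickness_map")
}

#' @export
print.thickness_map <- function(x, ...) {
  v <- x$values[x$mask]
  cat(sprintf("%s thickness map '%s' [%s]: %d x %d px, %d valid\n",
              x$layer, x$case_id, x$label, nrow(x$values), ncol(x$values),
              sum(x$mask)))
  if (length(v))
    cat(sprintf("  thickness (voxels): min %.2f / median %.2f / max %.2f\n",
                min(v), stats::median(v), max(v)))
  invisible(x)
}

#' Compute the three topographic thickness maps of a case
#'
#' Elementwise boundary subtraction: total retina `TR = b_bm - b_ilm`,
#' neurosensory retina `NSR = b_rpe - b_ilm`, RPE-drusen complex
#' `RPEDC = b_bm - b_rpe`.  Exact on integer inputs; `TR = NSR + RPEDC`
#' holds at every pixel by construction.  Masks start all-true.
#'
#' @param case a [layer_boundaries] object.
#' @return A named list of three [thickness_map] objects: `TR`, `NSR`,
#'   `RPEDC`.
#' @export
compute_thickness_maps <- function(case) {
  stopifnot(inherits(case, "layer_boundaries"))
  mk <- function(v, layer)
    thickness_map(v, layer, case$spacing_x_mm, case$spacing_y_mm,
                  case$fovea_xy, case$case_id, case$label)
  list(TR    = mk(case$b_bm  - case$b_ilm, "TR"),
       NSR   = mk(case$b_rpe - case$b_ilm, "NSR"),
       RPEDC = mk(case$b_bm  - case$b_rpe, "RPEDC"))
}

#' Restrict a map to a fovea-centred region of interest
#'
#' Masks out pixels outside a disc of physical radius `radius_mm` around
#' the fovea.  The disc is defined in millimetres, so on an anisotropic
#' lateral grid it is an ellipse in pixel indices.  Values are untouched;
#' the operation is idempotent and only ever shrinks the mask.
#'
#' @param map a [thickness_map] or [enface_map].
#' @param radius_mm positive ROI radius in millimetres.
#' @return The map with an updated mask.
#' @export
apply_roi <- function(map, radius_mm) {
  stopifnot(inherits(map, c("thickness_map", "enface_map")), radius_mm > 0)
  nx <- nrow(map$values); ny <- ncol(map$values)
  dx <- (seq_len(nx) - map$fovea_xy[1]) * map$spacing_x_mm
  dy <- (seq_len(ny) - map$fovea_xy[2]) * map$spacing_y_mm
  inside <- outer(dx^2, dy^2, `+`) <= radius_mm^2
  new_mask <- map$mask & inside
  if (sum(new_mask) < 2)
    stop(sprintf("ROI radius %.3f mm leaves fewer than 2 valid pixels",
                 radius_mm), call. = FALSE)
  map$mask <- new_mask
  map
}
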