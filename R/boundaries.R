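#' Segmented SD-OCT layer boundary surfaces
#'
#' Container for the three expert-reviewed boundary surfaces of a single eye:
#' the inner limiting membrane (ILM), the RPE border and Bruch's membrane
#' (BM).  Each surface is a matrix of axial depths (voxel units, fractional
#' values allowed) over the lateral A-scan x B-scan grid; axial index
#' increases with depth, so at every lateral position ILM <= RPE <= BM.
#'
#' @param b_ilm,b_rpe,b_bm numeric matrices of axial depth, all of dimension
#'   `n_ascan x n_bscan` (rows index the A-scan/x axis, columns the B-scan/y
#'   axis).
#' @param n_axial axial extent of the source volume in voxels; all finite
#'   depths must lie in `[0, n_axial)`.
#' @param spacing_x_mm,spacing_y_mm lateral sampling pitch in millimetres per
#'   A-scan and per B-scan.
#' @param fovea_xy length-2 vector, lateral pixel coordinates (x, y) of the
#'   fovea centre (1-based, may be fractional), inside the grid.
#' @param case_id opaque case identifier.
#' @param label class label: `"AMD"`, `"CONTROL"` or `"UNKNOWN"`.
#' @param repair if `TRUE`, clamp `b_rpe` into `[b_ilm, b_bm]` instead of
#'   failing on boundary-order violations; the number of repaired pixels is
#'   stored in attribute `"n_repaired"` and reported with a warning.
#'
#' @return An object of class `layer_boundaries`.
#' @export
layer_boundaries <- function(b_ilm, b_rpe, b_bm, n_axial,
                             spacing_x_mm, spacing_y_mm, fovea_xy,
                             case_id = "case", label = "UNKNOWN",
                             repair = FALSE) {
  b_ilm <- as.matrix(b_ilm); b_rpe <- as.matrix(b_rpe); b_bm <- as.matrix(b_bm)
  if (!identical(dim(b_ilm), dim(b_rpe)) || !identical(dim(b_ilm), dim(b_bm)))
    stop("boundary grids must share one lateral shape", call. = FALSE)
  label <- match.arg(label, c("AMD", "CONTROL", "UNKNOWN"))
  n_axial <- as.integer(n_axial)
  stopifnot(n_axial >= 1, spacing_x_mm > 0, spacing_y_mm > 0,
            length(fovea_xy) == 2)

  n_repaired <- 0L
  bad <- (b_rpe < b_ilm) | (b_rpe > b_bm)
  bad[is.na(bad)] <- FALSE
  if (any(bad)) {
    if (repair) {
      b_rpe <- pmin(pmax(b_rpe, b_ilm), b_bm)
      n_repaired <- sum(bad)
      warning(sprintf("clamped b_rpe into [b_ilm, b_bm] at %d pixel(s)",
                      n_repaired), call. = FALSE)
    } else {
      stop(sprintf("boundary order violated (b_ilm <= b_rpe <= b_bm) at %d pixel(s)",
                   sum(bad)), call. = FALSE)
    }
  }
  if (any(b_bm < b_ilm, na.rm = TRUE))
    stop("boundary order violated: b_bm < b_ilm", call. = FALSE)

  depths <- c(b_ilm, b_rpe, b_bm)
  fin <- depths[is.finite(depths)]
  if (length(fin) && (min(fin) < 0 || max(fin) >= n_axial))
    stop(sprintf("finite depths must lie in [0, n_axial = %d)", n_axial),
         call. = FALSE)
  if (fovea_xy[1] < 1 || fovea_xy[1] > nrow(b_ilm) ||
      fovea_xy[2] < 1 || fovea_xy[2] > ncol(b_ilm))
    stop("fovea_xy must lie inside the lateral grid", call. = FALSE)

  structure(
    list(b_ilm = b_ilm, b_rpe = b_rpe, b_bm = b_bm,
         n_ascan = nrow(b_ilm), n_bscan = ncol(b_ilm), n_axial = n_axial,
         spacing_x_mm = spacing_x_mm, spacing_y_mm = spacing_y_mm,
         fovea_xy = as.numeric(fovea_xy),
         case_id = as.character(case_id), label = label),
    class = "layer_boundaries", n_repaired = n_repaired)
}

#' @export
print.layer_boundaries <- function(x, ...) {
  cat(sprintf("SD-OCT layer boundaries '%s' [%s]\n", x$case_id, x$label))
  cat(sprintf("  lateral grid : %d x %d (A-scan x B-scan), axial %d voxels\n",
              x$n_ascan, x$n_bscan, x$n_axial))
  cat(sprintf("  spacing      : %.4f x %.4f mm, fovea at (%.1f, %.1f)\n",
              x$spacing_x_mm, x$spacing_y_mm, x$fovea_xy[1], x$fovea_xy[2]))
  invisible(x)
}

#' SD-OCT reflectance volume
#'
#' Nonnegative reflectance intensities indexed `(x = A-scan, z = axial,
#' y = B-scan)`, matching the lateral geometry of a [layer_boundaries] case.
#'
#' @param reflectance 3-D array, dimension `n_ascan x n_axial x n_bscan`.
#' @param case the paired [layer_boundaries] object.
#' @return An object of class `oct_volume`.
#' @export
oct_volume <- function(reflectance, case) {
  stopifnot(inherits(case, "layer_boundaries"))
  d <- dim(reflectance)
  if (length(d) != 3 ||
      d[1] != case$n_ascan || d[2] != case$n_axial || d[3] != case$n_bscan)
    stop(sprintf("reflectance must be %d x %d x %d (x, z, y)",
                 case$n_ascan, case$n_axial, case$n_bscan), call. = FALSE)
  if (!all(is.finite(reflectance)) || any(reflectance < 0))
    stop("reflectance intensities must be finite and >= 0", call. = FALSE)
  structure(list(reflectance = reflectance,
                 n_ascan = case$n_ascan, n_axial = case$n_axial,
                 n_bscan = case$n_bscan,
                 spacing_x_mm = case$spacing_x_mm,
                 spacing_y_mm = case$spacing_y_mm,
                 fovea_xy = case$fovea_xy, case_id = case$case_id),
            class = "oct_volume")
}

#' @export
print.oct_volume <- function(x, ...) {
  cat(sprintf("SD-OCT volume '%s': %d x %d x %d voxels (x, z, y)\n",
              x$case_id, x$n_ascan, x$n_axial, x$n_bscan))
  invisible(x)
}
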