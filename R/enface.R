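#' En-face reflectance map
#'
#' 2-D projection of volume reflectance sampled along the RPE border,
#' averaged over an axial half-window of `d` voxels.
#'
#' @param values numeric matrix of mean reflectance (finite, >= 0 inside
#'   the mask).
#' @param d integer axial half-window (voxels, >= 0).
#' @inheritParams thickness_map
#' @return An object of class `enface_map`.
#' @export
enface_map <- function(values, d, spacing_x_mm, spacing_y_mm, fovea_xy,
                       case_id = "case", label = "UNKNOWN", mask = NULL) {
  values <- as.matrix(values)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(values), ncol(values))
  stopifnot(identical(dim(mask), dim(values)), d >= 0)
  v <- values[mask]
  if (length(v) && (any(!is.finite(v)) || any(v < 0)))
    stop("negative or non-finite reflectance inside the mask", call. = FALSE)
  structure(list(values = values, mask = mask, d = as.integer(d),
                 layer = "ENFACE",
                 spacing_x_mm = spacing_x_mm, spacing_y_mm = spacing_y_mm,
                 fovea_xy = as.numeric(fovea_xy),
                 case_id = as.character(case_id), label = label),
            class = "enface_map")
}

#' @export
print.enface_map <- function(x, ...) {
  cat(sprintf("En-face RPE map '%s' [%s]: %d x %d px, d = %d, %d valid\n",
              x$case_id, x$label, nrow(x$values), ncol(x$values), x$d,
              sum(x$mask)))
  invisible(x)
}

#' Reconstruct the en-face reflectance projection along the RPE border
#'
#' At each lateral position the boundary depth is rounded (half-to-even) to
#' a voxel index and the reflectance is averaged over the axial window
#' `[z - d, z + d]`.  Windows are clipped at the volume edges, so the mean
#' shrinks there rather than producing missing pixels; with
#' `strict = TRUE` clipped pixels are masked out instead.  Pixels with a
#' non-finite boundary are always masked.
#'
#' @param volume an [oct_volume].
#' @param b_rpe RPE border depth matrix (defaults expected from the paired
#'   [layer_boundaries]); lateral shape must match the volume.
#' @param d integer axial half-window, `0 <= d < n_axial`.
#' @param strict mask pixels whose window was clipped at a volume edge.
#' @param label,case_id identity fields for the resulting map.
#' @return An [enface_map] object.
#' @export
reconstruct_enface <- function(volume, b_rpe, d, strict = FALSE,
                               label = "UNKNOWN", case_id = volume$case_id) {
  stopifnot(inherits(volume, "oct_volume"))
  b_rpe <- as.matrix(b_rpe)
  nx <- volume$n_ascan; nz <- volume$n_axial; ny <- volume$n_bscan
  if (!identical(dim(b_rpe), c(nx, ny)))
    stop("b_rpe lateral shape must match the volume", call. = FALSE)
  d <- as.integer(d)
  if (d < 0 || d >= nz)
    stop(sprintf("d must satisfy 0 <= d < n_axial (= %d)", nz), call. = FALSE)

  vals <- matrix(0, nx, ny)
  mask <- is.finite(b_rpe)
  zc <- round(b_rpe)                       # half-to-even, voxel index 0-based
  for (iy in seq_len(ny)) {
    for (ix in seq_len(nx)) {
      if (!mask[ix, iy]) next
      lo <- max(0L, zc[ix, iy] - d); hi <- min(nz - 1L, zc[ix, iy] + d)
      if (hi < 0L || lo > nz - 1L) { mask[ix, iy] <- FALSE; next }
      if (strict && (hi - lo != 2L * d)) { mask[ix, iy] <- FALSE; next }
      vals[ix, iy] <- mean(volume$reflectance[ix, (lo:hi) + 1L, iy])
    }
  }
  enface_map(vals, d, volume$spacing_x_mm, volume$spacing_y_mm,
             volume$fovea_xy, case_id = case_id, label = label, mask = mask)
}
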