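#' Parameters for the synthetic SD-OCT cohort generator
#'
#' Defines the morphology the pipeline assumes: smooth layer surfaces over a
#' fovea-centred field, a Gaussian foveal pit on the inner surface, and (for
#' AMD eyes) drusen as localized Gaussian elevations of the RPE border
#' toward the ILM, which thicken the RPE-drusen complex while leaving
#' Bruch's membrane fixed.  Defaults emulate a 6.7 mm x 6.7 mm macular field
#' on a reduced 200 x 50 x 128 grid.
#'
#' @param grid integer vector `(n_ascan, n_bscan, n_axial)`.
#' @param spacing_x_mm,spacing_y_mm lateral sampling pitch (mm); defaults
#'   spread 6.7 mm across each lateral axis.
#' @param base_depth_ilm mean ILM depth (voxels).
#' @param nsr_thickness_mean,nsr_thickness_sd mean and spatial SD of the
#'   neurosensory retina thickness field (voxels).
#' @param rpedc_thickness_mean,rpedc_thickness_sd same for the RPE-drusen
#'   complex baseline (voxels).
#' @param pit_depth,pit_sigma_mm foveal pit Gaussian amplitude (voxels) and
#'   lateral width (mm); `pit_depth` must stay below `nsr_thickness_mean`.
#' @param drusen_count_mean Poisson mean of the drusen count per AMD eye
#'   (at least one druse is always placed).
#' @param drusen_amp_range min/max druse elevation (voxels); the maximum
#'   must stay below `nsr_thickness_mean` so boundary order survives.
#' @param drusen_sigma_range_mm min/max lateral Gaussian width of a druse.
#' @param surface_noise_sd SD (voxels) of the smooth surface noise added to
#'   each boundary-defining field.
#' @param noise_smooth_mm Gaussian smoothing width applied to the white
#'   noise, giving the fields realistic spatial correlation.
#' @param speckle_cv coefficient of variation of the multiplicative
#'   reflectance noise in [gen_volume()].
#' @param intensity_means named compartment mean intensities
#'   (`vitreous`, `nsr`, `rpedc`, `sub_bm`); the RPE-drusen band is the
#'   brightest.
#'
#' @return A list of class `synthetic_params`.
#' @export
synthetic_params <- function(grid = c(200L, 50L, 128L),
                             spacing_x_mm = 6.7 / grid[1],
                             spacing_y_mm = 6.7 / grid[2],
                             base_depth_ilm = 25,
                             nsr_thickness_mean = 40, nsr_thickness_sd = 2,
                             rpedc_thickness_mean = 8, rpedc_thickness_sd = 1,
                             pit_depth = 15, pit_sigma_mm = 0.5,
                             drusen_count_mean = 8,
                             drusen_amp_range = c(5, 20),
                             drusen_sigma_range_mm = c(0.05, 0.15),
                             surface_noise_sd = 1,
                             noise_smooth_mm = 0.2,
                             speckle_cv = 0.2,
                             intensity_means = c(vitreous = 30, nsr = 90,
                                                 rpedc = 160, sub_bm = 50)) {
  p <- list(grid = as.integer(grid), spacing_x_mm = spacing_x_mm,
            spacing_y_mm = spacing_y_mm, base_depth_ilm = base_depth_ilm,
            nsr_thickness_mean = nsr_thickness_mean,
            nsr_thickness_sd = nsr_thickness_sd,
            rpedc_thickness_mean = rpedc_thickness_mean,
            rpedc_thickness_sd = rpedc_thickness_sd,
            pit_depth = pit_depth, pit_sigma_mm = pit_sigma_mm,
            drusen_count_mean = drusen_count_mean,
            drusen_amp_range = as.numeric(drusen_amp_range),
            drusen_sigma_range_mm = as.numeric(drusen_sigma_range_mm),
            surface_noise_sd = surface_noise_sd,
            noise_smooth_mm = noise_smooth_mm,
            speckle_cv = speckle_cv, intensity_means = intensity_means)
  validate_synthetic_params(p)
  class(p) <- "synthetic_params"
  p
}

validate_synthetic_params <- function(p) {
  if (length(p$grid) != 3 || any(p$grid < 2))
    stop("grid must be (n_ascan, n_bscan, n_axial), all >= 2", call. = FALSE)
  if (p$nsr_thickness_mean <= 0 || p$rpedc_thickness_mean <= 0)
    stop("thickness means must be positive", call. = FALSE)
  if (max(p$drusen_amp_range) >= p$nsr_thickness_mean)
    stop("drusen amplitude must stay below nsr_thickness_mean (boundary order)",
         call. = FALSE)
  if (p$pit_depth >= p$nsr_thickness_mean)
    stop("pit depth must stay below nsr_thickness_mean", call. = FALSE)
  if (p$speckle_cv < 0 || p$surface_noise_sd < 0)
    stop("noise amplitudes must be nonnegative", call. = FALSE)
  invisible(p)
}

# White noise smoothed with a separable Gaussian kernel, renormalized so
# the realized field has SD exactly `sd`.  The noise field is generated
# with a margin of one kernel radius on every side and cropped after
# smoothing, keeping the field stationary (no inflated edge variance).
smooth_field <- function(nx, ny, sd, smooth_mm, sx_mm, sy_mm) {
  if (sd == 0) return(matrix(0, nx, ny))
  k1 <- function(s) {
    if (s <= 0) return(1)
    r <- max(1L, ceiling(3 * s))
    k <- exp(-(seq(-r, r))^2 / (2 * s^2))
    k / sum(k)
  }
  kx <- k1(smooth_mm / sx_mm); ky <- k1(smooth_mm / sy_mm)
  rx <- (length(kx) - 1L) / 2L; ry <- (length(ky) - 1L) / 2L
  z <- matrix(stats::rnorm((nx + 2L * rx) * (ny + 2L * ry)),
              nx + 2L * rx, ny + 2L * ry)
  conv_axis <- function(m, k, axis) {
    if (length(k) == 1) return(m)
    r <- (length(k) - 1L) / 2L
    out <- matrix(0, nrow(m), ncol(m))
    for (i in seq_along(k)) {
      off <- i - r - 1L
      if (axis == 1L) {
        src <- pmin(pmax(seq_len(nrow(m)) + off, 1L), nrow(m))
        out <- out + k[i] * m[src, , drop = FALSE]
      } else {
        src <- pmin(pmax(seq_len(ncol(m)) + off, 1L), ncol(m))
        out <- out + k[i] * m[, src, drop = FALSE]
      }
    }
    out
  }
  f <- conv_axis(conv_axis(z, kx, 1L), ky, 2L)
  f <- f[rx + seq_len(nx), ry + seq_len(ny), drop = FALSE]
  s <- stats::sd(as.numeric(f))
  if (s == 0) matrix(0, nx, ny) else f / s * sd
}

# lateral squared distance (mm^2) from a fractional pixel centre
lateral_dist2_mm <- function(nx, ny, cx, cy, sx, sy) {
  dx <- (seq_len(nx) - cx) * sx
  dy <- (seq_len(ny) - cy) * sy
  outer(dx^2, dy^2, `+`)
}

#' Generate one synthetic boundary case
#'
#' Builds the ILM as a base plane plus a foveal Gaussian pit and smooth
#' noise, then stacks the neurosensory and RPE-drusen complex thickness
#' fields.  For AMD eyes, `K ~ Poisson(drusen_count_mean)` (at least 1)
#' Gaussian bumps are subtracted from the RPE border at uniform random
#' lateral centres, lifting it toward the ILM and thickening the RPE-drusen
#' complex.  Bump amplitudes are clipped where they would invert boundary
#' order; the clip count is stored in attribute `"n_clipped"`.
#'
#' @param params a [synthetic_params] object.
#' @param label `"AMD"` or `"CONTROL"`.
#' @param seed integer RNG seed; same seed, same case.
#' @param case_id case identifier.
#' @return A [layer_boundaries] object.
#' @export
gen_case <- function(params, label = c("CONTROL", "AMD"), seed = 1L,
                     case_id = NULL) {
  stopifnot(inherits(params, "synthetic_params"))
  validate_synthetic_params(params)
  label <- match.arg(label)
  if (is.null(case_id)) case_id <- sprintf("%s_%d", tolower(label), seed)
  set.seed(seed)
  nx <- params$grid[1]; ny <- params$grid[2]; nz <- params$grid[3]
  sx <- params$spacing_x_mm; sy <- params$spacing_y_mm
  fovea <- c((nx + 1) / 2, (ny + 1) / 2)

  d2 <- lateral_dist2_mm(nx, ny, fovea[1], fovea[2], sx, sy)
  pit <- params$pit_depth * exp(-d2 / (2 * params$pit_sigma_mm^2))
  b_ilm <- params$base_depth_ilm + pit +
    smooth_field(nx, ny, params$surface_noise_sd, params$noise_smooth_mm, sx, sy)
  nsr <- params$nsr_thickness_mean +
    smooth_field(nx, ny, params$nsr_thickness_sd, params$noise_smooth_mm, sx, sy)
  rpedc <- params$rpedc_thickness_mean +
    smooth_field(nx, ny, params$rpedc_thickness_sd, params$noise_smooth_mm, sx, sy)
  b_rpe <- b_ilm + nsr
  b_bm <- b_rpe + rpedc

  n_clipped <- 0L
  if (label == "AMD") {
    k <- max(1L, stats::rpois(1, params$drusen_count_mean))
    bump <- matrix(0, nx, ny)
    for (i in seq_len(k)) {
      cx <- stats::runif(1, 1, nx); cy <- stats::runif(1, 1, ny)
      amp <- stats::runif(1, params$drusen_amp_range[1], params$drusen_amp_range[2])
      sig <- stats::runif(1, params$drusen_sigma_range_mm[1],
                          params$drusen_sigma_range_mm[2])
      bump <- bump + amp * exp(-lateral_dist2_mm(nx, ny, cx, cy, sx, sy) /
                                 (2 * sig^2))
    }
    b_rpe <- b_rpe - bump
    low <- b_rpe < b_ilm
    if (any(low)) {
      n_clipped <- sum(low)
      b_rpe[low] <- b_ilm[low]
    }
  }
  if (max(b_bm) >= nz || min(b_ilm) < 0)
    stop("parameters place boundaries outside the axial extent", call. = FALSE)
  out <- layer_boundaries(b_ilm, b_rpe, b_bm, nz, sx, sy, fovea,
                          case_id = case_id, label = label)
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Generate a synthetic reflectance volume for a boundary case
#'
#' Piecewise-constant compartment means (vitreous < neurosensory retina <
#' RPE-drusen band, which is brightest; dimmer below Bruch's membrane),
#' multiplied by positive Gamma noise with the requested coefficient of
#' variation.  A voxel at axial coordinate `z` (0-based) belongs to the
#' compartment whose boundaries bracket it: vitreous for `z < b_ilm`,
#' neurosensory for `b_ilm <= z < b_rpe`, RPE-drusen for
#' `b_rpe <= z < b_bm`, sub-BM otherwise.
#'
#' @param case a [layer_boundaries] object.
#' @param params a [synthetic_params] object (noise and intensity settings).
#' @param seed integer RNG seed.
#' @return An [oct_volume] object.
#' @export
gen_volume <- function(case, params, seed = 1L) {
  stopifnot(inherits(case, "layer_boundaries"),
            inherits(params, "synthetic_params"))
  set.seed(seed)
  nx <- case$n_ascan; ny <- case$n_bscan; nz <- case$n_axial
  im <- params$intensity_means
  # mean intensity array built from z-vs-boundary comparisons, axis (x, z, y)
  z0 <- 0:(nz - 1)
  mean_arr <- array(im[["vitreous"]], dim = c(nx, nz, ny))
  # per B-scan slice: compare the axial coordinate to each boundary depth
  for (iy in seq_len(ny)) {
    bi <- case$b_ilm[, iy]; br <- case$b_rpe[, iy]; bb <- case$b_bm[, iy]
    zge <- function(b) outer(b, z0, `<=`)           # z >= boundary depth
    mean_arr[, , iy] <- im[["vitreous"]] +
      (im[["nsr"]] - im[["vitreous"]]) * zge(bi) +
      (im[["rpedc"]] - im[["nsr"]]) * zge(br) +
      (im[["sub_bm"]] - im[["rpedc"]]) * zge(bb)
  }
  if (params$speckle_cv > 0) {
    shape <- 1 / params$speckle_cv^2
    noise <- array(stats::rgamma(length(mean_arr), shape = shape,
                                 scale = 1 / shape), dim = dim(mean_arr))
    mean_arr <- mean_arr * noise
  }
  oct_volume(mean_arr, case)
}

#' Generate a labelled synthetic cohort
#'
#' Per-case seeds are derived deterministically from the cohort seed, so the
#' cohort is fully reproducible.  AMD cases come first, then controls.
#'
#' @param params a [synthetic_params] object.
#' @param n_amd,n_control class counts (>= 0).
#' @param seed cohort RNG seed.
#' @return A list of [layer_boundaries] objects with attribute `"manifest"`,
#'   a data frame of `case_id`, `label`, `seed`.
#' @export
gen_cohort <- function(params, n_amd, n_control, seed = 1L) {
  stopifnot(n_amd >= 0, n_control >= 0)
  n <- n_amd + n_control
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  labels <- c(rep("AMD", n_amd), rep("CONTROL", n_control))
  ids <- c(sprintf("amd_%03d", seq_len(n_amd)),
           sprintf("ctl_%03d", seq_len(n_control)))
  cases <- vector("list", n)
  for (i in seq_len(n))
    cases[[i]] <- gen_case(params, labels[i], seed = seeds[i], case_id = ids[i])
  names(cases) <- ids
  attr(cases, "manifest") <- data.frame(case_id = ids, label = labels,
                                        seed = seeds,
                                        stringsAsFactors = FALSE)
  cases
}
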