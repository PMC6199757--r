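#' The eight map / function arrangements
#'
#' Registry of the arrangements under which a case is described: each of the
#' three thickness maps and the en-face RPE projection, crossed with the
#' semivariogram (SV) and semimadogram (SM).
#'
#' @return A data frame with columns `arrangement`, `map`, `fun`.
#' @export
arrangements <- function() {
  data.frame(
    arrangement = c("TR-SV", "TR-SM", "NSR-SV", "NSR-SM",
                    "RPEDC-SV", "RPEDC-SM", "ENFACE-SV", "ENFACE-SM"),
    map = rep(c("TR", "NSR", "RPEDC", "ENFACE"), each = 2),
    fun = rep(c("SEMIVARIOGRAM", "SEMIMADOGRAM"), 4),
    stringsAsFactors = FALSE)
}

arrangement_fun <- function(arrangement) {
  reg <- arrangements()
  row <- reg[reg$arrangement == arrangement, ]
  if (!nrow(row))
    stop(sprintf("unknown arrangement '%s' (known: %s)", arrangement,
                 paste(reg$arrangement, collapse = ", ")), call. = FALSE)
  row
}

#' Flatten a variogram curve into a fixed-length feature vector
#'
#' Values are ordered direction-major (in the config's declared direction
#' order) and lag-ascending within each direction, giving
#' `|directions| x |lags|` features (60 under the defaults).  Cells that
#' were empty contribute their flagged 0, so the length is invariant under
#' masking.
#'
#' @param curve a `geostat_curve` from [empirical_curve()].
#' @param arrangement one of the ids in [arrangements()]; its function
#'   (SV/SM) must match the curve's config.
#' @param case_id,label identity metadata carried into the row.
#' @return A one-row data frame: `arrangement`, `case_id`, `label`,
#'   `f_001 .. f_NNN`.
#' @export
build_feature_vector <- function(curve, arrangement, case_id, label) {
  stopifnot(inherits(curve, "geostat_curve"))
  row <- arrangement_fun(arrangement)
  if (row$fun != curve$config$fun)
    stop(sprintf("arrangement '%s' expects %s but the curve holds %s",
                 arrangement, row$fun, curve$config$fun), call. = FALSE)
  tab <- curve$table
  vals <- unlist(lapply(curve$config$directions_deg, function(d) {
    sub <- tab[tab$direction == d, ]
    sub$value[order(sub$lag)]
  }), use.names = FALSE)
  out <- data.frame(arrangement = arrangement, case_id = case_id,
                    label = label, stringsAsFactors = FALSE)
  fv <- as.data.frame(as.list(vals))
  names(fv) <- sprintf("f_%03d", seq_along(vals))
  cbind(out, fv)
}

#' Extract geostatistical feature vectors for one case
#'
#' Runs the full per-case pipeline: thickness maps by boundary subtraction,
#' en-face RPE projection when a volume is supplied, fovea-centred ROI
#' masking, then one directional curve and feature row per requested
#' arrangement.
#'
#' @param case a [layer_boundaries] object.
#' @param volume an [oct_volume]; required for the `ENFACE-*` arrangements.
#' @param arrangement ids from [arrangements()] (default: the six
#'   thickness-map arrangements).
#' @param config a [geostat_config]; its `fun` field is overridden per
#'   arrangement.
#' @param roi_radius_mm ROI radius in mm (required; the field of view is
#'   3.35 mm from the fovea under the default geometry).
#' @param d en-face axial half-window (voxels); required for `ENFACE-*`.
#' @return A data frame of feature rows, one per arrangement.
#' @export
extract_features <- function(case, volume = NULL,
                             arrangement = c("TR-SV", "TR-SM", "NSR-SV",
                                             "NSR-SM", "RPEDC-SV", "RPEDC-SM"),
                             config = geostat_config(),
                             roi_radius_mm, d = NULL) {
  stopifnot(inherits(case, "layer_boundaries"))
  reg <- do.call(rbind, lapply(arrangement, arrangement_fun))
  need_enface <- any(reg$map == "ENFACE")
  if (need_enface && is.null(volume))
    stop("ENFACE arrangements require a reflectance volume", call. = FALSE)
  if (need_enface && is.null(d))
    stop("ENFACE arrangements require the axial half-window d", call. = FALSE)

  maps <- compute_thickness_maps(case)
  maps <- lapply(maps, apply_roi, radius_mm = roi_radius_mm)
  if (need_enface) {
    ef <- reconstruct_enface(volume, case$b_rpe, d = d, label = case$label,
                             case_id = case$case_id)
    maps$ENFACE <- apply_roi(ef, radius_mm = roi_radius_mm)
  }

  rows <- lapply(seq_len(nrow(reg)), function(i) {
    cfg <- config; cfg$fun <- reg$fun[i]
    curve <- empirical_curve(maps[[reg$map[i]]], cfg)
    build_feature_vector(curve, reg$arrangement[i], case$case_id, case$label)
  })
  do.call(rbind, rows)
}

#' Extract features for a whole cohort
#'
#' @param cases list of [layer_boundaries] (e.g. from [gen_cohort()]).
#' @param volumes optional named list of [oct_volume]s matching `cases`.
#' @inheritParams extract_features
#' @return A data frame with one row per case x arrangement.
#' @export
extract_cohort_features <- function(cases, volumes = NULL,
                                    arrangement = c("TR-SV", "TR-SM",
                                                    "NSR-SV", "NSR-SM",
                                                    "RPEDC-SV", "RPEDC-SM"),
                                    config = geostat_config(),
                                    roi_radius_mm, d = NULL) {
  rows <- lapply(seq_along(cases), function(i)
    extract_features(cases[[i]],
                     volume = if (is.null(volumes)) NULL else volumes[[i]],
                     arrangement = arrangement, config = config,
                     roi_radius_mm = roi_radius_mm, d = d))
  do.call(rbind, rows)
}
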