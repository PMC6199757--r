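#' Pair-selection geometry for directional variogram estimation
#'
#' Controls which pixel pairs contribute to each (direction, lag) cell of an
#' empirical semivariogram or semimadogram.  A pair with integer lateral
#' offset `v = (dx, dy)` counts toward direction `theta` and lag `h` when
#' all of the following hold (closed intervals, Euclidean distance):
#'
#' * `max(1, h - lag_tolerance) <= |v| <= h + lag_tolerance` — the lower
#'   bound is clamped to 1 so the zero-offset self-pair never counts;
#' * the angle between `v` and the direction axis (mod 180 degrees) is at
#'   most `angular_tolerance_deg` (a half-angle, the geostatistics
#'   convention; the default 10 degrees with 45-degree direction spacing
#'   gives non-overlapping sectors);
#' * the perpendicular distance of `v` from the direction axis is at most
#'   `bandwidth_px`.
#'
#' Distances and angles are measured in raw pixel units on the native
#' (possibly anisotropic) grid by default.  With `units = "PHYSICAL"` the
#' offsets are first rescaled by the map's mm spacing, normalized to the
#' finer lateral pitch, before the distance, angle and bandwidth tests:
#' distances are then multiples of the finer pixel pitch and angles are
#' true physical angles, correcting the geometric distortion of
#' anisotropic sampling while keeping the lag scale commensurate with the
#' pixel defaults.  Angles are measured counterclockwise from the map's
#' column (A-scan, x) axis toward the row (B-scan, y) axis.
#'
#' @param lags strictly increasing positive integer lags (default `1:15`).
#' @param lag_tolerance nonnegative lag half-width `Delta h` (default 3).
#' @param directions_deg direction axes in degrees (default
#'   `c(0, 45, 90, 135)`).
#' @param angular_tolerance_deg half-angle tolerance, in `[0, 90)`
#'   (default 10).
#' @param bandwidth_px maximum perpendicular offset (default 3).
#' @param fun `"SEMIVARIOGRAM"` (half mean squared difference) or
#'   `"SEMIMADOGRAM"` (half mean absolute difference).
#' @param units `"PIXEL"` or `"PHYSICAL"`.
#' @return A list of class `geostat_config`.
#' @export
geostat_config <- function(lags = 1:15, lag_tolerance = 3,
                           directions_deg = c(0, 45, 90, 135),
                           angular_tolerance_deg = 10, bandwidth_px = 3,
                           fun = c("SEMIVARIOGRAM", "SEMIMADOGRAM"),
                           units = c("PIXEL", "PHYSICAL")) {
  fun <- match.arg(fun); units <- match.arg(units)
  lags <- as.numeric(lags)
  if (any(lags < 1) || any(diff(lags) <= 0))
    stop("lags must be strictly increasing and >= 1", call. = FALSE)
  if (angular_tolerance_deg < 0 || angular_tolerance_deg >= 90)
    stop("angular_tolerance_deg must lie in [0, 90)", call. = FALSE)
  if (bandwidth_px < 0) stop("bandwidth_px must be >= 0", call. = FALSE)
  if (lag_tolerance < 0) stop("lag_tolerance must be >= 0", call. = FALSE)
  structure(list(lags = lags, lag_tolerance = lag_tolerance,
                 directions_deg = as.numeric(directions_deg),
                 angular_tolerance_deg = angular_tolerance_deg,
                 bandwidth_px = bandwidth_px, fun = fun, units = units),
            class = "geostat_config")
}

ANG_EPS <- 1e-9

# angle of (dx, dy) in degrees, folded into [0, 180)
offset_angle <- function(dx, dy) {
  a <- atan2(dy, dx) * 180 / pi
  a <- a %% 180
  a
}

# smallest angular difference between two axes (mod 180)
axis_angle_diff <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

#' Admissible integer pixel offsets for one (direction, lag) cell
#'
#' Enumerates every integer offset `(dx, dy)` satisfying the distance,
#' angle and bandwidth constraints of a [geostat_config], canonicalized to
#' the half-plane `dy > 0 | (dy == 0 & dx > 0)` so each unordered pixel
#' pair is generated exactly once (the estimators are symmetric, so a
#' direction and its opposite give identical offset sets).
#'
#' @param config a [geostat_config].
#' @param direction_deg one of the configured directions.
#' @param lag one of the configured lags.
#' @param spacing optional `c(sx, sy)` in mm, used only for
#'   `units = "PHYSICAL"`.
#' @return A two-column integer matrix (`dx`, `dy`), possibly with zero
#'   rows (an empty admissible set is flagged downstream, not an error).
#' @export
admissible_offsets <- function(config, direction_deg, lag,
                               spacing = c(1, 1)) {
  stopifnot(inherits(config, "geostat_config"))
  sx <- if (config$units == "PHYSICAL") spacing[1] / min(spacing) else 1
  sy <- if (config$units == "PHYSICAL") spacing[2] / min(spacing) else 1
  r_hi <- lag + config$lag_tolerance
  r_lo <- max(1, lag - config$lag_tolerance)
  # enumeration window: offsets whose scaled length can reach r_hi
  mx <- ceiling(r_hi / sx); my <- ceiling(r_hi / sy)
  g <- expand.grid(dx = -mx:mx, dy = -my:my)
  g <- g[g$dy > 0 | (g$dy == 0 & g$dx > 0), , drop = FALSE]
  px <- g$dx * sx; py <- g$dy * sy
  r <- sqrt(px^2 + py^2)
  keep <- r >= r_lo - ANG_EPS & r <= r_hi + ANG_EPS
  ang <- offset_angle(px, py)
  keep <- keep & axis_angle_diff(ang, direction_deg) <=
    config$angular_tolerance_deg + ANG_EPS
  th <- direction_deg * pi / 180
  perp <- abs(-px * sin(th) + py * cos(th))
  keep <- keep & perp <= config$bandwidth_px + ANG_EPS
  out <- as.matrix(g[keep, , drop = FALSE])
  storage.mode(out) <- "integer"
  dimnames(out) <- list(NULL, c("dx", "dy"))
  out
}

map_values_mask <- function(map) {
  if (inherits(map, c("thickness_map", "enface_map")))
    list(values = map$values, mask = map$mask,
         spacing = c(map$spacing_x_mm, map$spacing_y_mm))
  else if (is.matrix(map))
    list(values = map, mask = matrix(TRUE, nrow(map), ncol(map)),
         spacing = c(1, 1))
  else stop("map must be a thickness_map, enface_map or matrix", call. = FALSE)
}

new_geostat_curve <- function(df, config) {
  structure(list(table = df, config = config), class = "geostat_curve")
}

#' Directional empirical semivariogram / semimadogram of a masked map
#'
#' For each configured (direction, lag) cell, accumulates over all valid
#' pixel pairs generated by [admissible_offsets()] (both endpoints inside
#' the mask).  The semivariogram value is `sum((x_i - x_j)^2) / (2 N)` and
#' the semimadogram value `sum(|x_i - x_j|) / (2 N)`, with the pair count
#' `N` recorded per cell.  Cells with no admissible pair get value 0 and
#' are flagged `empty`; with `strict = TRUE` they raise instead.  The
#' efficient path accumulates shifted-grid differences per offset under the
#' joint mask, which enumerates exactly the same unordered pairs as a
#' direct pair loop.
#'
#' @param map a [thickness_map], [enface_map] or bare numeric matrix
#'   (bare matrices are treated as fully valid with unit spacing).
#' @param config a [geostat_config].
#' @param strict error on empty (direction, lag) cells.
#' @return A `geostat_curve`: a table of `direction`, `lag`, `value`,
#'   `n_pairs`, `empty` plus the config used.
#' @export
empirical_curve <- function(map, config, strict = FALSE) {
  stopifnot(inherits(config, "geostat_config"))
  m <- map_values_mask(map)
  if (sum(m$mask) < 2)
    stop("map must contain at least 2 valid pixels", call. = FALSE)
  vals <- m$values; mask <- m$mask
  vals[!mask] <- 0                       # masked cells never reach the sums
  nx <- nrow(vals); ny <- ncol(vals)

  cells <- expand.grid(lag = config$lags, direction = config$directions_deg)
  cells <- cells[, c("direction", "lag")]
  value <- numeric(nrow(cells)); npairs <- integer(nrow(cells))
  square <- config$fun == "SEMIVARIOGRAM"

  for (ci in seq_len(nrow(cells))) {
    offs <- admissible_offsets(config, cells$direction[ci], cells$lag[ci],
                               spacing = m$spacing)
    acc <- 0; n <- 0L
    if (nrow(offs)) for (oi in seq_len(nrow(offs))) {
      dx <- offs[oi, 1L]; dy <- offs[oi, 2L]
      xlo <- max(1L, 1L - dx); xhi <- min(nx, nx - dx)
      ylo <- max(1L, 1L - dy); yhi <- min(ny, ny - dy)
      if (xlo > xhi || ylo > yhi) next
      x1 <- xlo:xhi; y1 <- ylo:yhi
      jm <- mask[x1, y1, drop = FALSE] &
        mask[x1 + dx, y1 + dy, drop = FALSE]
      if (!any(jm)) next
      d <- vals[x1, y1, drop = FALSE] - vals[x1 + dx, y1 + dy, drop = FALSE]
      d <- d[jm]
      acc <- acc + if (square) sum(d * d) else sum(abs(d))
      n <- n + length(d)
    }
    npairs[ci] <- n
    value[ci] <- if (n > 0L) acc / (2 * n) else 0
  }
  if (all(npairs == 0L))
    stop("pair-selection geometry incompatible with this grid: all cells empty",
         call. = FALSE)
  if (any(npairs == 0L)) {
    if (strict)
      stop(sprintf("%d empty (direction, lag) cell(s) under strict mode",
                   sum(npairs == 0L)), call. = FALSE)
    warning(sprintf("%d empty (direction, lag) cell(s); values set to 0",
                    sum(npairs == 0L)), call. = FALSE)
  }
  new_geostat_curve(
    data.frame(direction = cells$direction, lag = cells$lag, value = value,
               n_pairs = npairs, empty = npairs == 0L), config)
}

#' Brute-force reference variogram estimator
#'
#' Same contract as [empirical_curve()], computed by direct enumeration of
#' all valid pixel pairs with per-pair distance, angle and bandwidth tests.
#' Quadratic in the number of valid pixels; intended as an independent
#' oracle on small grids (<= ~40 x 40).
#'
#' @inheritParams empirical_curve
#' @return A `geostat_curve`.
#' @export
brute_force_curve <- function(map, config, strict = FALSE) {
  stopifnot(inherits(config, "geostat_config"))
  m <- map_values_mask(map)
  idx <- which(m$mask, arr.ind = TRUE)
  if (nrow(idx) < 2)
    stop("map must contain at least 2 valid pixels", call. = FALSE)
  v <- m$values[m$mask]
  sx <- if (config$units == "PHYSICAL") m$spacing[1] / min(m$spacing) else 1
  sy <- if (config$units == "PHYSICAL") m$spacing[2] / min(m$spacing) else 1

  p <- nrow(idx)
  ut <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  i <- ut[, 1L]; j <- ut[, 2L]
  dx <- (idx[j, 1L] - idx[i, 1L]); dy <- (idx[j, 2L] - idx[i, 2L])
  px <- dx * sx; py <- dy * sy
  r <- sqrt(px^2 + py^2)
  ang <- offset_angle(px, py)
  dv <- v[i] - v[j]
  square <- config$fun == "SEMIVARIOGRAM"
  contrib <- if (square) dv * dv else abs(dv)

  cells <- expand.grid(lag = config$lags, direction = config$directions_deg)
  cells <- cells[, c("direction", "lag")]
  value <- numeric(nrow(cells)); npairs <- integer(nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    th <- cells$direction[ci]
    r_lo <- max(1, cells$lag[ci] - config$lag_tolerance)
    r_hi <- cells$lag[ci] + config$lag_tolerance
    thr <- th * pi / 180
    perp <- abs(-px * sin(thr) + py * cos(thr))
    keep <- r >= r_lo - ANG_EPS & r <= r_hi + ANG_EPS &
      axis_angle_diff(ang, th) <= config$angular_tolerance_deg + ANG_EPS &
      perp <= config$bandwidth_px + ANG_EPS
    n <- sum(keep)
    npairs[ci] <- n
    value[ci] <- if (n > 0L) sum(contrib[keep]) / (2 * n) else 0
  }
  if (all(npairs == 0L))
    stop("pair-selection geometry incompatible with this grid: all cells empty",
         call. = FALSE)
  if (any(npairs == 0L) && strict)
    stop("empty (direction, lag) cell(s) under strict mode", call. = FALSE)
  new_geostat_curve(
    data.frame(direction = cells$direction, lag = cells$lag, value = value,
               n_pairs = npairs, empty = npairs == 0L), config)
}

#' @export
print.geostat_curve <- function(x, ...) {
  cat(sprintf("%s curve: %d direction(s) x %d lag(s)\n",
              tolower(x$config$fun), length(x$config$directions_deg),
              length(x$config$lags)))
  print(utils::head(x$table, 8))
  if (nrow(x$table) > 8) cat(sprintf("  ... %d more rows\n", nrow(x$table) - 8))
  invisible(x)
}

#' @export
as.data.frame.geostat_curve <- function(x, ...) x$table

#' Plot a directional variogram curve
#'
#' One line per direction, lag on the abscissa; the classic diagnostic view
#' in which sill-like flattening and anisotropy are read off by eye.
#'
#' @param x a `geostat_curve`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.geostat_curve <- function(x, ...) {
  tab <- x$table
  dirs <- sort(unique(tab$direction))
  lags <- sort(unique(tab$lag))
  m <- sapply(dirs, function(d) tab$value[tab$direction == d][order(tab$lag[tab$direction == d])])
  graphics::matplot(lags, m, type = "b", pch = 16, lty = 1,
                    xlab = "lag (pixels)",
                    ylab = if (x$config$fun == "SEMIVARIOGRAM")
                      expression(gamma(h)) else "m(h)", ...)
  graphics::legend("bottomright", legend = paste0(dirs, "°"),
                   col = seq_along(dirs), lty = 1, pch = 16, bty = "n")
  invisible(x)
}
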