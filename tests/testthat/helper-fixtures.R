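# Shared fixtures built in code.

# constant-boundary case: ilm/rpe/bm planes at given depths
flat_case <- function(ilm = 10, rpe = 14, bm = 15, nx = 6, ny = 5,
                      n_axial = 32, sx = 0.1, sy = 0.1, label = "UNKNOWN") {
  layer_boundaries(matrix(ilm, nx, ny), matrix(rpe, nx, ny),
                   matrix(bm, nx, ny), n_axial, sx, sy,
                   fovea_xy = c((nx + 1) / 2, (ny + 1) / 2),
                   case_id = "flat", label = label)
}

# reduced synthetic geometry so per-test generation stays cheap
tiny_params <- function(...) {
  synthetic_params(grid = c(48L, 24L, 96L),
                   spacing_x_mm = 6.7 / 48, spacing_y_mm = 6.7 / 24, ...)
}

# random masked map for oracle-equivalence checks
random_masked_map <- function(n = 16, p_masked = 0.2) {
  v <- matrix(stats::rnorm(n * n), n, n)
  m <- matrix(stats::runif(n * n) > p_masked, n, n)
  if (sum(m) < 2) m[1:2] <- TRUE
  list(values = v, mask = m,
       map = thickness_map(abs(v), "TR", 0.1, 0.1, c(n / 2, n / 2), mask = m))
}

curve_df <- function(curve) as.data.frame(curve)
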