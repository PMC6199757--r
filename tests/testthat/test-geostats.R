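test_that("admissible offsets reduce to the axis vector at zero tolerances", {
  cfg <- geostat_config(lags = 1:2, lag_tolerance = 0,
                        angular_tolerance_deg = 0, bandwidth_px = 0)
  expect_identical(admissible_offsets(cfg, 0, 1),
                   matrix(c(1L, 0L), 1, dimnames = list(NULL, c("dx", "dy"))))
  expect_identical(admissible_offsets(cfg, 90, 2),
                   matrix(c(0L, 2L), 1, dimnames = list(NULL, c("dx", "dy"))))
  # a direction and its opposite share one canonical offset set
  cfg2 <- geostat_config(lags = 1:4)
  for (th in c(0, 45, 90, 135))
    expect_identical(admissible_offsets(cfg2, th, 3),
                     admissible_offsets(cfg2, th + 180, 3))
})

test_that("the 3x3 column-gradient map gives 0.5 at direction 0, lag 1", {
  m <- matrix(rep(0:2, times = 3), nrow = 3)   # value = x index - 1
  cfg <- geostat_config(lags = 1, lag_tolerance = 0,
                        directions_deg = 0, angular_tolerance_deg = 0,
                        bandwidth_px = 0)
  for (fun in c("SEMIVARIOGRAM", "SEMIMADOGRAM")) {
    cfg$fun <- fun
    cur <- empirical_curve(m, cfg)$table
    expect_identical(cur$n_pairs, 6L)          # 2 pairs per row x 3 rows
    expect_identical(cur$value, 0.5)           # 6 * 1 / (2 * 6)
  }
})

test_that("constant maps give zero curves with positive pair counts", {
  cfg <- geostat_config(lags = 1:4)
  for (fun in c("SEMIVARIOGRAM", "SEMIMADOGRAM")) {
    cfg$fun <- fun
    tab <- empirical_curve(matrix(3.7, 20, 20), cfg)$table
    expect_true(all(tab$value == 0))
    expect_true(all(tab$n_pairs > 0))
  }
})

test_that("homogeneity and translation identities hold", {
  set.seed(42)
  m <- matrix(rnorm(400), 20, 20)
  cfg_sv <- geostat_config(lags = 1:5)
  cfg_sm <- geostat_config(lags = 1:5, fun = "SEMIMADOGRAM")
  sv <- empirical_curve(m, cfg_sv)$table$value
  sm <- empirical_curve(m, cfg_sm)$table$value
  for (c0 in c(-2.5, 3)) {
    expect_equal(empirical_curve(m * c0, cfg_sv)$table$value, c0^2 * sv,
                 tolerance = 1e-12)
    expect_equal(empirical_curve(m * c0, cfg_sm)$table$value, abs(c0) * sm,
                 tolerance = 1e-12)
    expect_equal(empirical_curve(m + c0, cfg_sv)$table$value, sv,
                 tolerance = 1e-12)
    expect_equal(empirical_curve(m + c0, cfg_sm)$table$value, sm,
                 tolerance = 1e-12)
  }
  expect_true(all(sv >= 0) && all(sm >= 0))
})

test_that("shifted-grid accumulation matches brute-force pair enumeration", {
  set.seed(7)
  cfg <- geostat_config(lags = 1:6)
  for (i in 1:8) {
    rm <- random_masked_map(14, p_masked = 0.3)
    for (fun in c("SEMIVARIOGRAM", "SEMIMADOGRAM")) {
      cfg$fun <- fun
      a <- suppressWarnings(empirical_curve(rm$map, cfg))$table
      b <- suppressWarnings(brute_force_curve(rm$map, cfg))$table
      expect_identical(a$n_pairs, b$n_pairs)
      expect_equal(a$value, b$value, tolerance = 1e-12)
    }
  }
})

test_that("shrinking the mask never increases any pair count", {
  set.seed(13)
  rm <- random_masked_map(16, p_masked = 0)
  cfg <- geostat_config(lags = 1:5)
  full <- empirical_curve(rm$map, cfg)$table$n_pairs
  shrunk_map <- rm$map
  shrunk_map$mask[sample(256, 120)] <- FALSE
  shrunk <- suppressWarnings(empirical_curve(shrunk_map, cfg))$table$n_pairs
  expect_true(all(shrunk <= full))
})

test_that("empty cells are flagged, strict mode errors, degenerate input errors", {
  m <- matrix(1:25, 5, 5)
  cfg <- geostat_config(lags = c(1, 8))     # lag 8 +- 3 cannot fit in 5x5
  expect_warning(cur <- empirical_curve(m, cfg), "empty")
  tab <- cur$table
  expect_true(any(tab$empty))
  expect_true(all(tab$value[tab$empty] == 0))
  expect_error(empirical_curve(m, cfg, strict = TRUE), "strict")

  cfg_far <- geostat_config(lags = 40, lag_tolerance = 0)
  expect_error(suppressWarnings(empirical_curve(m, cfg_far)), "incompatible")

  single <- thickness_map(matrix(1, 4, 4), "TR", 0.1, 0.1, c(2, 2),
                          mask = matrix(c(TRUE, rep(FALSE, 15)), 4, 4))
  expect_error(empirical_curve(single, geostat_config(lags = 1)),
               "2 valid pixels")
})

test_that("physical units correct anisotropic pair geometry", {
  set.seed(3)
  v <- abs(matrix(rnorm(30 * 30), 30, 30))
  # isotropic spacing: PHYSICAL and PIXEL are identical
  iso <- thickness_map(v, "TR", 0.1, 0.1, c(15, 15))
  cfg_px <- geostat_config(lags = 1:4)
  cfg_mm <- geostat_config(lags = 1:4, units = "PHYSICAL")
  expect_equal(empirical_curve(iso, cfg_px)$table,
               empirical_curve(iso, cfg_mm)$table, ignore_attr = TRUE)
  # 4x coarser y pitch: one row step spans four distance units, so the
  # offset (0, 1) serves lag 4, not lag 1, along the 90-degree axis
  aniso <- thickness_map(v, "TR", 0.05, 0.2, c(15, 15))
  cfg0 <- geostat_config(lags = c(1, 4), lag_tolerance = 0,
                         angular_tolerance_deg = 0, bandwidth_px = 0,
                         units = "PHYSICAL")
  sp <- c(0.05, 0.2)
  expect_identical(nrow(admissible_offsets(cfg0, 90, 1, spacing = sp)), 0L)
  expect_identical(admissible_offsets(cfg0, 90, 4, spacing = sp),
                   matrix(c(0L, 1L), 1, dimnames = list(NULL, c("dx", "dy"))))
  # brute force agrees in physical mode too
  a <- suppressWarnings(empirical_curve(aniso, cfg_mm))$table
  b <- suppressWarnings(brute_force_curve(aniso, cfg_mm))$table
  expect_identical(a$n_pairs, b$n_pairs)
  expect_equal(a$value, b$value, tolerance = 1e-12)
})

test_that("config validation rejects malformed geometry", {
  expect_error(geostat_config(lags = c(3, 2)), "increasing")
  expect_error(geostat_config(angular_tolerance_deg = 95), "\\[0, 90\\)")
  expect_error(geostat_config(bandwidth_px = -1), "bandwidth")
})
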