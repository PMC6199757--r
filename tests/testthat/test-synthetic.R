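test_that("noise-free control case has exactly the baseline RPEDC thickness", {
  p <- tiny_params(surface_noise_sd = 0, nsr_thickness_sd = 0,
                   rpedc_thickness_sd = 0)
  case <- gen_case(p, "CONTROL", seed = 3)
  rpedc <- case$b_bm - case$b_rpe
  expect_true(all(abs(rpedc - p$rpedc_thickness_mean) < 1e-12))
  # the foveal pit shows in the ILM depth but not in any thickness map
  expect_gt(max(case$b_ilm) - min(case$b_ilm), p$pit_depth * 0.9)
  expect_equal(max(case$b_rpe - case$b_ilm), p$nsr_thickness_mean,
               tolerance = 1e-12)
})

test_that("a single noise-free druse lifts the RPEDC peak by its amplitude", {
  amp <- 12
  p <- tiny_params(surface_noise_sd = 0, nsr_thickness_sd = 0,
                   rpedc_thickness_sd = 0, drusen_count_mean = 1e-9,
                   drusen_amp_range = c(amp, amp),
                   drusen_sigma_range_mm = c(0.3, 0.3))
  case <- gen_case(p, "AMD", seed = 21)
  rpedc <- case$b_bm - case$b_rpe
  peak <- max(rpedc) - p$rpedc_thickness_mean
  # K = max(1, Poisson(~0)) = 1 druse; the peak equals the amplitude up to
  # the sub-pixel offset of the random centre (sigma = 0.3 mm >> pixel)
  expect_gt(peak, 0.97 * amp)
  expect_lte(peak, amp + 1e-9)
  # far from the druse the baseline is untouched
  expect_equal(min(rpedc), p$rpedc_thickness_mean, tolerance = 1e-6)
})

test_that("generation is deterministic in the seed", {
  p <- tiny_params()
  a <- gen_case(p, "AMD", seed = 9)
  b <- gen_case(p, "AMD", seed = 9)
  expect_identical(a, b)
  expect_false(identical(gen_case(p, "AMD", seed = 10)$b_rpe, a$b_rpe))

  c1 <- gen_cohort(p, 3, 2, seed = 4)
  c2 <- gen_cohort(p, 3, 2, seed = 4)
  expect_identical(c1, c2)
  expect_identical(attr(c1, "manifest")$label,
                   c(rep("AMD", 3), rep("CONTROL", 2)))
})

test_that("every generated case satisfies the boundary invariants", {
  p <- tiny_params()
  for (s in 1:12) {
    case <- gen_case(p, if (s %% 2) "AMD" else "CONTROL", seed = s)
    expect_true(all(case$b_ilm <= case$b_rpe + 1e-12))
    expect_true(all(case$b_rpe <= case$b_bm + 1e-12))
    expect_true(all(case$b_ilm >= 0) && all(case$b_bm < case$n_axial))
  }
})

test_that("invalid generator parameters are rejected", {
  expect_error(tiny_params(drusen_amp_range = c(5, 50)), "amplitude")
  expect_error(tiny_params(pit_depth = 60), "pit depth")
  expect_error(tiny_params(nsr_thickness_mean = -1), "positive")
})

test_that("noise-free volume is piecewise-constant by compartment", {
  p <- tiny_params(speckle_cv = 0, surface_noise_sd = 0,
                   nsr_thickness_sd = 0, rpedc_thickness_sd = 0)
  case <- gen_case(p, "CONTROL", seed = 2)
  vol <- gen_volume(case, p, seed = 3)
  im <- p$intensity_means
  # probe one A-scan: vitreous above ILM, RPEDC band between RPE and BM
  ix <- 3; iy <- 4
  z_vit <- floor(case$b_ilm[ix, iy]) - 2
  z_band <- floor((case$b_rpe[ix, iy] + case$b_bm[ix, iy]) / 2)
  expect_identical(vol$reflectance[ix, z_vit + 1, iy], unname(im["vitreous"]))
  expect_identical(vol$reflectance[ix, z_band + 1, iy], unname(im["rpedc"]))
  # en-face projection at d = 0 of a noise-free volume equals the band mean
  # wherever the rounded border index falls inside the RPEDC band
  ef <- reconstruct_enface(vol, case$b_rpe, d = 0)
  in_band <- round(case$b_rpe) >= case$b_rpe
  expect_gt(sum(in_band), 0)
  expect_true(all(abs(ef$values[in_band] - im["rpedc"]) < 1e-12))
  expect_true(all(abs(ef$values[!in_band] - im["nsr"]) < 1e-12))
})

test_that("speckle noise has the requested mean and dispersion", {
  p <- tiny_params(speckle_cv = 0.3)
  case <- gen_case(p, "CONTROL", seed = 5)
  vol <- gen_volume(case, p, seed = 6)
  # voxels well inside the vitreous compartment share one gamma-noise mean
  sel <- vol$reflectance[, 1:5, ]       # shallow voxels: all vitreous
  expect_true(all(case$b_ilm > 6))
  mu <- p$intensity_means[["vitreous"]]
  se <- stats::sd(sel) / sqrt(length(sel))
  expect_lt(abs(mean(sel) - mu), 3 * se + 1e-9)
  expect_equal(stats::sd(sel) / mean(sel), 0.3, tolerance = 0.05)
})

test_that("drusen raise cohort RPEDC thickness; amplitude zero erases the classes", {
  p <- tiny_params(drusen_amp_range = c(5, 20))
  coh <- gen_cohort(p, 15, 15, seed = 77)
  mean_rpedc <- vapply(coh, function(cs) mean(cs$b_bm - cs$b_rpe), 0)
  labs <- attr(coh, "manifest")$label
  expect_gt(mean(mean_rpedc[labs == "AMD"]),
            mean(mean_rpedc[labs == "CONTROL"]))

  # with zero-amplitude drusen the generators are distributionally identical
  p0 <- tiny_params(drusen_amp_range = c(0, 0))
  coh0 <- gen_cohort(p0, 50, 50, seed = 78)
  m0 <- vapply(coh0, function(cs) mean(cs$b_bm - cs$b_rpe), 0)
  l0 <- attr(coh0, "manifest")$label
  expect_gt(stats::wilcox.test(m0[l0 == "AMD"], m0[l0 == "CONTROL"])$p.value,
            0.01)
})
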