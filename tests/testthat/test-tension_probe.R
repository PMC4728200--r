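uniform_image <- function(value, h = 40, w = 40, pitch = 0.29) {
  channel_image(matrix(value, h, w), pitch)
}

test_that("profiles sample uniform regions exactly and respect interpolation", {
  img <- uniform_image(0.6)
  prof <- sample_profile(img, c(2, 3), c(5, 3))
  expect_true(all(abs(prof - 0.6) < 1e-12))
  # endpoint sample equals the bilinear value at that point
  set.seed(2)
  img2 <- channel_image(matrix(runif(1600), 40, 40), 0.29)
  p0 <- c(11.5, 5.5) * 0.29; p1 <- c(30.5, 20.5) * 0.29  # pixel centers
  prof2 <- sample_profile(img2, p0, p1)
  expect_equal(prof2[1], img2$intensities[6, 12], tolerance = 1e-12)
  expect_equal(prof2[length(prof2)], img2$intensities[21, 31], tolerance = 1e-12)
  expect_error(sample_profile(img, c(1, 1), c(1, 1)), "zero-length")
  expect_error(sample_profile(img, c(-5, 1), c(5, 1)), "outside")
})

test_that("a probe across a synthetic Gaussian fiber peaks on the fiber axis", {
  cell <- generate_cell(small_cell(noise_sd = 0))
  tr <- cell$truth$fibers[1, ]
  prof <- sample_profile(cell$actin, c(tr$px0, tr$py0), c(tr$px1, tr$py1))
  k <- which.max(prof)
  expect_gt(prof[k], 0.9 * tr$peak)
  # maximum within one sample spacing of the geometric center
  expect_lte(abs(k - (length(prof) + 1) / 2), 1.5)
  expect_true(all(diff(prof[1:k]) > -1e-9) || all(diff(prof[k:length(prof)]) < 1e-9))
})

test_that("probe tension applies the cross-linear relation", {
  expect_equal(probe_tension(rep(1, 11), width = 1, T_cl_max = 7.3), 7.3)
  expect_equal(probe_tension(c(0.7, 0.8, 0.9), 1.58, 7.3),
               7.3 * 0.8 * 1.58, tolerance = 1e-12)
  # the printed worked example: c_mean = 0.797 over a 1.58 um fiber
  expect_equal(round(probe_tension(rep(0.797, 5), 1.58, 7.3), 1), 9.2)
  expect_warning(probe_tension(rep(0.5, 5), 0.5, 7.3), "0.6 um")
  expect_error(probe_tension(numeric(0), 1, 7.3), "empty")
})

test_that("probe additivity: a long segment equals the sum of its sub-segments", {
  cell <- generate_cell(small_cell(noise_sd = 0))
  img <- cell$actin
  p0 <- c(8, 4.5); p2 <- c(8, 16); pm <- (p0 + p2) / 2
  spacing <- 0.01
  long <- probe_tension(sample_profile(img, p0, p2, spacing),
                        sqrt(sum((p2 - p0)^2)), 7.3)
  half1 <- probe_tension(sample_profile(img, p0, pm, spacing),
                         sqrt(sum((pm - p0)^2)), 7.3)
  half2 <- probe_tension(sample_profile(img, pm, p2, spacing),
                         sqrt(sum((p2 - pm)^2)), 7.3)
  expect_equal(long, half1 + half2, tolerance = 2e-3)
})

test_that("tension is conserved along a uniform fiber and under rotation", {
  cell <- generate_cell(small_cell(noise_sd = 0))
  tr <- cell$truth$fibers[1, ]
  # two cross-sections of the same fiber, away from its ends
  mid <- c((tr$px0 + tr$px1) / 2, (tr$py0 + tr$py1) / 2)
  t1 <- probe_tension(sample_profile(cell$actin, c(tr$px0, tr$py0),
                                     c(tr$px1, tr$py1)), tr$width, 7.3)
  off <- 4  # um along the fiber (horizontal)
  t2 <- probe_tension(sample_profile(cell$actin, c(tr$px0 + off, tr$py0),
                                     c(tr$px1 + off, tr$py1)), tr$width, 7.3)
  expect_lt(abs(t1 - t2) / t1, 0.10)
  # rotating image and probe together leaves the tension unchanged: under a
  # 90 degree rotation a point (x, y) maps to (y, W - x) with W the image width
  rot <- channel_image(t(cell$actin$intensities)[ncol(cell$actin$intensities):1, ],
                       cell$actin$pixel_pitch)
  w_um <- ncol(cell$actin$intensities) * cell$actin$pixel_pitch
  rp0 <- c(tr$py0, w_um - tr$px0); rp1 <- c(tr$py1, w_um - tr$px1)
  t3 <- probe_tension(sample_profile(rot, rp0, rp1), tr$width, 7.3)
  expect_lt(abs(t1 - t3) / t1, 0.01)
})

test_that("the equivalent Young's modulus follows the circular-rod formula", {
  expect_equal(equivalent_young_modulus(4.5, 0.25, 0.2), 458.4, tolerance = 5e-4)
  # doubling the strain halves the modulus
  expect_equal(equivalent_young_modulus(4.5, 0.25, 0.4),
               equivalent_young_modulus(4.5, 0.25, 0.2) / 2)
  # identity check in consistent units: T = pi r^2 eps -> E = 1
  expect_equal(equivalent_young_modulus(pi * 0.5^2 * 0.3, 1, 0.3), 1)
  expect_error(equivalent_young_modulus(1, 0, 0.2), "diameter")
  expect_error(equivalent_young_modulus(1, 1, 0), "strain")
})

test_that("whole-cell tonus relates section tension to the focal force sum", {
  img <- uniform_image(0.5, h = 60, w = 60)
  res <- tonus(img, c(2, 8), c(15, 8), T_cl_max = 2, F_measured = 100)
  expect_equal(res$tension, 2 * 0.5 * 13, tolerance = 1e-9)
  expect_equal(res$ratio_pct, 13)
  blank <- uniform_image(0, h = 20, w = 20)
  res0 <- tonus(blank, c(1, 2), c(4, 2), 7.3, 0)
  expect_equal(res0$tension, 0)
  expect_equal(res0$ratio_pct, 0)
})

test_that("probe tables are measured row-wise with unit conversion", {
  img <- uniform_image(0.4, h = 60, w = 60)
  probes <- data.frame(x0 = c(2, 10), y0 = c(3, 10), x1 = c(4, 10), y1 = c(3, 14))
  out <- measure_probes(img, probes, T_cl_max = 5)
  expect_equal(out$width_um, c(2, 4))
  expect_equal(out$c_mean, c(0.4, 0.4))
  expect_equal(out$tension_nN, 5 * 0.4 * c(2, 4))
  # pixel-unit input
  outpx <- measure_probes(img, data.frame(x0 = 10, y0 = 10, x1 = 20, y1 = 10),
                          T_cl_max = 5, units = "px")
  expect_equal(outpx$width_um, 10 * 0.29)
})
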