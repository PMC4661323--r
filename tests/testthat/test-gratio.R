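test_that("resampling copies identical grids bit-exactly", {
  aff <- diag(c(2.3, 2.3, 2.3, 1))
  set.seed(4)
  v <- as_volume(array(rnorm(4^3), c(4, 4, 4)), aff)
  out <- resample_to_grid(v, c(4, 4, 4), aff)
  expect_identical(as.numeric(out), as.numeric(v))

  const <- as_volume(array(3.14, c(5, 5, 5)), aff)
  out2 <- resample_to_grid(const, c(3, 3, 3),
                           {a <- diag(c(3, 3, 3, 1)); a[1:3, 4] <- 1; a})
  expect_lt(max(abs(out2[!is.na(out2)] - 3.14)), 1e-12)
})

test_that("downsampling a world-space ramp is exact under trilinear", {
  # value = world x coordinate: linear, so interpolation is exact
  src_aff <- diag(c(0.8, 0.8, 0.8, 1)); src_aff[1:3, 4] <- c(-8, -8, -8)
  d_src <- c(21, 21, 21)
  w <- voxel_centers(d_src, src_aff)
  src <- as_volume(array(w[, 1], d_src), src_aff)
  tgt_aff <- diag(c(2.3, 2.3, 2.3, 1)); tgt_aff[1:3, 4] <- c(-5, -5, -5)
  d_tgt <- c(5, 5, 5)
  out <- resample_to_grid(src, d_tgt, tgt_aff)
  expect_equal(as.numeric(out), voxel_centers(d_tgt, tgt_aff)[, 1],
               tolerance = 1e-9)

  # nearest-neighbour picks the closest source sample
  nn <- resample_to_grid(src, d_tgt, tgt_aff, method = "nearest")
  expect_true(all(abs(as.numeric(nn) -
                        voxel_centers(d_tgt, tgt_aff)[, 1]) <= 0.4 + 1e-9))
})

test_that("displacement warps translate, invert and guard the FoV", {
  aff <- diag(c(2.3, 2.3, 2.3, 1))
  d3 <- c(9, 9, 9)
  vol <- array(0, d3); vol[5, 3, 5] <- 1       # delta ridge
  v <- as_volume(vol, aff)

  zero <- displacement_field(array(0, d3))
  expect_equal(as.numeric(apply_displacement(v, zero)), as.numeric(v))

  # 2-voxel pull shift along y moves the ridge 2 voxels
  f2 <- displacement_field(array(2 * 2.3, d3), axis = 2L)
  warped <- apply_displacement(v, f2)
  expect_equal(warped[5, 1, 5], 1)
  expect_equal(sum(warped == 1, na.rm = TRUE), 1L)

  # warp-then-invert: exact for integer-voxel constant shifts ...
  w <- voxel_centers(d3, aff)
  smooth <- as_volume(array(sin(w[, 2] / 7) + 0.3 * cos(w[, 1] / 5), d3),
                      aff)
  f_int <- displacement_field(array(2 * 2.3, d3), axis = 2L)
  back_i <- apply_displacement(apply_displacement(smooth, f_int), f_int,
                               invert = TRUE)
  keep <- !is.na(back_i)
  expect_lt(max(abs(back_i[keep] - smooth[keep])), 1e-12)
  # ... and first-order (interpolation-limited) for fractional shifts
  field <- displacement_field(array(1.5, d3), axis = 2L)
  back <- apply_displacement(apply_displacement(smooth, field), field,
                             invert = TRUE)
  keep <- !is.na(back)
  expect_lt(max(abs(back[keep] - smooth[keep])), 0.05)

  too_far <- displacement_field(array(100 * 2.3, d3))
  expect_error(apply_displacement(v, too_far), "field of view")
})

test_that("alpha calibration solves the anchored ROI statistic", {
  aff <- diag(4)
  d3 <- c(4, 4, 4)
  roi <- array(TRUE, d3)
  # constant MT/density ratio 5.1 with anchor 0.7 -> alpha = 0.51/5.1 = 0.1
  mt <- as_volume(array(5.1, d3), aff)
  dens <- as_volume(array(1, d3), aff)
  cal <- calibrate_alpha(mt, dens, roi, g_reference = 0.7)
  expect_equal(cal$alpha, 0.1, tolerance = 1e-9)
  expect_equal(cal$achieved, 0.7, tolerance = 1e-8)

  # anchor 1 -> alpha 0 without solving
  cal1 <- calibrate_alpha(mt, dens, roi, g_reference = 1)
  expect_equal(cal1$alpha, 0)

  # heterogeneous ROI: root find agrees with an independent optimiser oracle
  set.seed(21)
  ratios <- array(runif(prod(d3), 4.8, 5.4), d3)
  mt2 <- as_volume(ratios, aff)
  cal2 <- calibrate_alpha(mt2, dens, roi, g_reference = 0.7)
  # staged grid-refinement oracle, independent of the root finder
  obj <- function(a) abs(mean(sqrt(pmax(1 - a * ratios, 0))) - 0.7)
  lo <- 0; hi <- 1 / max(ratios)
  for (stage in 1:5) {
    grid <- seq(lo, hi, length.out = 1001)
    i <- which.min(vapply(grid, obj, 0))
    lo <- grid[max(i - 1, 1)]; hi <- grid[min(i + 1, length(grid))]
  }
  oracle <- (lo + hi) / 2
  expect_equal(cal2$alpha, oracle, tolerance = 1e-10)

  # ratio-of-means mode closed form
  cal3 <- calibrate_alpha(mt2, dens, roi, g_reference = 0.7,
                          mode = "ratio-of-means")
  expect_equal(cal3$alpha, (1 - 0.49) / mean(ratios), tolerance = 1e-12)

  # unreachable anchor: with heterogeneous ratios the feasible interval
  # (all radicands >= 0) bottoms out above a too-small g_reference
  expect_error(calibrate_alpha(mt2, dens, roi, g_reference = 0.05),
               "feasible")
  expect_error(calibrate_alpha(mt, dens, array(FALSE, d3)), "empty")
})

test_that("the g map follows the calibrated ratio formula and masks", {
  aff <- diag(4)
  d3 <- c(3, 3, 1)
  mt <- as_volume(array(5.1, d3), aff)
  dens <- as_volume(array(1, d3), aff)
  res <- compute_g_map(mt, dens, 0.1)
  expect_equal(as.numeric(res$g_map), rep(0.7, prod(d3)), tolerance = 1e-12)

  mt0 <- as_volume(array(0, d3), aff)
  expect_equal(as.numeric(compute_g_map(mt0, dens, 0.1)$g_map),
               rep(1, prod(d3)))                         # no myelin

  # negative radicand and non-positive density are masked, never clipped
  mt_hot <- as_volume(array(12, d3), aff)                # alpha*MT/d = 1.2
  res2 <- compute_g_map(mt_hot, dens, 0.1)
  expect_false(any(res2$validity_mask))
  expect_true(all(is.na(res2$g_map)))
  dens0 <- as_volume(array(0, d3), aff)
  expect_false(any(compute_g_map(mt, dens0, 0.1)$validity_mask))
})

test_that("g is monotone in MT and density, and density rescaling is absorbed", {
  aff <- diag(4)
  d3 <- c(4, 4, 4)
  set.seed(8)
  mt <- as_volume(array(runif(prod(d3), 1, 3), d3), aff)
  dens <- as_volume(array(runif(prod(d3), 0.6, 1.4), d3), aff)
  g0 <- compute_g_map(mt, dens, 0.1)$g_map
  g_hi_mt <- compute_g_map(as_volume(unclass(mt) * 1.2, aff), dens,
                           0.1)$g_map
  g_hi_de <- compute_g_map(mt, as_volume(unclass(dens) * 1.2, aff),
                           0.1)$g_map
  expect_true(all(g_hi_mt < g0))
  expect_true(all(g_hi_de > g0))

  # multiply density by c and recalibrate: identical g map (alpha -> c*alpha)
  roi <- array(TRUE, d3)
  cal_a <- calibrate_alpha(mt, dens, roi, g_reference = 0.75)
  dens_c <- as_volume(unclass(dens) * 3.3, aff)
  cal_b <- calibrate_alpha(mt, dens_c, roi, g_reference = 0.75)
  expect_equal(cal_b$alpha, cal_a$alpha * 3.3, tolerance = 1e-9)
  expect_equal(as.numeric(compute_g_map(mt, dens_c, cal_b)$g_map),
               as.numeric(compute_g_map(mt, dens, cal_a)$g_map),
               tolerance = 1e-9)
})
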