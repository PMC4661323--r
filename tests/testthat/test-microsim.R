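test_that("volume fractions follow the nested-circle areas", {
  pop <- fiber_population(outer_radius = 1, g = 0.7, voxel_area = 4)
  vf <- compute_volume_fractions(pop)
  expect_equal(vf$fvf, pi / 4)
  expect_equal(vf$mvf, (1 - 0.49) * pi / 4)
  expect_equal(vf$evf, 1 - pi / 4)

  # unmyelinated fibers contribute nothing to the myelin fraction
  pop2 <- fiber_population(outer_radius = c(1, 2), g = c(1, 1),
                           voxel_area = 50)
  expect_equal(compute_volume_fractions(pop2)$mvf, 0)

  # sampled population with constant g: mvf/fvf = 1 - g^2 to machine precision
  pop3 <- sample_population(50, g_distribution = list(name = "constant",
                                                      value = 0.7),
                            target_fvf = 0.5, seed = 7)
  vf3 <- compute_volume_fractions(pop3)
  expect_equal(vf3$mvf / vf3$fvf, 0.51, tolerance = 1e-14)
  expect_equal(vf3$fvf, 0.5, tolerance = 1e-12)
})

test_that("populations that overflow the voxel are rejected", {
  expect_error(fiber_population(10, 0.7, voxel_area = 4), "overflow")
  expect_error(fiber_population(1, 0, 4), "g-ratios")
  expect_error(fiber_population(-1, 0.7, 4), "radii")
  expect_error(compute_volume_fractions(
    structure(list(fibers = tibble::tibble(), voxel_area = 1),
              class = "fiber_population")), "empty")
})

test_that("microscopic mean g is the plain average", {
  pop <- fiber_population(c(5, 0.1), c(0.6, 0.8), voxel_area = 100)
  expect_equal(microscopic_mean_g(pop), 0.7)
  pop2 <- sample_population(200, g_distribution = list(name = "constant",
                                                       value = 0.7),
                            seed = 2)
  expect_equal(microscopic_mean_g(pop2), 0.7)
})

test_that("area-weighted RMS g matches its closed forms", {
  pop <- fiber_population(c(1, 1), c(0.6, 0.8), voxel_area = 100)
  expect_equal(area_weighted_rms_g(pop), sqrt(0.5))
  pop2 <- fiber_population(c(0.3, 1.2, 2), rep(0.7, 3), voxel_area = 100)
  expect_equal(area_weighted_rms_g(pop2), 0.7)
})

test_that("sqrt(1 - MVF/FVF) equals the area-weighted RMS g identically", {
  for (seed in 1:20) {
    pop <- sample_population(
      100,
      radius_distribution = list(name = "lognormal", median = 0.6,
                                 sigma = 0.5),
      g_distribution = list(name = "mixture", mean = 0.65, sd = 0.08,
                            unmyelinated_fraction = 0.2),
      target_fvf = 0.55, seed = seed)
    vf <- compute_volume_fractions(pop)
    expect_equal(mr_g_from_fractions(vf), area_weighted_rms_g(pop),
                 tolerance = 1e-12)
  }
})

test_that("constant-g populations make the MR and microscopic g coincide", {
  for (seed in 1:5) {
    pop <- sample_population(80, g_distribution = list(name = "constant",
                                                       value = 0.72),
                             target_fvf = 0.6, seed = seed)
    expect_equal(mr_g_from_fractions(compute_volume_fractions(pop)),
                 microscopic_mean_g(pop))
  }
})

test_that("MR g exceeds the area-weighted mean when g varies (Jensen)", {
  for (seed in 1:10) {
    pop <- sample_population(
      200, g_distribution = list(name = "mixture", mean = 0.6, sd = 0.05,
                                 unmyelinated_fraction = 0.25),
      target_fvf = 0.5, seed = seed)
    r2 <- pop$fibers$outer_radius^2
    aw_mean <- sum(pop$fibers$g * r2) / sum(r2)
    expect_gt(area_weighted_rms_g(pop), aw_mean)
    # an unmyelinated pool drags the aggregate above the myelinated pool
    myelinated_mean <- mean(pop$fibers$g[pop$fibers$g < 1])
    expect_gt(mr_g_from_fractions(compute_volume_fractions(pop)),
              myelinated_mean)
  }
})

test_that("mr_g_from_fractions honours its limits and domain", {
  expect_equal(mr_g_from_fractions(mvf = 0.51 * 0.3, fvf = 0.3), 0.7)
  expect_equal(mr_g_from_fractions(mvf = 0, fvf = 0.5), 1)     # unmyelinated
  expect_equal(mr_g_from_fractions(mvf = 0.5, fvf = 0.5), 0)   # fully myelinated
  expect_error(mr_g_from_fractions(mvf = 0.1, fvf = 0), "fvf")
  expect_error(mr_g_from_fractions(mvf = 0.6, fvf = 0.5), "mvf")
})

test_that("population sampling is reproducible and hits its targets", {
  spec_args <- list(n_fibers = 500,
                    g_distribution = list(name = "constant", value = 0.7),
                    target_fvf = 0.6, seed = 11)
  p1 <- do.call(sample_population, spec_args)
  p2 <- do.call(sample_population, spec_args)
  expect_identical(p1$fibers, p2$fibers)
  expect_equal(compute_volume_fractions(p1)$fvf, 0.6, tolerance = 1e-9)

  # unmyelinated fraction realised within binomial sampling error
  n <- 10000
  p3 <- sample_population(
    n, g_distribution = list(name = "mixture", mean = 0.65, sd = 0.05,
                             unmyelinated_fraction = 0.2),
    target_fvf = 0.4, seed = 3)
  frac <- mean(p3$fibers$g == 1)
  ci_half <- 4 * sqrt(0.2 * 0.8 / n)
  expect_lt(abs(frac - 0.2), ci_half)

  expect_error(sample_population(10, target_fvf = 0.95), "packing")
})

test_that("fiber populations round-trip through TSV", {
  pop <- sample_population(20, seed = 9, target_fvf = 0.5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_population_tsv(pop, path)
  back <- read_population_tsv(path, voxel_area = pop$voxel_area)
  expect_equal(back$fibers$outer_radius, pop$fibers$outer_radius,
               tolerance = 1e-12)
  expect_equal(back$fibers$g, pop$fibers$g, tolerance = 1e-12)
})

test_that("Rushton velocity factor peaks at 1/sqrt(e) and vanishes at g = 1", {
  opt <- optimal_g_ratio()
  expect_equal(opt$g_opt, exp(-0.5), tolerance = 1e-6)
  expect_equal(round(opt$g_opt, 1), 0.6)
  expect_equal(opt$f_max, 1 / sqrt(2 * exp(1)), tolerance = 1e-9)
  expect_lt(conduction_velocity_factor(1 - 1e-8), 1e-3)
  expect_error(conduction_velocity_factor(1), "strictly")
  expect_error(conduction_velocity_factor(0), "strictly")

  # unimodal on a dense grid: increasing then decreasing around the peak
  g <- seq(0.01, 0.99, by = 1e-3)
  f <- conduction_velocity_factor(g)
  d <- diff(f)
  expect_equal(sum(diff(sign(d)) != 0), 1L)
})
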