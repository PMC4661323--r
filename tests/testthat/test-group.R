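aff <- diag(c(2, 2, 2, 1))

const_map <- function(value, d3 = c(4, 4, 4)) as_volume(array(value, d3), aff)

test_that("group summary computes mean, SD and CoV per voxel", {
  stack <- group_stack(list(const_map(0.63), const_map(0.7),
                            const_map(0.77)))
  gs <- group_summary(stack)
  expect_equal(unique(as.numeric(gs$mean_map)), 0.7)
  expect_equal(unique(as.numeric(gs$sd_map)), 0.07, tolerance = 1e-12)
  expect_equal(unique(as.numeric(gs$cov_map)), 0.1, tolerance = 1e-12)
  expect_equal(unique(as.numeric(gs$n_valid_map)), 3)

  # identical subjects: sd = cov = 0, mean = the map
  gs2 <- group_summary(group_stack(list(const_map(0.5), const_map(0.5))))
  expect_equal(unique(as.numeric(gs2$sd_map)), 0)
  expect_equal(unique(as.numeric(gs2$cov_map)), 0)

  # voxels valid in < 2 subjects are invalid
  m1 <- const_map(0.7); m1[1, 1, 1] <- NA
  m2 <- const_map(0.7); m2[1, 1, 1] <- NA
  m3 <- const_map(0.7)
  gs3 <- group_summary(group_stack(list(m1, m2, m3)))
  expect_true(is.na(gs3$mean_map[1, 1, 1]))
  expect_equal(gs3$n_valid_map[1, 1, 1], 1)
})

test_that("CoV masking is strict at the threshold and monotone", {
  m1 <- const_map(1); m1[1, 1, 1] <- 0.7
  m2 <- const_map(1); m2[1, 1, 1] <- 1.3
  gs <- group_summary(group_stack(list(m1, m2)))
  # that voxel has cov = 0.3 * sqrt(2)/... compute directly
  cov_val <- gs$cov_map[1, 1, 1]
  mask_at <- cov_threshold_mask(gs, threshold = cov_val)
  expect_false(mask_at[1, 1, 1])                 # strict <
  mask_above <- cov_threshold_mask(gs, threshold = cov_val + 1e-9)
  expect_true(mask_above[1, 1, 1])
  # monotone: raising the threshold never removes voxels
  expect_true(all(mask_at[cov_threshold_mask(gs, 0.01)]))
})

test_that("cohort CoV is consistent with the imposed between-subject SD", {
  n <- 37
  d3 <- c(12, 12, 12)
  mu <- 0.7; sigma <- 0.07
  set.seed(37)
  maps <- lapply(seq_len(n), function(i)
    as_volume(array(rnorm(prod(d3), mu, sigma), d3), aff))
  gs <- group_summary(group_stack(maps))
  # (n-1) s^2 / sigma^2 ~ chi^2_{n-1}: check central 99% coverage
  stat <- (n - 1) * as.numeric(gs$sd_map)^2 / sigma^2
  inside <- mean(stat > qchisq(0.005, n - 1) & stat < qchisq(0.995, n - 1))
  expect_gt(inside, 0.975)
  expect_lt(abs(median(as.numeric(gs$cov_map)) - sigma / mu), 0.01)
})

test_that("white-matter histograms conserve counts and honour masks", {
  m <- const_map(0.7)
  wm <- array(TRUE, c(4, 4, 4))
  h <- wm_histogram(m, wm, bins = 64)
  expect_equal(sum(h$count > 0), 1L)
  expect_equal(sum(h$count), sum(wm))
  expect_equal(nrow(h), 64L)

  set.seed(2)
  m2 <- as_volume(array(runif(64, 0.2, 0.9), c(4, 4, 4)), aff)
  cov_mask <- array(runif(64) < 0.5, c(4, 4, 4))
  h_all <- wm_histogram(m2, wm)
  h_res <- wm_histogram(m2, wm, cov_mask)
  expect_equal(sum(h_res$count), sum(cov_mask))
  # restricted support contained in unrestricted support
  expect_true(all(h_all$count[h_res$count > 0] > 0))
  expect_error(wm_histogram(m2, array(FALSE, c(4, 4, 4))), "empty")
})

test_that("corpus-callosum parcellation partitions equidistant AP intervals", {
  d3 <- c(8, 40, 8)
  mask <- array(FALSE, d3)
  mask[4:5, 1:40, 4:5] <- TRUE                   # beam along y = A-P
  vol <- as_volume(mask, diag(c(2, 2, 2, 1)))
  parc <- parcellate_cc(vol, n_intervals = 8L)
  labs <- parc[mask]
  expect_setequal(unique(labs), 1:8)
  expect_true(all(parc[!mask] == 0))
  expect_equal(sum(parc > 0), sum(mask))         # partition
  # equal-width world intervals -> 5 y-planes each at 40 planes / 8
  counts <- table(labs)
  expect_true(all(counts == sum(mask) / 8))
  # posterior labelling: smallest world y gets label 1
  ys <- which(apply(parc == 1, 2, any))
  expect_true(all(ys <= 5))
  # anterior labelling flips the order
  parc_a <- parcellate_cc(vol, 8L, labels_from = "anterior")
  expect_equal(as.integer(parc_a[mask]), 9L - as.integer(labs))

  thin <- array(FALSE, d3); thin[4, 3:6, 4] <- TRUE
  expect_error(parcellate_cc(as_volume(thin, diag(c(2, 2, 2, 1))), 8L),
               "planes")
})

test_that("parcellation counts match a brute-force geometric oracle", {
  s <- noiseless_subject()
  parc <- parcellate_cc(s$cc_mask, 8L)
  aff_d <- vol_affine(s$cc_mask)
  vox <- which(as.logical(s$cc_mask))
  sub <- arrayInd(vox, dim(s$cc_mask)[1:3]) - 1L
  y <- (aff_d %*% rbind(t(sub), 1))[2, ]
  width <- (max(y) - min(y)) / 8
  lab_oracle <- pmin(floor((y - min(y)) / width) + 1, 8)
  expect_equal(as.integer(parc[vox]), as.integer(lab_oracle))
})

test_that("tract ROIs are inclusive-threshold conjunctions with size flags", {
  d3 <- c(6, 6, 6)
  p <- array(0, d3); p[1:3, , ] <- 0.5; p[4, , ] <- 0.8
  prob <- as_volume(p, aff)
  cov_mask <- array(TRUE, d3); cov_mask[, 1, ] <- FALSE
  roi <- tract_roi(prob, 0.5, cov_mask)
  oracle <- (p >= 0.5) & cov_mask
  expect_equal(as.logical(roi), as.vector(oracle))
  expect_equal(attr(roi, "n_voxels"), sum(oracle))
  expect_false(attr(roi, "flagged_small"))       # 120 voxels >= 100

  empty <- tract_roi(as_volume(array(0, d3), aff))
  expect_true(attr(empty, "flagged_small"))
  expect_equal(attr(empty, "n_voxels"), 0L)
})

test_that("ROI statistics follow the subject-then-group convention", {
  m1 <- const_map(0.6); m2 <- const_map(0.8)
  stack <- group_stack(list(m1, m2), c("a", "b"))
  single <- array(FALSE, c(4, 4, 4)); single[2, 2, 2] <- TRUE
  rois <- list(point = single, all = array(TRUE, c(4, 4, 4)))
  rs <- roi_statistics(stack, rois)
  point <- dplyr::filter(rs$table, roi == "point")
  expect_equal(point$mean, c(0.6, 0.8))
  expect_equal(point$sd, c(0, 0))
  expect_equal(point$n_voxels, c(1L, 1L))
  smry <- dplyr::filter(rs$summary, roi == "all")
  expect_equal(smry$group_mean, 0.7)
  expect_equal(smry$mean_within_sd, 0)           # constant maps
  expect_equal(smry$between_subject_sd, sd(c(0.6, 0.8)))

  # an all-invalid subject/ROI row is dropped with a warning
  m3 <- const_map(0.7); m3[2, 2, 2] <- NA
  stack2 <- group_stack(list(m1, m3), c("a", "c"))
  expect_warning(rs2 <- roi_statistics(stack2, rois["point"]), "dropped")
  expect_equal(nrow(rs2$table), 1L)
})

test_that("tract contrasts match ANOVA and Welch-t oracles", {
  # 3-subject toy table with a hand-computable t statistic
  tab <- tibble::tibble(
    roi = rep(c("cst", "or"), each = 3),
    subject = rep(c("s1", "s2", "s3"), 2),
    mean = c(0.70, 0.72, 0.68, 0.60, 0.63, 0.66))
  res <- tract_contrasts(tab, reference_tract = "cst")
  x <- tab$mean[4:6]; y <- tab$mean[1:3]
  se <- sqrt(var(x) / 3 + var(y) / 3)
  t_oracle <- (mean(x) - mean(y)) / se
  expect_equal(res$posthoc$t, t_oracle, tolerance = 1e-12)
  df_oracle <- se^4 / ((var(x) / 3)^2 / 2 + (var(y) / 3)^2 / 2)
  expect_equal(res$posthoc$df, df_oracle, tolerance = 1e-9)
  expect_equal(res$anova$p_value,
               summary(aov(mean ~ roi, data = tab))[[1]]$`Pr(>F)`[1])

  # clear separation is flagged
  tab2 <- tibble::tibble(
    roi = rep(c("cst", "low"), each = 4), subject = rep(paste0("s", 1:4), 2),
    mean = c(0.70, 0.701, 0.699, 0.7, 0.60, 0.601, 0.599, 0.6))
  res2 <- tract_contrasts(tab2, "cst")
  expect_true(res2$posthoc$smaller_than_reference)
  expect_identical(tidy_contrasts(res2), res2$posthoc)
  expect_identical(glance_contrasts(res2), res2$anova)

  expect_error(tract_contrasts(tab, "missing"), "not in table")
})

test_that("type-I error of the tract contrasts is near nominal under the null", {
  set.seed(123)
  n_rep <- 300
  flags <- 0; tests <- 0; anova_hits <- 0
  for (r in seq_len(n_rep)) {
    tab <- tibble::tibble(
      roi = rep(c("cst", "or", "slf", "cing"), each = 10),
      subject = rep(paste0("s", 1:10), 4),
      mean = rnorm(40, 0.65, 0.03))
    res <- tract_contrasts(tab, "cst")
    flags <- flags + sum(res$posthoc$p_value < 0.05)
    tests <- tests + nrow(res$posthoc)
    anova_hits <- anova_hits + (res$anova$p_value < 0.05)
  }
  rate <- flags / tests
  expect_gt(rate, 0.03); expect_lt(rate, 0.07)
  expect_gt(anova_hits / n_rep, 0.02); expect_lt(anova_hits / n_rep, 0.09)
})

test_that("MT-density correlations recover known dependence", {
  d3 <- c(4, 4, 4)
  ids <- paste0("s", 1:4)
  mt_vals <- c(1.8, 2.0, 2.2, 2.6)
  mt_stack <- group_stack(lapply(mt_vals, const_map), ids)
  de_stack <- group_stack(lapply(2 * mt_vals, const_map), ids)
  rois <- list(wm = array(TRUE, d3))
  tab <- mt_density_correlation(mt_stack, de_stack, rois)
  expect_equal(tab$r, 1, tolerance = 1e-12)

  # a printed toy table against the closed-form Pearson oracle
  de_vals <- c(1.1, 0.9, 1.4, 1.2)
  de2 <- group_stack(lapply(de_vals, const_map), ids)
  tab2 <- mt_density_correlation(mt_stack, de2, rois)
  r_oracle <- sum((mt_vals - mean(mt_vals)) * (de_vals - mean(de_vals))) /
    sqrt(sum((mt_vals - mean(mt_vals))^2) * sum((de_vals - mean(de_vals))^2))
  expect_equal(tab2$r, r_oracle, tolerance = 1e-12)
  expect_equal(tab2$n, 4L)

  # independent draws: correlation centred at zero
  set.seed(5)
  rs <- replicate(60, {
    a <- group_stack(lapply(rnorm(6, 2, 0.3), const_map), paste0("x", 1:6))
    b <- group_stack(lapply(rnorm(6, 1, 0.2), const_map), paste0("x", 1:6))
    mt_density_correlation(a, b, rois)$r
  })
  expect_lt(abs(mean(rs)), 0.15)
})
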