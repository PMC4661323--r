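#' A cohort stack of co-registered subject maps
#'
#' One modality (g, MT, density, FA, ...) across subjects, already in a
#' common space. Per-subject validity is carried as NA voxels.
#'
#' @param maps list of 3-D `gvol`s (or arrays), one per subject, on one
#'   grid.
#' @param subject_ids character vector (default S1, S2, ...).
#' @return a `group_stack`: 4-D array (x, y, z, subject) + ids.
#' @export
group_stack <- function(maps, subject_ids = NULL) {
  if (length(maps) < 2L) stop("need at least 2 subjects")
  d3 <- dim(maps[[1]])[1:3]
  for (m in maps[-1])
    if (!same_grid(maps[[1]], m)) stop("subject maps are not on one grid")
  if (is.null(subject_ids)) subject_ids <- paste0("S", seq_along(maps))
  if (length(subject_ids) != length(maps))
    stop("subject_ids length mismatch")
  arr <- array(NA_real_, c(d3, length(maps)))
  for (s in seq_along(maps)) arr[, , , s] <- as.numeric(maps[[s]])
  structure(list(data = as_volume(arr, vol_affine(maps[[1]])),
                 subject_ids = subject_ids),
            class = "group_stack")
}

#' Voxel-wise cohort summary: mean, SD, CoV
#'
#' Computed over the subjects valid (non-NA) at each voxel: sample mean,
#' sample SD (n - 1 denominator), and the coefficient of variation CoV =
#' SD / mean where the mean is positive. Voxels with fewer than 2 valid
#' subjects are invalid.
#'
#' @param stack a [group_stack()].
#' @return a `group_summary`: `mean_map`, `sd_map`, `cov_map`,
#'   `n_valid_map` (all 3-D `gvol`s).
#' @export
group_summary <- function(stack) {
  stopifnot(inherits(stack, "group_stack"))
  arr <- stack$data
  d3 <- dim(arr)[1:3]; ns <- dim(arr)[4]
  flat <- matrix(arr, ncol = ns)
  ok <- is.finite(flat)
  n <- rowSums(ok)
  x <- flat; x[!ok] <- 0
  s1 <- rowSums(x)
  mu <- ifelse(n >= 2, s1 / n, NA_real_)
  ss <- rowSums((x - ifelse(is.na(mu), 0, mu))^2 * ok)
  sdv <- ifelse(n >= 2, sqrt(ss / pmax(n - 1, 1)), NA_real_)
  cov <- ifelse(!is.na(mu) & mu > 0, sdv / mu, NA_real_)
  aff <- vol_affine(arr)
  structure(
    list(mean_map = as_volume(array(mu, d3), aff),
         sd_map = as_volume(array(sdv, d3), aff),
         cov_map = as_volume(array(cov, d3), aff),
         n_valid_map = as_volume(array(n, d3), aff)),
    class = "group_summary"
  )
}

#' Reliability mask from the CoV map
#'
#' Voxels where the between-subject coefficient of variation is strictly
#' below the threshold (default 0.3) and the summary is valid. Used to
#' exclude unreliable estimates at white-matter edges before ROI analyses.
#'
#' @param summary a [group_summary()].
#' @param threshold strict upper bound on CoV, default 0.3.
#' @return 3-D logical `gvol`.
#' @export
cov_threshold_mask <- function(summary, threshold = 0.3) {
  stopifnot(inherits(summary, "group_summary"))
  cov <- as.numeric(summary$cov_map)
  m <- is.finite(cov) & cov < threshold
  inherit_affine(array(m, dim(summary$cov_map)[1:3]), summary$cov_map)
}

#' White-matter histogram of a mean map
#'
#' Bin counts of the voxel values inside the white-matter mask, optionally
#' further restricted to a reliability (CoV) mask. Default 64 bins on
#' \[0, 1\]; bins are left-closed, the last bin closed on both sides.
#'
#' @param mean_map 3-D `gvol` (e.g. the cohort mean g map).
#' @param wm_mask 3-D logical mask.
#' @param cov_mask optional additional logical mask.
#' @param bins number of bins, default 64.
#' @param range histogram range, default `c(0, 1)`.
#' @return tibble with `bin`, `lower`, `upper`, `count`.
#' @export
wm_histogram <- function(mean_map, wm_mask, cov_mask = NULL, bins = 64L,
                         range = c(0, 1)) {
  m <- wm_mask & is.finite(as.vector(mean_map))
  if (!is.null(cov_mask)) m <- m & cov_mask
  vals <- as.numeric(mean_map)[which(m)]
  if (!length(vals)) stop("empty mask: nothing to histogram")
  edges <- seq(range[1], range[2], length.out = bins + 1L)
  cut_idx <- findInterval(vals, edges, rightmost.closed = TRUE,
                          all.inside = FALSE)
  cut_idx[cut_idx < 1L | cut_idx > bins] <- NA_integer_
  counts <- tabulate(cut_idx, nbins = bins)
  tibble::tibble(bin = seq_len(bins), lower = edges[-(bins + 1L)],
                 upper = edges[-1L], count = counts)
}

# voxel axis of the grid that carries the world anterior-posterior (y)
# direction, with its sign
ap_axis_from_affine <- function(affine) {
  R <- affine[1:3, 1:3]
  ax <- which.max(abs(R[2, ]))  # world y row
  list(axis = ax, sign = sign(R[2, ax]))
}

#' Parcellate a corpus-callosum mask along anterior-posterior
#'
#' Splits the mask into `n_intervals` (default 8) equidistant intervals of
#' world-space anterior-posterior extent — equal width in millimetres, not
#' voxel counts — spanning the mask's A-P bounding range. Every mask voxel
#' receives exactly one label; labels run 1..n from posterior to anterior
#' by default.
#'
#' @param cc_mask 3-D logical `gvol` of the corpus callosum.
#' @param n_intervals number of intervals, default 8.
#' @param labels_from `"posterior"` (default) or `"anterior"`.
#' @return integer 3-D `gvol`, 0 outside the mask, labels 1..n inside.
#' @export
parcellate_cc <- function(cc_mask, n_intervals = 8L,
                          labels_from = c("posterior", "anterior")) {
  labels_from <- match.arg(labels_from)
  if (!any(cc_mask)) stop("corpus-callosum mask is empty")
  aff <- vol_affine(cc_mask)
  d3 <- dim(cc_mask)[1:3]
  vox <- which(cc_mask)
  sub <- arrayInd(vox, d3) - 1L
  y <- (aff %*% rbind(t(sub), 1))[2, ]  # world A-P coordinate
  rng <- range(y)
  ap_vox <- length(unique(round(y / voxel_size(aff)[ap_axis_from_affine(aff)$axis], 6)))
  if (ap_vox < n_intervals)
    stop(sprintf("mask spans only %d voxel planes along A-P; need >= %d",
                 ap_vox, n_intervals))
  width <- (rng[2] - rng[1]) / n_intervals
  lab <- pmin(floor((y - rng[1]) / width) + 1L, n_intervals)  # top edge -> n
  if (labels_from == "anterior") lab <- n_intervals + 1L - lab
  out <- array(0L, d3)
  out[vox] <- as.integer(lab)
  as_volume(out, aff)
}

#' Tract ROI from a probabilistic atlas map
#'
#' Conjunction of the probabilistic tract map thresholded at
#' `prob_threshold` (inclusive, default 50%) and the reliability mask.
#' ROIs smaller than `min_voxels` (default 100) are flagged — the
#' convention under which small tracts are excluded from reporting.
#'
#' @param prob_map 3-D `gvol` of probabilities in \[0, 1\].
#' @param prob_threshold inclusive threshold, default 0.5.
#' @param cov_mask optional logical reliability mask.
#' @param min_voxels flag threshold, default 100.
#' @return logical 3-D `gvol` with attributes `n_voxels` and
#'   `flagged_small`.
#' @export
tract_roi <- function(prob_map, prob_threshold = 0.5, cov_mask = NULL,
                      min_voxels = 100L) {
  p <- as.numeric(prob_map)
  if (any(p < -1e-9 | p > 1 + 1e-9, na.rm = TRUE))
    stop("probability map values must lie in [0, 1]")
  m <- is.finite(p) & p >= prob_threshold
  m <- array(m, dim(prob_map)[1:3])
  if (!is.null(cov_mask)) m <- m & cov_mask
  out <- inherit_affine(m, prob_map)
  attr(out, "n_voxels") <- sum(m)
  attr(out, "flagged_small") <- sum(m) < min_voxels
  out
}

as_roi_list <- function(rois) {
  if (is.list(rois)) {
    if (is.null(names(rois))) names(rois) <- paste0("roi", seq_along(rois))
    lapply(rois, function(r) array(as.logical(r), dim(r)[1:3]))
  } else {
    # labelled parcellation array
    labs <- sort(unique(as.integer(rois[rois > 0])))
    out <- lapply(labs, function(l) array(rois == l, dim(rois)[1:3]))
    names(out) <- paste0("roi", labs)
    out
  }
}

#' Per-subject, per-ROI summary table
#'
#' For each subject and ROI: the mean, SD and count of valid voxels.
#' The group summary follows the ex-vivo comparison convention — the
#' within-ROI SD is computed per subject first and then averaged across the
#' group (mode `"subject-then-group"`, default); `"group-across-roi"`
#' additionally reports the across-subject SD of the subject means.
#'
#' @param stack a [group_stack()].
#' @param rois named list of logical masks, or an integer-labelled
#'   parcellation volume.
#' @param mode summary convention, see above.
#' @return list with `table` (tibble: roi, subject, mean, sd, n_voxels) and
#'   `summary` (tibble per ROI: group_mean, mean_within_sd,
#'   between_subject_sd, n_subjects).
#' @export
roi_statistics <- function(stack, rois,
                           mode = c("subject-then-group",
                                    "group-across-roi")) {
  mode <- match.arg(mode)
  stopifnot(inherits(stack, "group_stack"))
  rois <- as_roi_list(rois)
  d3 <- dim(stack$data)[1:3]
  for (r in rois) if (!all(dim(r) == d3)) stop("ROI grid mismatch")
  rows <- list()
  for (rn in names(rois)) {
    idx <- which(rois[[rn]])
    if (!length(idx)) stop("ROI '", rn, "' is empty")
    for (s in seq_along(stack$subject_ids)) {
      v <- stack$data[, , , s][idx]
      v <- v[is.finite(v)]
      if (!length(v)) {
        warning("ROI '", rn, "' entirely invalid for subject ",
                stack$subject_ids[s], "; row dropped")
        next
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        roi = rn, subject = stack$subject_ids[s],
        mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0,
        n_voxels = length(v))
    }
  }
  table <- dplyr::bind_rows(rows)
  summary <- table |>
    dplyr::group_by(.data$roi) |>
    dplyr::summarise(
      group_mean = mean(.data$mean),
      mean_within_sd = mean(.data$sd),
      between_subject_sd = stats::sd(.data$mean),
      n_subjects = dplyr::n(),
      .groups = "drop")
  list(table = table, summary = summary, mode = mode)
}

#' ANOVA and post-hoc contrasts across tract ROIs
#'
#' One-way ANOVA on subject-level tract means (does the g-ratio differ
#' between tracts?), followed by one-sided two-sample Welch t-tests of each
#' tract against a reference tract (is this tract's g-ratio smaller than
#' the reference's, e.g. the cortico-spinal tract?). P-values are
#' uncorrected and flagged at `alpha_level` (default 0.05).
#'
#' @param table ROI table from [roi_statistics()] (columns roi, subject,
#'   mean).
#' @param reference_tract name of the reference ROI.
#' @param alpha_level flag threshold, default 0.05.
#' @return list with `anova` (tibble: statistic, df1, df2, p_value) and
#'   `posthoc` (tibble: roi, t, df, p_value, smaller_than_reference).
#' @export
tract_contrasts <- function(table, reference_tract, alpha_level = 0.05) {
  if (!reference_tract %in% table$roi)
    stop("reference tract '", reference_tract, "' not in table")
  tr <- unique(table$roi)
  if (length(tr) < 2L) stop("need at least 2 tracts")
  if (min(table(table$roi)) < 3L) stop("need at least 3 subjects per tract")
  if (all(stats::aggregate(mean ~ roi, table, stats::var)$mean == 0))
    stop("degenerate input: zero variance in every tract")
  fit <- stats::aov(mean ~ roi, data = as.data.frame(table))
  an <- summary(fit)[[1]]
  anova_tbl <- tibble::tibble(
    statistic = an$`F value`[1], df1 = an$Df[1], df2 = an$Df[2],
    p_value = an$`Pr(>F)`[1])
  ref <- table$mean[table$roi == reference_tract]
  rows <- lapply(setdiff(tr, reference_tract), function(rn) {
    x <- table$mean[table$roi == rn]
    tt <- stats::t.test(x, ref, alternative = "less")
    tibble::tibble(roi = rn, t = unname(tt$statistic),
                   df = unname(tt$parameter), p_value = tt$p.value,
                   smaller_than_reference = tt$p.value < alpha_level)
  })
  list(anova = anova_tbl, posthoc = dplyr::bind_rows(rows),
       reference = reference_tract, alpha_level = alpha_level)
}

#' Per-ROI correlation of MT and fiber density across subjects
#'
#' For each ROI: the subject-wise ROI means of MT and density are
#' correlated across the cohort (Pearson), with a two-sided significance
#' test.
#'
#' @param mt_stack,density_stack [group_stack()]s of the two modalities on
#'   one grid, same subjects.
#' @param rois named mask list or labelled parcellation.
#' @return tibble with `roi`, `r`, `p_value`, `n`.
#' @export
mt_density_correlation <- function(mt_stack, density_stack, rois) {
  stopifnot(inherits(mt_stack, "group_stack"),
            inherits(density_stack, "group_stack"))
  if (!identical(mt_stack$subject_ids, density_stack$subject_ids))
    stop("stacks hold different subjects")
  if (length(mt_stack$subject_ids) < 3L) stop("need at least 3 subjects")
  mt_tab <- roi_statistics(mt_stack, rois)$table
  de_tab <- roi_statistics(density_stack, rois)$table
  joined <- dplyr::inner_join(
    mt_tab[, c("roi", "subject", "mean")],
    de_tab[, c("roi", "subject", "mean")],
    by = c("roi", "subject"), suffix = c("_mt", "_density"))
  joined |>
    dplyr::group_by(.data$roi) |>
    dplyr::group_modify(function(df, key) {
      if (stats::sd(df$mean_mt) == 0 || stats::sd(df$mean_density) == 0)
        stop("zero variance in ROI '", key$roi, "'")
      ct <- stats::cor.test(df$mean_mt, df$mean_density, method = "pearson")
      tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value,
                     n = nrow(df))
    }) |>
    dplyr::ungroup()
}
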