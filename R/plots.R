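#' Plot a white-matter histogram
#'
#' Bar plot of the bin counts produced by [wm_histogram()], optionally
#' overlaying a second (e.g. CoV-restricted) histogram for comparison.
#'
#' @param hist_tbl tibble from [wm_histogram()].
#' @param restricted optional second histogram tibble.
#' @return a ggplot object.
#' @export
plot_wm_histogram <- function(hist_tbl, restricted = NULL) {
  hist_tbl$which <- "all WM"
  df <- hist_tbl
  if (!is.null(restricted)) {
    restricted$which <- "CoV-restricted"
    df <- dplyr::bind_rows(hist_tbl, restricted)
  }
  ggplot2::ggplot(df, ggplot2::aes(
    x = (.data$lower + .data$upper) / 2, y = .data$count,
    fill = .data$which)) +
    ggplot2::geom_col(position = "identity", alpha = 0.6, width =
                        df$upper[1] - df$lower[1]) +
    ggplot2::labs(x = "mean MR g-ratio", y = "voxels", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a ROI profile with error bars
#'
#' Group mean with the group-averaged within-ROI SD per ROI — the display
#' convention used for corpus-callosum parcel profiles.
#'
#' @param roi_summary `summary` tibble from [roi_statistics()].
#' @return a ggplot object.
#' @export
plot_roi_profile <- function(roi_summary) {
  ggplot2::ggplot(roi_summary, ggplot2::aes(x = .data$roi,
                                            y = .data$group_mean)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$group_mean - .data$mean_within_sd,
      ymax = .data$group_mean + .data$mean_within_sd), width = 0.2) +
    ggplot2::labs(x = NULL, y = "MR g-ratio") +
    ggplot2::theme_minimal()
}

#' Middle axial slice of a volume as a ggplot raster
#' @param volume 3-D `gvol`.
#' @param slice slice index (default: middle along z).
#' @return a ggplot object.
#' @export
plot_slice <- function(volume, slice = NULL) {
  d <- dim(volume)[1:3]
  if (is.null(slice)) slice <- ceiling(d[3] / 2)
  sl <- volume[, , slice]
  df <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]))
  df$value <- as.vector(sl)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::theme_void()
}

#' Tidy summaries of fitted objects
#'
#' `tidy()` returns the per-ROI post-hoc table of a [tract_contrasts()]
#' result; `glance()` its one-row ANOVA summary.
#'
#' @param x a `tract_contrasts` result list.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy_contrasts <- function(x, ...) x$posthoc

#' @rdname tidy_contrasts
#' @export
glance_contrasts <- function(x, ...) x$anova
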