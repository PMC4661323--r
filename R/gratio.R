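#' Resample a volume onto a target grid
#'
#' World-space resampling: each target voxel center is mapped through the
#' target affine into world coordinates and back through the inverse source
#' affine into continuous source indices, where the value is interpolated
#' trilinearly (default) or by nearest neighbour. Target voxels that fall
#' outside the source field of view become NA. Used to bring the
#' fine-resolution MT map onto the coarser diffusion grid before the
#' g-ratio is formed.
#'
#' @param volume 3-D `gvol` (source affine taken from it unless overridden).
#' @param target_dim integer length-3 target grid shape.
#' @param target_affine 4x4 target voxel-to-world matrix.
#' @param method `"trilinear"` or `"nearest"`.
#' @param source_affine optional override of the source affine.
#' @return 3-D `gvol` on the target grid.
#' @export
resample_to_grid <- function(volume, target_dim, target_affine,
                             method = c("trilinear", "nearest"),
                             source_affine = NULL) {
  method <- match.arg(method)
  src_aff <- validate_affine(
    if (is.null(source_affine)) vol_affine(volume) else source_affine)
  tgt_aff <- validate_affine(target_affine)
  target_dim <- as.integer(target_dim)
  src <- array(as.numeric(volume), dim(volume)[1:3])
  sd3 <- dim(src)

  if (all(sd3 == target_dim) && max(abs(src_aff - tgt_aff)) <= 1e-9)
    return(as_volume(src, tgt_aff))  # identical grids: exact copy

  # continuous 0-based source indices of all target voxel centers
  M <- solve(src_aff) %*% tgt_aff
  idx <- as.matrix(expand.grid(i = 0:(target_dim[1] - 1L),
                               j = 0:(target_dim[2] - 1L),
                               k = 0:(target_dim[3] - 1L)))
  s <- t(M %*% rbind(t(idx), 1))[, 1:3, drop = FALSE]

  out <- interp3(src, s, method)
  as_volume(array(out, target_dim), tgt_aff)
}

# trilinear / nearest interpolation at continuous 0-based indices (n x 3)
interp3 <- function(src, s, method = "trilinear") {
  sd3 <- dim(src)
  if (method == "nearest") {
    ni <- round(s)
    ok <- ni[, 1] >= 0 & ni[, 1] <= sd3[1] - 1 &
          ni[, 2] >= 0 & ni[, 2] <= sd3[2] - 1 &
          ni[, 3] >= 0 & ni[, 3] <= sd3[3] - 1
    out <- rep(NA_real_, nrow(s))
    out[ok] <- src[cbind(ni[ok, 1] + 1, ni[ok, 2] + 1, ni[ok, 3] + 1)]
    return(out)
  }
  f <- floor(s)
  w <- s - f
  ok <- f[, 1] >= 0 & f[, 1] <= sd3[1] - 2 + 1e-12 &
        f[, 2] >= 0 & f[, 2] <= sd3[2] - 2 + 1e-12 &
        f[, 3] >= 0 & f[, 3] <= sd3[3] - 2 + 1e-12
  # allow points exactly on the upper face
  hi <- s[, 1] >= sd3[1] - 1 - 1e-9 | s[, 2] >= sd3[2] - 1 - 1e-9 |
        s[, 3] >= sd3[3] - 1 - 1e-9
  on_face <- hi & s[, 1] <= sd3[1] - 1 + 1e-9 & s[, 2] <= sd3[2] - 1 + 1e-9 &
    s[, 3] <= sd3[3] - 1 + 1e-9 & f[, 1] >= -1e-9 & f[, 2] >= -1e-9 &
    f[, 3] >= -1e-9
  f[on_face, ] <- pmin(f[on_face, , drop = FALSE],
                       rep(sd3 - 2, each = sum(on_face)))
  w[on_face, ] <- s[on_face, , drop = FALSE] - f[on_face, , drop = FALSE]
  ok <- (ok | on_face) & s[, 1] >= -1e-9 & s[, 2] >= -1e-9 & s[, 3] >= -1e-9
  out <- rep(NA_real_, nrow(s))
  if (!any(ok)) return(out)
  fo <- f[ok, , drop = FALSE] + 1  # 1-based corner
  wo <- w[ok, , drop = FALSE]
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wt <- (if (dx) wo[, 1] else 1 - wo[, 1]) *
          (if (dy) wo[, 2] else 1 - wo[, 2]) *
          (if (dz) wo[, 3] else 1 - wo[, 3])
    acc <- acc + wt * src[cbind(fo[, 1] + dx, fo[, 2] + dy, fo[, 3] + dz)]
  }
  out[ok] <- acc
  out
}

#' A phase-encode displacement field
#'
#' Susceptibility-induced geometric distortion in EPI displaces signal along
#' the phase-encoding axis only. The field stores a per-voxel displacement
#' in millimetres along one stated voxel axis.
#'
#' @param field 3-D array of displacements (mm), finite everywhere.
#' @param axis voxel axis of phase encoding (1, 2 or 3), default 2.
#' @param jacobian apply intensity modulation by the warp's 1-D Jacobian.
#' @return a `displacement_field` object.
#' @export
displacement_field <- function(field, axis = 2L, jacobian = FALSE) {
  if (length(dim(field)) != 3L) stop("field must be a 3-D array")
  if (any(!is.finite(field))) stop("field must be finite everywhere")
  if (!axis %in% 1:3) stop("axis must be 1, 2 or 3")
  structure(list(field = field, axis = as.integer(axis),
                 jacobian = isTRUE(jacobian)),
            class = "displacement_field")
}

#' Warp a volume along the phase-encode axis
#'
#' One-dimensional warp with linear interpolation:
#' out(x) = in(x + d(x)/voxel_size) along the field's axis. `invert = TRUE`
#' applies the negated field — the first-order correction, exact for
#' locally constant fields. With `jacobian` set on the field, intensities
#' are modulated by 1 + dd/dx to conserve integrated signal. 4-D inputs are
#' warped volume by volume.
#'
#' @param volume 3-D or 4-D `gvol`.
#' @param field a [displacement_field()] on the volume's grid.
#' @param invert apply the negated field.
#' @return warped `gvol`; voxels displaced outside the field of view are NA.
#' @export
apply_displacement <- function(volume, field, invert = FALSE) {
  stopifnot(inherits(field, "displacement_field"))
  d <- dim(volume)
  d3 <- d[1:3]
  if (!all(dim(field$field) == d3))
    stop("displacement field is not on the volume's grid")
  vs <- voxel_size(volume)[field$axis]
  d_vox <- field$field / vs * (if (invert) -1 else 1)
  if (max(abs(d_vox)) >= d3[field$axis])
    stop("displacement exceeds the field of view")
  ax <- field$axis
  n_ax <- d3[ax]

  warp1 <- function(vol3) {
    # sample positions along the axis, per voxel
    pos <- slice.index(vol3, ax) - 1 + d_vox
    f <- floor(pos); w <- pos - f
    ok <- f >= 0 & f <= n_ax - 2 + 1e-12
    on_face <- !ok & pos >= n_ax - 1 - 1e-9 & pos <= n_ax - 1 + 1e-9
    f[on_face] <- n_ax - 2; w[on_face] <- 1
    ok <- ok | on_face
    gather <- function(off) {
      idx_list <- list(slice.index(vol3, 1), slice.index(vol3, 2),
                       slice.index(vol3, 3))
      idx_list[[ax]] <- pmin(pmax(f + off + 1, 1), n_ax)
      vol3[cbind(as.vector(idx_list[[1]]), as.vector(idx_list[[2]]),
                 as.vector(idx_list[[3]]))]
    }
    out <- (1 - as.vector(w)) * gather(0L) + as.vector(w) * gather(1L)
    out[!as.vector(ok)] <- NA_real_
    out <- array(out, d3)
    if (field$jacobian) {
      # forward-difference Jacobian of the applied field (voxel units)
      jac <- 1 + diff_along(array(d_vox, d3), ax)
      out <- out * jac
    }
    out
  }

  if (length(d) == 3L) {
    as_volume(warp1(array(as.numeric(volume), d3)), vol_affine(volume))
  } else {
    out <- array(NA_real_, d)
    for (t in seq_len(d[4]))
      out[, , , t] <- warp1(array(as.numeric(volume[, , , t]), d3))
    as_volume(out, vol_affine(volume))
  }
}

# central-difference derivative along one axis (one-sided at edges)
diff_along <- function(a, ax) {
  d <- dim(a)
  pos <- slice.index(a, ax)
  sub <- cbind(as.vector(slice.index(a, 1)), as.vector(slice.index(a, 2)),
               as.vector(slice.index(a, 3)))
  up <- sub; up[, ax] <- pmin(up[, ax] + 1L, d[ax])
  dn <- sub; dn[, ax] <- pmax(dn[, ax] - 1L, 1L)
  span <- ifelse(pos == 1L | pos == d[ax], 1, 2)
  array((a[up] - a[dn]) / as.vector(span), d)
}

#' Calibrate the g-ratio scaling constant alpha
#'
#' Solves for the single constant alpha that converts MT/density into
#' MVF/FVF inside g = sqrt(1 - alpha * MT / density), by anchoring the
#' g-ratio of a reference ROI to a literature value (0.7 for the splenium
#' of the corpus callosum, measured ex vivo for large-diameter axons).
#' Default mode `"mean-of-g"` finds alpha such that the ROI mean of
#' voxel-wise g equals `g_reference` (monotone 1-D root find); mode
#' `"ratio-of-means"` anchors g formed from ROI-mean MT and ROI-mean
#' density instead (closed form). One subject's alpha is then used,
#' unchanged, for every subject of a cohort.
#'
#' @param mt_map,density_map co-registered 3-D `gvol`s (MT in percent
#'   units; density dimensionless).
#' @param reference_roi 3-D logical ROI mask (e.g. a splenium mask).
#' @param g_reference anchor value, default 0.7.
#' @param mode `"mean-of-g"` (default) or `"ratio-of-means"`.
#' @param tol solver tolerance on the achieved ROI statistic, default 1e-8.
#' @param roi_name identifier recorded in the calibration.
#' @return a `calibration_record`: `alpha`, `g_reference`, `achieved`,
#'   `mode`, `reference_roi`, `solver_tolerance`, `n_voxels`.
#' @export
calibrate_alpha <- function(mt_map, density_map, reference_roi,
                            g_reference = 0.7,
                            mode = c("mean-of-g", "ratio-of-means"),
                            tol = 1e-8, roi_name = "reference") {
  mode <- match.arg(mode)
  dens <- if (inherits(density_map, "density_map")) density_map$density
          else density_map
  stopifnot_same_grid(mt_map, dens, "MT and density maps")
  if (!any(reference_roi)) stop("reference ROI is empty")
  if (g_reference <= 0 || g_reference > 1)
    stop("g_reference must lie in (0, 1]")
  mt <- as.numeric(mt_map)[which(reference_roi)]
  de <- as.numeric(dens)[which(reference_roi)]
  usable <- is.finite(mt) & is.finite(de) & de > 0 & mt > 0
  if (any(!usable)) {
    warning(sum(!usable), " invalid voxel(s) excluded from the reference ROI")
    mt <- mt[usable]; de <- de[usable]
  }
  if (!length(mt)) stop("no usable voxels in the reference ROI")
  r <- mt / de

  if (g_reference == 1) {
    alpha <- 0; achieved <- 1
  } else if (mode == "ratio-of-means") {
    alpha <- (1 - g_reference^2) * mean(de) / mean(mt)
    achieved <- sqrt(1 - alpha * mean(mt) / mean(de))
  } else {
    alpha_max <- 1 / max(r)  # keeps every ROI radicand >= 0
    fobj <- function(a) mean(sqrt(pmax(1 - a * r, 0))) - g_reference
    if (fobj(alpha_max) > 0)
      stop("no alpha in the feasible interval reaches g_reference")
    root <- stats::uniroot(fobj, c(0, alpha_max), tol = min(tol, 1e-10) / 10)
    alpha <- root$root
    achieved <- mean(sqrt(pmax(1 - alpha * r, 0)))
  }
  if (abs(achieved - g_reference) > max(tol, 1e-8))
    warning(sprintf("achieved ROI g %.8f misses the reference %.4f", achieved,
                    g_reference))
  structure(
    list(alpha = alpha, g_reference = g_reference, achieved = achieved,
         mode = mode, reference_roi = roi_name, solver_tolerance = tol,
         n_voxels = length(mt)),
    class = "calibration_record"
  )
}

#' @export
print.calibration_record <- function(x, ...) {
  cat(sprintf(
    "<calibration_record> alpha = %.6g (%s, ROI '%s', n = %d)\n  anchor g = %.4f, achieved = %.8f\n",
    x$alpha, x$mode, x$reference_roi, x$n_voxels, x$g_reference, x$achieved))
  invisible(x)
}

#' Compute the calibrated g-ratio map
#'
#' Voxel-wise g = sqrt(1 - alpha * MT / density) on the shared (diffusion)
#' grid. Voxels with non-positive density, a negative radicand
#' (alpha*MT/density > 1) or invalid inputs are masked NA — never clipped —
#' so distortion and partial-volume artefacts (the implausible g ~ 1 edge
#' voxels produced by uncorrected susceptibility displacement) remain
#' visible. MT = 0 gives g = 1 (no myelin).
#'
#' @param mt_map 3-D MT saturation `gvol`, percent units.
#' @param density_map a `density_map` or plain 3-D `gvol`.
#' @param calibration a [calibrate_alpha()] record (or a single alpha).
#' @return a `gratio_result`: `g_map`, logical `validity_mask`,
#'   `calibration`.
#' @export
compute_g_map <- function(mt_map, density_map, calibration) {
  dens <- if (inherits(density_map, "density_map")) density_map$density
          else density_map
  stopifnot_same_grid(mt_map, dens, "MT and density maps")
  alpha <- if (inherits(calibration, "calibration_record")) calibration$alpha
           else as.numeric(calibration)
  if (!is.finite(alpha) || alpha < 0) stop("alpha must be a finite value >= 0")
  mt <- as.numeric(mt_map); de <- as.numeric(dens)
  radicand <- 1 - alpha * mt / de
  valid <- is.finite(mt) & is.finite(de) & de > 0 & radicand >= 0 & mt >= 0
  g <- rep(NA_real_, length(mt))
  g[valid] <- sqrt(radicand[valid])
  d3 <- dim(mt_map)[1:3]
  structure(
    list(g_map = inherit_affine(array(g, d3), mt_map),
         validity_mask = inherit_affine(array(valid, d3), mt_map),
         calibration = if (inherits(calibration, "calibration_record"))
           calibration else list(alpha = alpha)),
    class = "gratio_result"
  )
}

#' @export
print.gratio_result <- function(x, ...) {
  v <- as.logical(x$validity_mask)
  cat(sprintf(
    "<gratio_result> %s grid, %d/%d valid voxels, alpha = %.6g\n",
    paste(dim(x$g_map)[1:3], collapse = "x"), sum(v), length(v),
    x$calibration$alpha))
  invisible(x)
}
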