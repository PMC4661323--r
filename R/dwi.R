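#' A single-shell diffusion-weighted series
#'
#' 4-D volume stack (x, y, z, direction) with per-volume b-values (s/mm^2)
#' and unit gradient directions. The acquisition this emulates holds 60
#' b = 1000 directions plus 6 low-b (b = 100) volumes; the low-b rows enter
#' the tensor fit with their true b-value, never as b = 0.
#'
#' @param volumes 4-D array, one volume per gradient direction.
#' @param bvals numeric vector of b-values, s/mm^2.
#' @param bvecs n x 3 matrix of gradient directions; rows with b > 0 must be
#'   unit vectors (non-unit rows are normalised with a warning).
#' @param affine 4x4 voxel-to-world matrix.
#' @return a `dwi_series` object.
#' @export
dwi_series <- function(volumes, bvals, bvecs, affine = vol_affine(volumes)) {
  if (length(dim(volumes)) != 4L)
    stop("volumes must be a 4-D (x, y, z, direction) array")
  n <- dim(volumes)[4]
  bvecs <- as.matrix(bvecs)
  if (length(bvals) != n || nrow(bvecs) != n || ncol(bvecs) != 3)
    stop("bvals/bvecs must match the number of volumes")
  if (n < 7L)
    stop("need at least 7 volumes for a tensor fit")
  nrm <- sqrt(rowSums(bvecs^2))
  zero <- nrm < 1e-8
  if (any(zero & bvals > 0))
    stop("zero gradient vector with b > 0")
  off <- !zero & abs(nrm - 1) > 1e-6
  if (any(off)) {
    warning(sum(off), " non-unit gradient vector(s) normalised")
    bvecs[off, ] <- bvecs[off, ] / nrm[off]
  }
  bmax <- max(bvals)
  hi <- bvecs[bvals > 0.9 * bmax, , drop = FALSE]
  if (nrow(unique(round(hi, 6))) < 6L)
    stop("need at least 6 unique directions at the high shell")
  structure(
    list(volumes = as_volume(unclass(volumes), affine),
         bvals = as.numeric(bvals), bvecs = bvecs),
    class = "dwi_series"
  )
}

# b-matrix design: log S = log S0 - b g' D g, 7 columns
# (1, Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)
tensor_design <- function(bvals, bvecs) {
  cbind(
    1,
    -bvals * bvecs[, 1]^2,
    -bvals * bvecs[, 2]^2,
    -bvals * bvecs[, 3]^2,
    -2 * bvals * bvecs[, 1] * bvecs[, 2],
    -2 * bvals * bvecs[, 1] * bvecs[, 3],
    -2 * bvals * bvecs[, 2] * bvecs[, 3]
  )
}

#' Weighted least-squares diffusion tensor fit
#'
#' Log-linear fit per voxel: an ordinary least-squares pass on log-signals,
#' then one reweighting iteration with weights equal to the squared
#' predicted signals (the standard WLS scheme for log-linearised tensor
#' estimation). Non-positive signals are excluded from a voxel's fit;
#' a voxel needs at least 7 usable measurements to be valid.
#'
#' @param series a [dwi_series()].
#' @param mask 3-D logical array of voxels to fit (default: all).
#' @return a `tensor_fit` list: `tensor` (4-D, 6 components
#'   Dxx, Dyy, Dzz, Dxy, Dxz, Dyz in mm^2/s), `s0`, `residual_variance`,
#'   logical `valid`, and the design metadata.
#' @export
fit_tensor_wls <- function(series, mask = NULL) {
  stopifnot(inherits(series, "dwi_series"))
  d <- dim(series$volumes)
  d3 <- d[1:3]; n <- d[4]
  if (is.null(mask)) mask <- array(TRUE, d3)
  if (!all(dim(mask) == d3)) stop("mask dimensions do not match the series")

  X <- tensor_design(series$bvals, series$bvecs)
  vox <- which(mask)
  sig <- matrix(aperm(unclass(series$volumes), c(4, 1, 2, 3)),
                nrow = n)[, vox, drop = FALSE]

  beta <- matrix(NA_real_, 7L, length(vox))
  rvar <- rep(NA_real_, length(vox))
  valid <- rep(FALSE, length(vox))

  pos_all <- colSums(sig > 0 & is.finite(sig)) == n
  # fast path: all measurements usable -> one shared OLS solve
  if (any(pos_all)) {
    Y <- log(sig[, pos_all, drop = FALSE])
    XtX <- crossprod(X)
    b_ols <- solve(XtX, crossprod(X, Y))
    pred <- X %*% b_ols
    w <- exp(2 * pred)               # squared predicted signals
    for (jj in seq_len(ncol(Y))) {
      Xw <- X * w[, jj]
      b <- solve(crossprod(X, Xw), crossprod(Xw, Y[, jj]))
      beta[, which(pos_all)[jj]] <- b
      r <- Y[, jj] - X %*% b
      rvar[which(pos_all)[jj]] <- sum(w[, jj] * r^2) / sum(w[, jj])
    }
    valid[pos_all] <- TRUE
  }
  # slow path: voxels with excluded measurements
  for (j in which(!pos_all)) {
    use <- sig[, j] > 0 & is.finite(sig[, j])
    if (sum(use) < 7L) next
    Xu <- X[use, , drop = FALSE]
    y <- log(sig[use, j])
    b0 <- tryCatch(solve(crossprod(Xu), crossprod(Xu, y)),
                   error = function(e) NULL)
    if (is.null(b0)) next
    w <- exp(2 * as.numeric(Xu %*% b0))
    Xw <- Xu * w
    b <- tryCatch(solve(crossprod(Xu, Xw), crossprod(Xw, y)),
                  error = function(e) NULL)
    if (is.null(b)) next
    beta[, j] <- b
    r <- y - Xu %*% b
    rvar[j] <- sum(w * r^2) / sum(w)
    valid[j] <- TRUE
  }

  tensor <- array(NA_real_, c(d3, 6L))
  s0 <- array(NA_real_, d3)
  rv <- array(NA_real_, d3)
  vd <- array(FALSE, d3)
  s0[vox] <- exp(beta[1, ])
  for (cmp in 1:6) {
    tmp <- array(NA_real_, d3)
    tmp[vox] <- beta[cmp + 1L, ]
    tensor[, , , cmp] <- tmp
  }
  rv[vox] <- rvar
  vd[vox] <- valid

  aff <- vol_affine(series$volumes)
  structure(
    list(tensor = as_volume(tensor, aff), s0 = as_volume(s0, aff),
         residual_variance = as_volume(rv, aff),
         valid = as_volume(vd, aff)),
    class = "tensor_fit"
  )
}

#' Scalar invariants of the fitted tensor
#'
#' Per-voxel eigen-decomposition with eigenvalues sorted descending:
#' AD = l1, RD = (l2 + l3)/2, MD = mean(l), and
#' FA = sqrt(3/2) * sqrt(sum((l - MD)^2)) / sqrt(sum(l^2)). Voxels with
#' negative eigenvalues are flagged (`negative_eig`), not clipped.
#'
#' @param fit a [fit_tensor_wls()] result.
#' @return a `tensor_indices` list of 3-D `gvol`s: `fa`, `md`, `ad`, `rd`,
#'   `evals` (4-D, descending), `valid`, `negative_eig`.
#' @export
tensor_indices <- function(fit) {
  stopifnot(inherits(fit, "tensor_fit"))
  d3 <- dim(fit$s0)[1:3]
  vox <- which(as.logical(fit$valid))
  tens <- matrix(fit$tensor, ncol = 6L)[vox, , drop = FALSE]

  ev <- matrix(NA_real_, length(vox), 3L)
  for (j in seq_along(vox)) {
    Dm <- matrix(c(tens[j, 1], tens[j, 4], tens[j, 5],
                   tens[j, 4], tens[j, 2], tens[j, 6],
                   tens[j, 5], tens[j, 6], tens[j, 3]), 3, 3)
    ev[j, ] <- eigen(Dm, symmetric = TRUE, only.values = TRUE)$values
  }
  md <- rowMeans(ev)
  fa <- sqrt(1.5) * sqrt(rowSums((ev - md)^2)) / sqrt(rowSums(ev^2))
  neg <- ev[, 3] < 0

  put <- function(v) { a <- array(NA_real_, d3); a[vox] <- v
                       inherit_affine(a, fit$s0) }
  evals <- array(NA_real_, c(d3, 3L))
  for (cmp in 1:3) { tmp <- array(NA_real_, d3); tmp[vox] <- ev[, cmp]
                     evals[, , , cmp] <- tmp }
  vd <- array(FALSE, d3); vd[vox] <- TRUE
  ng <- array(FALSE, d3); ng[vox] <- neg
  structure(
    list(fa = put(fa), md = put(md), ad = put(ev[, 1]),
         rd = put((ev[, 2] + ev[, 3]) / 2),
         evals = as_volume(evals, vol_affine(fit$s0)),
         valid = inherit_affine(vd, fit$s0),
         negative_eig = inherit_affine(ng, fit$s0)),
    class = "tensor_indices"
  )
}

#' Tensor-based fiber-density proxy
#'
#' A stand-in for a full fiber-density solver: the linear-anisotropy
#' coefficient cl = (l1 - l2) / (l1 + l2 + l3), clamped at zero, then
#' divided by its white-matter-mask mean so the mask mean is exactly 1.
#' That per-subject division is the method's "global factor": any residual
#' proportionality between this proxy and the true fiber volume fraction is
#' absorbed by the g-ratio calibration constant alpha. Voxels with negative
#' eigenvalues are excluded.
#'
#' @param indices a [tensor_indices()] result.
#' @param fit the matching [fit_tensor_wls()] result (grid reference).
#' @param wm_mask 3-D logical white-matter mask.
#' @return a `density_map` list: `density` (3-D), `normalization_factor`,
#'   `source = "internal proxy"`, `valid`.
#' @export
fiber_density_proxy <- function(indices, fit, wm_mask) {
  stopifnot(inherits(indices, "tensor_indices"))
  d3 <- dim(indices$fa)[1:3]
  if (!all(dim(wm_mask) == d3)) stop("wm_mask does not match the grid")
  if (!any(wm_mask)) stop("empty white-matter mask")
  ev <- indices$evals
  cl <- (ev[, , , 1] - ev[, , , 2]) / (ev[, , , 1] + ev[, , , 2] + ev[, , , 3])
  cl <- pmax(cl, 0)
  valid <- as.logical(indices$valid) & !as.logical(indices$negative_eig)
  cl[!valid] <- NA_real_
  m <- mean(cl[wm_mask & valid], na.rm = TRUE)
  if (!is.finite(m) || m <= 1e-9)   # degenerate: no anisotropy in the mask
    stop("raw density has (numerically) zero mean over the mask")
  structure(
    list(density = inherit_affine(array(cl / m, d3), indices$fa),
         normalization_factor = m,
         source = "internal proxy",
         valid = inherit_affine(array(valid, d3), indices$fa)),
    class = "density_map"
  )
}

#' Load an externally computed fiber-density map
#'
#' Accepts a NIfTI fiber-density volume computed by an external tool and
#' wraps it as a `density_map`. The map must match the reference grid unless
#' `resample = TRUE`, in which case it is trilinearly resampled. With
#' `renormalize = TRUE` the map is divided by its mask mean (mean 1
#' contract); otherwise it is trusted as-is.
#'
#' @param path NIfTI file path.
#' @param grid_reference a `gvol` (or any object with dim + affine) defining
#'   the target grid.
#' @param wm_mask mask for renormalisation (required if `renormalize`).
#' @param renormalize divide by mask mean, default FALSE.
#' @param resample allow trilinear resampling onto the reference grid.
#' @return a `density_map` list with `source = "external file"`.
#' @export
load_external_density <- function(path, grid_reference, wm_mask = NULL,
                                  renormalize = FALSE, resample = FALSE) {
  vol <- read_volume(path)
  if (!same_grid(vol, grid_reference)) {
    if (!resample)
      stop("density grid does not match the reference; set resample = TRUE")
    vol <- resample_to_grid(vol, dim(grid_reference)[1:3],
                            vol_affine(grid_reference), method = "trilinear")
  }
  dens <- array(as.numeric(vol), dim(vol)[1:3])
  dens[dens < 0] <- NA_real_
  nf <- 1
  if (renormalize) {
    if (is.null(wm_mask)) stop("renormalize = TRUE needs a wm_mask")
    nf <- mean(dens[wm_mask], na.rm = TRUE)
    if (!is.finite(nf) || nf <= 0) stop("non-positive mask mean")
    dens <- dens / nf
  }
  structure(
    list(density = as_volume(dens, vol_affine(vol)),
         normalization_factor = nf, source = "external file",
         valid = as_volume(is.finite(dens), vol_affine(vol))),
    class = "density_map"
  )
}
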