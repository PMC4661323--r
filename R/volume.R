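#' Attach a world-space affine to an image array
#'
#' Volumes in gratiomap are plain numeric arrays (3-D, or 4-D for multi-echo
#' / multi-direction stacks) carrying a 4x4 voxel-to-world affine as the
#' `"affine"` attribute, following the NIfTI RAS+ convention with 0-based
#' voxel indices: world = affine %*% c(i, j, k, 1).
#'
#' @param data numeric array, 3-D or 4-D.
#' @param affine 4x4 numeric voxel-to-world matrix; must be invertible in its
#'   upper-left 3x3 block.
#' @return the array with the affine attached, class `"gvol"`.
#' @export
as_volume <- function(data, affine = diag(4)) {
  if (!is.array(data) || !(length(dim(data)) %in% c(3L, 4L)))
    stop("`data` must be a 3-D or 4-D array")
  affine <- validate_affine(affine)
  structure(data, affine = affine, class = c("gvol", class(data)))
}

validate_affine <- function(affine) {
  affine <- unname(as.matrix(affine))
  if (!all(dim(affine) == c(4L, 4L)))
    stop("affine must be a 4x4 matrix")
  if (abs(det(affine[1:3, 1:3])) < .Machine$double.eps * 10)
    stop("affine is singular")
  storage.mode(affine) <- "double"
  affine
}

#' @export
#' @rdname as_volume
vol_affine <- function(x) {
  a <- attr(x, "affine")
  if (is.null(a)) diag(4) else a
}

#' Voxel edge lengths in mm implied by an affine
#' @param x a volume or a 4x4 affine.
#' @return length-3 numeric vector of voxel sizes.
#' @export
voxel_size <- function(x) {
  a <- if (is.matrix(x) && all(dim(x) == c(4, 4))) x else vol_affine(x)
  sqrt(colSums(a[1:3, 1:3]^2))
}

#' @keywords internal
same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a)[1:3], dim(b)[1:3]) &&
    max(abs(vol_affine(a) - vol_affine(b))) <= tol
}

#' @keywords internal
stopifnot_same_grid <- function(a, b, what = "volumes") {
  if (!same_grid(a, b))
    stop(sprintf("%s are not on the same grid (dim/affine mismatch)", what))
  invisible(TRUE)
}

# carry an affine onto a derived array
inherit_affine <- function(data, template) {
  as_volume(data, vol_affine(template))
}

#' Read a NIfTI-1 volume
#'
#' Reads `.nii` / `.nii.gz` through RNifti and returns a `gvol` array with
#' the voxel-to-world affine attached. RNifti's xform precedence is used
#' (sform when its code is non-zero, otherwise qform), which matches the
#' common neuroimaging convention.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a 3-D or 4-D `gvol` array.
#' @export
read_volume <- function(path) {
  if (!grepl("\\.nii(\\.gz)?$", path))
    stop("expected a .nii or .nii.gz file: ", path)
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = dim(aff))
  d <- dim(img)
  if (!(length(d) %in% c(3L, 4L)))
    stop("expected a 3-D or 4-D NIfTI payload, got ", length(d), "-D")
  as_volume(array(as.numeric(img), d), aff)
}

#' Write a volume to NIfTI-1
#'
#' Data are stored as float32 (the on-disk convention); computation inside
#' the package stays double. Both sform and qform are set to the volume's
#' affine.
#'
#' @param volume a `gvol` (or array plus `affine`).
#' @param path output `.nii` or `.nii.gz` path.
#' @param affine optional override affine.
#' @param datatype NIfTI storage type, default `"float"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, affine = NULL, datatype = "float") {
  if (!grepl("\\.nii(\\.gz)?$", path))
    stop("expected a .nii or .nii.gz output path: ", path)
  aff <- validate_affine(if (is.null(affine)) vol_affine(volume) else affine)
  arr <- array(as.numeric(volume), dim(volume))
  img <- RNifti::asNifti(arr)
  # sform only: it is authoritative on read, and RNifti's qform setter
  # renormalises the scale away
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Voxel centers of a grid in world coordinates
#' @param dim3 integer length-3 grid shape.
#' @param affine 4x4 voxel-to-world matrix (0-based indices).
#' @return n x 3 matrix of world coordinates, voxel order = column-major.
#' @export
voxel_centers <- function(dim3, affine) {
  idx <- as.matrix(expand.grid(
    i = seq_len(dim3[1]) - 1L,
    j = seq_len(dim3[2]) - 1L,
    k = seq_len(dim3[3]) - 1L
  ))
  t(affine %*% rbind(t(idx), 1))[, 1:3, drop = FALSE]
}

# simple 6-connected binary erosion used for ROI interiors
erode_mask <- function(mask) {
  m <- mask & !is.na(mask)
  d <- dim(m)
  shift <- function(arr, ax, by) {
    out <- array(FALSE, d)
    src <- lapply(d, seq_len)
    dst <- src
    if (by > 0) { dst[[ax]] <- (1 + by):d[ax]; src[[ax]] <- 1:(d[ax] - by) }
    else        { dst[[ax]] <- 1:(d[ax] + by); src[[ax]] <- (1 - by):d[ax] }
    out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
    out
  }
  out <- m
  for (ax in 1:3) out <- out & shift(m, ax, 1L) & shift(m, ax, -1L)
  out
}
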