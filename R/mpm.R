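#' A weighted multi-echo FLASH stack
#'
#' One of the three weighted acquisitions (PDw, T1w or MTw) of a
#' multi-parameter mapping (MPM) protocol: a 4-D magnitude image
#' (x, y, z, echo) plus its excitation flip angle and repetition time.
#'
#' @param volumes 4-D array (x, y, z, echo) of magnitudes, arbitrary units.
#' @param flip_angle excitation flip angle in radians, in (0, pi/2).
#' @param tr repetition time in seconds.
#' @param echo_times echo times in seconds, ascending; length = n echoes.
#' @param affine 4x4 voxel-to-world matrix.
#' @return a `flash_stack` object.
#' @export
flash_stack <- function(volumes, flip_angle, tr, echo_times,
                        affine = vol_affine(volumes)) {
  if (length(dim(volumes)) == 3L) dim(volumes) <- c(dim(volumes), 1L)
  if (length(dim(volumes)) != 4L)
    stop("volumes must be a 4-D (x, y, z, echo) array")
  n_echo <- dim(volumes)[4]
  if (length(echo_times) != n_echo || is.unsorted(echo_times))
    stop("echo_times must be ascending with one entry per echo")
  if (flip_angle <= 0 || flip_angle >= pi / 2)
    stop("flip_angle (radians) must lie in (0, pi/2)")
  if (tr <= 0) stop("tr must be positive (seconds)")
  structure(
    list(volumes = as_volume(unclass(volumes), affine),
         flip_angle = flip_angle, tr = tr, echo_times = echo_times),
    class = "flash_stack"
  )
}

#' The PDw/T1w/MTw FLASH triplet of an MPM acquisition
#'
#' @param pdw,t1w,mtw [flash_stack()] objects on one co-registered grid.
#'   The PDw and T1w repetition times must match; the MTw TR may differ.
#' @return an `mpm_acquisition` object.
#' @export
mpm_acquisition <- function(pdw, t1w, mtw) {
  for (s in list(pdw, t1w, mtw))
    if (!inherits(s, "flash_stack")) stop("all inputs must be flash_stacks")
  stopifnot_same_grid(pdw$volumes, t1w$volumes, "PDw/T1w stacks")
  stopifnot_same_grid(pdw$volumes, mtw$volumes, "PDw/MTw stacks")
  if (abs(pdw$tr - t1w$tr) > 1e-9)
    stop("PDw and T1w repetition times must match")
  structure(list(pdw = pdw, t1w = t1w, mtw = mtw), class = "mpm_acquisition")
}

#' Default MPM protocol parameters
#'
#' Flip angles 5 (PDw), 29 (T1w), 9 (MTw) degrees; TR 25.25 ms (PDw, T1w)
#' and 29.25 ms (MTw); eight echoes of which the first six are averaged.
#' @return nested list of per-weighting `flip_angle` (rad) and `tr` (s).
#' @export
mpm_protocol <- function() {
  list(
    pdw = list(flip_angle = 5  * pi / 180, tr = 25.25e-3),
    t1w = list(flip_angle = 29 * pi / 180, tr = 25.25e-3),
    mtw = list(flip_angle = 9  * pi / 180, tr = 29.25e-3),
    n_echoes_acquired = 8L,
    n_echoes_averaged = 6L
  )
}

#' Small-flip-angle FLASH signal model
#'
#' The rational approximation of the spoiled gradient-echo steady state:
#' S = A * alpha * R1 * TR / (alpha^2/2 + delta + R1 * TR), where delta is
#' the additional per-TR saturation caused by an MT pre-pulse (0 without
#' one). `mt_sat` is delta in percent units.
#'
#' @param a_app apparent signal amplitude (arbitrary units).
#' @param r1 longitudinal relaxation rate, 1/s.
#' @param flip_angle radians.
#' @param tr seconds.
#' @param mt_sat MT saturation in percent units (delta * 100), default 0.
#' @return signal, same shape as the inputs (vectorised).
#' @export
flash_signal <- function(a_app, r1, flip_angle, tr, mt_sat = 0) {
  delta <- mt_sat / 100
  a_app * flip_angle * r1 * tr / (flip_angle^2 / 2 + delta + r1 * tr)
}

#' Average the first echoes of a FLASH stack
#'
#' Echo averaging boosts SNR before map fitting; the acquisition protocol
#' averages the first six of eight echoes.
#'
#' @param stack a [flash_stack()].
#' @param n_echoes number of leading echoes to average (default 6, capped
#'   at the number available only by erroring).
#' @return 3-D `gvol` of voxel-wise means.
#' @export
average_echoes <- function(stack, n_echoes = 6L) {
  stopifnot(inherits(stack, "flash_stack"))
  avail <- dim(stack$volumes)[4]
  if (n_echoes < 1L || n_echoes > avail)
    stop(sprintf("n_echoes = %d but stack has %d echoes", n_echoes, avail))
  v <- stack$volumes[, , , seq_len(n_echoes), drop = FALSE]
  out <- rowMeans(v, dims = 3L)
  inherit_affine(out, stack$volumes)
}

#' Fit R1 and apparent amplitude from the PDw/T1w pair
#'
#' Inverts the dual-flip-angle FLASH approximation:
#' R1 = (S_T1 a_T1 / TR_T1 - S_PD a_PD / TR_PD) / (2 (S_PD/a_PD - S_T1/a_T1))
#' and the matching closed form for A. Exact under the rational signal
#' model. Voxels with non-positive signals or a degenerate denominator
#' (no T1 contrast) are flagged invalid, not clipped.
#'
#' @param pd_mean,t1_mean echo-averaged 3-D volumes.
#' @param pd_meta,t1_meta lists with `flip_angle` (rad) and `tr` (s).
#' @return list with 3-D `r1` (1/s), `a_app` (a.u.) and logical `valid`.
#' @export
fit_r1_a <- function(pd_mean, t1_mean, pd_meta, t1_meta) {
  stopifnot_same_grid(pd_mean, t1_mean, "PDw/T1w mean volumes")
  a_pd <- pd_meta$flip_angle; tr_pd <- pd_meta$tr
  a_t1 <- t1_meta$flip_angle; tr_t1 <- t1_meta$tr
  s_pd <- as.numeric(pd_mean); s_t1 <- as.numeric(t1_mean)

  denom <- s_pd / a_pd - s_t1 / a_t1
  scale <- pmax(abs(s_pd / a_pd), abs(s_t1 / a_t1))
  valid <- is.finite(s_pd) & is.finite(s_t1) & s_pd > 0 & s_t1 > 0 &
    abs(denom) > 1e-9 * pmax(scale, .Machine$double.eps)

  r1 <- 0.5 * (s_t1 * a_t1 / tr_t1 - s_pd * a_pd / tr_pd) / denom
  a_app <- s_pd * s_t1 * (tr_pd * a_t1 / a_pd - tr_t1 * a_pd / a_t1) /
    (s_t1 * tr_pd * a_t1 - s_pd * tr_t1 * a_pd)
  r1[!valid] <- NA_real_
  a_app[!valid] <- NA_real_
  d <- dim(pd_mean)[1:3]
  list(
    r1 = inherit_affine(array(r1, d), pd_mean),
    a_app = inherit_affine(array(a_app, d), pd_mean),
    valid = inherit_affine(array(valid, d), pd_mean)
  )
}

#' Fit the MT saturation map
#'
#' delta = (A * a_MT / S_MT - 1) * R1 * TR_MT - a_MT^2 / 2, reported in
#' percent units (x100). Algebraically exact under the MT-FLASH forward
#' model. Non-positive MTw signals and voxels with invalid R1/A are flagged;
#' negative saturations are kept (flagged downstream, never clipped) so
#' artefacts stay visible.
#'
#' @param mt_mean echo-averaged MTw 3-D volume.
#' @param mt_meta list with `flip_angle` (rad) and `tr` (s).
#' @param r1,a_app maps from [fit_r1_a()].
#' @return list with 3-D `mt_sat` (percent units) and logical `valid`.
#' @export
fit_mt_sat <- function(mt_mean, mt_meta, r1, a_app) {
  stopifnot_same_grid(mt_mean, r1, "MTw mean and R1 volumes")
  a_mt <- mt_meta$flip_angle; tr_mt <- mt_meta$tr
  s_mt <- as.numeric(mt_mean)
  valid <- is.finite(s_mt) & s_mt > 0 &
    is.finite(as.numeric(r1)) & is.finite(as.numeric(a_app))
  delta <- (as.numeric(a_app) * a_mt / s_mt - 1) * as.numeric(r1) * tr_mt -
    a_mt^2 / 2
  mt_sat <- 100 * delta
  mt_sat[!valid] <- NA_real_
  d <- dim(mt_mean)[1:3]
  list(
    mt_sat = inherit_affine(array(mt_sat, d), mt_mean),
    valid = inherit_affine(array(valid, d), mt_mean),
    negative = inherit_affine(array(valid & mt_sat < 0, d), mt_mean)
  )
}

#' Compute MT, R1 and A maps from an MPM acquisition
#'
#' The full map-fitting chain: average the first `n_echoes` echoes of each
#' weighting, invert the dual-angle pair for R1 and A, then solve the MTw
#' signal for the MT saturation. Fits everywhere; masking is left to
#' downstream steps.
#'
#' @param acq an [mpm_acquisition()].
#' @param n_echoes echoes to average (default: 6, or all echoes if fewer
#'   were acquired).
#' @return an `mpm_maps` list: `mt_sat` (p.u.), `r1` (1/s), `a_app` (a.u.),
#'   logical `valid`; all 3-D `gvol`s on the acquisition grid.
#' @export
fit_mpm <- function(acq, n_echoes = NULL) {
  stopifnot(inherits(acq, "mpm_acquisition"))
  if (is.null(n_echoes))
    n_echoes <- min(6L, dim(acq$pdw$volumes)[4])
  pd_mean <- average_echoes(acq$pdw, n_echoes)
  t1_mean <- average_echoes(acq$t1w, n_echoes)
  mt_mean <- average_echoes(acq$mtw, n_echoes)
  ra <- fit_r1_a(pd_mean, t1_mean,
                 list(flip_angle = acq$pdw$flip_angle, tr = acq$pdw$tr),
                 list(flip_angle = acq$t1w$flip_angle, tr = acq$t1w$tr))
  mt <- fit_mt_sat(mt_mean,
                   list(flip_angle = acq$mtw$flip_angle, tr = acq$mtw$tr),
                   ra$r1, ra$a_app)
  structure(
    list(mt_sat = mt$mt_sat, r1 = ra$r1, a_app = ra$a_app,
         valid = inherit_affine(array(as.logical(ra$valid) & as.logical(mt$valid),
                                      dim(ra$valid)[1:3]), ra$valid)),
    class = "mpm_maps"
  )
}
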