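#' A population of myelinated fibers inside one voxel
#'
#' The voxel microstructure model: fibers are parallel annular cylinders seen
#' in cross-section as nested circles, each with an outer radius (axon plus
#' myelin sheath) and a g-ratio g = inner/outer radius. g = 1 means an
#' unmyelinated axon (zero myelin thickness). Only the cross-sectional areas
#' matter for the volume-fraction theory, so fibers are constrained by the
#' aggregate packing bound sum(pi R_O^2) <= voxel_area, not by geometric
#' placement.
#'
#' @param outer_radius numeric vector of outer radii, micrometres, > 0.
#' @param g numeric vector of per-fiber g-ratios in (0, 1].
#' @param voxel_area voxel cross-sectional area in square micrometres.
#' @return an object of class `fiber_population`: a list with `fibers`
#'   (a tibble with columns `outer_radius`, `g`, `inner_radius`) and
#'   `voxel_area`.
#' @examples
#' pop <- fiber_population(outer_radius = 1, g = 0.7, voxel_area = 4)
#' compute_volume_fractions(pop)
#' @export
fiber_population <- function(outer_radius, g, voxel_area) {
  n <- max(length(outer_radius), length(g))
  outer_radius <- rep_len(as.numeric(outer_radius), n)
  g <- rep_len(as.numeric(g), n)
  if (any(!is.finite(outer_radius)) || any(outer_radius <= 0))
    stop("all outer radii must be finite and > 0")
  if (any(!is.finite(g)) || any(g <= 0) || any(g > 1))
    stop("all g-ratios must lie in (0, 1]")
  if (!is.numeric(voxel_area) || length(voxel_area) != 1 || voxel_area <= 0)
    stop("voxel_area must be a single positive number")
  fiber_area <- sum(pi * outer_radius^2)
  if (fiber_area > voxel_area * (1 + 1e-12))
    stop(sprintf(
      "fibers overflow the voxel: total fiber area %.4g exceeds voxel_area %.4g",
      fiber_area, voxel_area))
  structure(
    list(
      fibers = tibble::tibble(
        outer_radius = outer_radius,
        g = g,
        inner_radius = g * outer_radius
      ),
      voxel_area = voxel_area
    ),
    class = "fiber_population"
  )
}

#' @export
print.fiber_population <- function(x, ...) {
  cat(sprintf("<fiber_population> %d fibers in a %.4g um^2 voxel\n",
              nrow(x$fibers), x$voxel_area))
  print(x$fibers, ...)
  invisible(x)
}

check_population <- function(pop) {
  if (!inherits(pop, "fiber_population"))
    stop("expected a fiber_population")
  if (nrow(pop$fibers) == 0L)
    stop("population is empty; aggregation is undefined")
  invisible(pop)
}

#' Voxel volume fractions from an explicit fiber list
#'
#' Sums fiber and myelin cross-sectional areas over the voxel:
#' FVF = sum(pi R_O^2) / A, MVF = sum(pi (R_O^2 - R_I^2)) / A, and the
#' extra-axonal fraction EVF = 1 - FVF. Stored fibers are explicit draws, so
#' probability-weighted expectations over a radius distribution reduce to
#' plain sums.
#'
#' @param pop a [fiber_population()].
#' @return a one-row tibble with columns `fvf`, `mvf`, `evf`.
#' @export
compute_volume_fractions <- function(pop) {
  check_population(pop)
  fvf <- sum(pi * pop$fibers$outer_radius^2) / pop$voxel_area
  mvf <- sum(pi * (pop$fibers$outer_radius^2 - pop$fibers$inner_radius^2)) /
    pop$voxel_area
  tibble::tibble(fvf = fvf, mvf = mvf, evf = 1 - fvf)
}

#' Mean microscopic g-ratio of a population
#'
#' The unweighted arithmetic mean of per-fiber g-ratios — the expectation of
#' the microscopic g-ratio under the population's empirical distribution.
#'
#' @inheritParams compute_volume_fractions
#' @return a single ratio.
#' @export
microscopic_mean_g <- function(pop) {
  check_population(pop)
  mean(pop$fibers$g)
}

#' Area-weighted root-mean-square g-ratio
#'
#' The voxel-level aggregate that MRI actually measures when g varies within
#' the voxel: sqrt( sum(g_j^2 R_O,j^2) / sum(R_O,j^2) ). Algebraically
#' identical to sqrt(1 - MVF/FVF) for any fiber list, which is the bridge
#' between the microscopic model and the imaging estimate.
#'
#' @inheritParams compute_volume_fractions
#' @return a single ratio.
#' @export
area_weighted_rms_g <- function(pop) {
  check_population(pop)
  r2 <- pop$fibers$outer_radius^2
  sqrt(sum(pop$fibers$g^2 * r2) / sum(r2))
}

#' MR g-ratio from volume fractions
#'
#' g = sqrt(1 - MVF/FVF). Accepts either the tibble returned by
#' [compute_volume_fractions()] or explicit `mvf`/`fvf` vectors (vectorised).
#' MVF = 0 gives g = 1 (unmyelinated limit); MVF = FVF gives g = 0.
#'
#' @param vf optional tibble/list with elements `fvf` and `mvf`.
#' @param mvf,fvf numeric vectors, used when `vf` is missing.
#' @return numeric vector of g-ratios in \[0, 1\].
#' @export
mr_g_from_fractions <- function(vf = NULL, mvf = NULL, fvf = NULL) {
  if (!is.null(vf)) { mvf <- vf$mvf; fvf <- vf$fvf }
  if (any(!is.finite(fvf)) || any(fvf <= 0))
    stop("fvf must be positive (g undefined at fvf = 0)")
  if (any(mvf < 0) || any(mvf > fvf + 1e-15))
    stop("mvf must lie in [0, fvf]")
  sqrt(pmax(1 - mvf / fvf, 0))
}

#' Sample a reproducible fiber population
#'
#' Draws outer radii and g-ratios from named distributions. Radii:
#' `lognormal` (median, sigma on the log scale) or `constant`. g-ratios:
#' `constant` (point mass), `truncnorm` (normal truncated to (0, 1]), or
#' `mixture` — a two-pool model with a myelinated pool (truncated normal)
#' and an unmyelinated fraction placed exactly at g = 1, emulating the
#' multi-modal g distributions reported for corpus callosum tissue.
#' Rejected draws (g outside (0, 1], radii <= 0) are resampled.
#'
#' @param n_fibers number of fibers.
#' @param radius_distribution named list, e.g.
#'   `list(name = "lognormal", median = 0.5, sigma = 0.4)` (micrometres).
#' @param g_distribution named list: `list(name = "constant", value = 0.7)`,
#'   `list(name = "truncnorm", mean = 0.7, sd = 0.05)`, or
#'   `list(name = "mixture", mean = 0.65, sd = 0.05, unmyelinated_fraction = 0.2)`.
#' @param voxel_area voxel area in um^2, or `NULL` to derive it from
#'   `target_fvf`.
#' @param target_fvf if given, the voxel area is scaled so the realised FVF
#'   equals this value exactly (must not exceed the hexagonal packing bound
#'   ~0.9069).
#' @param seed integer seed; identical seeds give identical populations.
#' @return a [fiber_population()].
#' @export
sample_population <- function(n_fibers,
                              radius_distribution = list(name = "lognormal",
                                                         median = 0.5,
                                                         sigma = 0.4),
                              g_distribution = list(name = "constant",
                                                    value = 0.7),
                              voxel_area = NULL,
                              target_fvf = NULL,
                              seed = 1L) {
  stopifnot(n_fibers >= 1)
  packing_bound <- pi / (2 * sqrt(3))  # hexagonal circle packing
  if (!is.null(target_fvf) &&
      (target_fvf <= 0 || target_fvf > packing_bound))
    stop(sprintf("target_fvf must lie in (0, %.4f] (packing bound)",
                 packing_bound))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  radii <- switch(radius_distribution$name,
    lognormal = stats::rlnorm(n_fibers,
                              meanlog = log(radius_distribution$median),
                              sdlog = radius_distribution$sigma),
    constant = rep(radius_distribution$value, n_fibers),
    stop("unknown radius distribution: ", radius_distribution$name)
  )
  bad <- which(!is.finite(radii) | radii <= 0)
  while (length(bad)) {  # resample rejected draws
    radii[bad] <- stats::rlnorm(length(bad),
                                meanlog = log(radius_distribution$median),
                                sdlog = radius_distribution$sigma)
    bad <- which(!is.finite(radii) | radii <= 0)
  }

  g <- switch(g_distribution$name,
    constant = rep(g_distribution$value, n_fibers),
    truncnorm = rtrunc_unit(n_fibers, g_distribution$mean, g_distribution$sd),
    mixture = {
      unmy <- stats::runif(n_fibers) < g_distribution$unmyelinated_fraction
      out <- rtrunc_unit(n_fibers, g_distribution$mean, g_distribution$sd)
      out[unmy] <- 1
      out
    },
    stop("unknown g distribution: ", g_distribution$name)
  )

  if (!is.null(target_fvf)) {
    voxel_area <- sum(pi * radii^2) / target_fvf
  } else if (is.null(voxel_area)) {
    voxel_area <- sum(pi * radii^2) / 0.5  # default: half-filled voxel
  }
  fiber_population(radii, g, voxel_area)
}

# normal truncated to (0, 1] by resampling
rtrunc_unit <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= 0 | x > 1)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x <= 0 | x > 1)
  }
  x
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Rushton conduction-velocity factor
#'
#' For a myelinated fiber of fixed outer diameter, conduction velocity is
#' proportional to f(g) = g * sqrt(ln(1/g)) (Rushton's classical result).
#' The factor is unimodal on (0, 1) with its maximum at g = 1/sqrt(e)
#' ~ 0.607, the "optimal" g-ratio of about 0.6.
#'
#' @param g numeric vector of g-ratios, strictly inside (0, 1).
#' @return f(g), same length as `g`.
#' @export
conduction_velocity_factor <- function(g) {
  if (any(!is.finite(g)) || any(g <= 0) || any(g >= 1))
    stop("g must lie strictly inside (0, 1)")
  g * sqrt(log(1 / g))
}

#' Locate the g-ratio that maximises conduction velocity
#'
#' Dense grid search over (0, 1) followed by local refinement with
#' [stats::optimize()]. The analytic answer is 1/sqrt(e).
#'
#' @param step grid spacing, default 1e-4.
#' @return a list with `g_opt` and `f_max`.
#' @export
optimal_g_ratio <- function(step = 1e-4) {
  grid <- seq(step, 1 - step, by = step)
  f <- conduction_velocity_factor(grid)
  i <- which.max(f)
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]
  opt <- stats::optimize(conduction_velocity_factor, c(lo, hi),
                         maximum = TRUE, tol = 1e-12)
  list(g_opt = opt$maximum, f_max = opt$objective)
}

#' Export a fiber population as TSV
#'
#' One fiber per row with columns `outer_radius` and `g`.
#' @param pop a [fiber_population()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_population_tsv <- function(pop, path) {
  check_population(pop)
  utils::write.table(pop$fibers[, c("outer_radius", "g")], path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a fiber population from TSV
#' @param path TSV with columns `outer_radius`, `g`.
#' @param voxel_area voxel area in um^2.
#' @return a [fiber_population()].
#' @export
read_population_tsv <- function(path, voxel_area) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  fiber_population(df$outer_radius, df$g, voxel_area)
}
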