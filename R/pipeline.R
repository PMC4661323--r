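#' Read an FSL-style gradient table
#'
#' `bvals` is a whitespace-separated row of b-values; `bvecs` holds three
#' whitespace-separated rows (x, y, z components). Vectors for b > 0 rows
#' are normalised to unit length (with a warning if they were not); zero
#' vectors are only accepted where b = 0.
#'
#' @param bvals_path,bvecs_path text file paths.
#' @param n_volumes optional expected volume count, checked if given.
#' @return list with `bvals` (numeric) and `bvecs` (n x 3 matrix).
#' @export
read_gradient_table <- function(bvals_path, bvecs_path, n_volumes = NULL) {
  for (p in c(bvals_path, bvecs_path))
    if (!file.exists(p)) stop("no such file: ", p)
  bvals <- scan(bvals_path, what = numeric(), quiet = TRUE)
  raw <- readLines(bvecs_path, warn = FALSE)
  raw <- raw[nzchar(trimws(raw))]
  if (length(raw) != 3L)
    stop("bvecs file must have exactly 3 non-empty rows, got ", length(raw))
  rows <- lapply(raw, function(l) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
    if (any(is.na(v))) stop("non-numeric token in bvecs")
    v
  })
  if (length(unique(lengths(rows))) != 1L)
    stop("ragged bvecs rows")
  bvecs <- do.call(cbind, lapply(rows, identity))
  if (nrow(bvecs) != length(bvals))
    stop(sprintf("bvals has %d entries but bvecs has %d columns",
                 length(bvals), nrow(bvecs)))
  if (!is.null(n_volumes) && length(bvals) != n_volumes)
    stop(sprintf("gradient table has %d rows but the series has %d volumes",
                 length(bvals), n_volumes))
  nrm <- sqrt(rowSums(bvecs^2))
  zero <- nrm < 1e-8
  if (any(zero & bvals > 0)) stop("zero gradient vector with b > 0")
  off <- !zero & abs(nrm - 1) > 1e-4
  if (any(off)) {
    warning(sum(off), " non-unit gradient vector(s) normalised")
  }
  bvecs[!zero, ] <- bvecs[!zero, ] / nrm[!zero]
  list(bvals = bvals, bvecs = bvecs)
}

#' Write an FSL-style gradient table
#' @param bvals numeric vector; `bvecs` n x 3 matrix.
#' @param bvals_path,bvecs_path output paths.
#' @param bvecs gradient directions.
#' @return invisibly, the two paths.
#' @export
write_gradient_table <- function(bvals, bvecs, bvals_path, bvecs_path) {
  writeLines(paste(format(bvals, trim = TRUE), collapse = " "), bvals_path)
  writeLines(apply(t(bvecs), 1, function(r)
    paste(format(r, trim = TRUE, digits = 10), collapse = " ")), bvecs_path)
  invisible(c(bvals_path, bvecs_path))
}

pipeline_defaults <- function() {
  list(
    stages = c("simulate", "fit-mpm", "fit-dti", "density", "calibrate",
               "map", "group"),
    seed = 1L,
    n_echoes = 6L,
    g_reference = 0.7,
    calibration_mode = "mean-of-g",
    calibration_subject = 1L,
    cov_threshold = 0.3,
    prob_threshold = 0.5,
    histogram_bins = 64L,
    correct_distortion = TRUE,
    phantom = list(),
    log_level = "info"
  )
}

#' Build and validate a pipeline run configuration
#'
#' Merges user settings over the defaults; unknown keys are rejected so
#' typos cannot silently change a run. The full configuration is serialised
#' into every output manifest, making each run reproducible from its
#' manifest alone.
#'
#' @param ... settings to override, or a single named list.
#' @return a validated `run_config` list.
#' @export
run_config <- function(...) {
  user <- list(...)
  if (length(user) == 1L && is.null(names(user)) && is.list(user[[1]]))
    user <- user[[1]]
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, user)
  bad <- setdiff(cfg$stages, pipeline_defaults()$stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (cfg$cov_threshold <= 0) stop("cov_threshold must be positive")
  if (cfg$g_reference <= 0 || cfg$g_reference > 1)
    stop("g_reference must lie in (0, 1]")
  structure(cfg, class = "run_config")
}

#' Read a run configuration from JSON
#' @param path JSON file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  run_config(jsonlite::fromJSON(path, simplifyVector = TRUE))
}

log_msg <- function(cfg, level, ...) {
  levels <- c(debug = 1, info = 2, warn = 3, quiet = 4)
  if (levels[[cfg$log_level]] <= levels[[level]])
    message(sprintf("[%s] %s", level, paste0(...)))
  invisible(NULL)
}

#' Run the synthetic g-ratio pipeline end to end
#'
#' Executes the requested stages — phantom simulation, MPM fitting, tensor
#' fitting, density, calibration, g-ratio mapping and group statistics — on
#' a synthetic cohort, writes NIfTI maps, gradient tables, TSV tables and a
#' JSON manifest to `out_dir`, and returns the in-memory results. The
#' manifest records the package version, the full configuration (seed
#' included) and MD5 checksums of every written file; a rerun with the same
#' configuration reproduces the outputs exactly. Requesting `map` without
#' `calibrate` (and without a stored alpha) is an error.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with `manifest`, `cohort`, `results`,
#'   `calibration`, `group`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("gratio-run-")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  st <- config$stages
  outputs <- character()
  emit <- function(obj, name, writer = write_volume) {
    p <- file.path(out_dir, name)
    writer(obj, p)
    outputs <<- c(outputs, p)
    p
  }

  if (!"simulate" %in% st)
    stop("this driver operates on synthetic cohorts; include the 'simulate' stage")
  log_msg(config, "info", "simulate: generating cohort")
  spec <- do.call(phantom_spec, utils::modifyList(list(seed = config$seed),
                                                  config$phantom))
  cohort <- generate_cohort(spec)
  s1 <- cohort[[1]]
  emit(s1$truth$g, "sub-01_truth_g.nii.gz")
  write_gradient_table(s1$dwi$bvals, s1$dwi$bvecs,
                       file.path(out_dir, "bvals"),
                       file.path(out_dir, "bvecs"))
  outputs <- c(outputs, file.path(out_dir, c("bvals", "bvecs")))

  results <- NULL; calibration <- NULL; group <- NULL
  need_maps <- any(c("fit-mpm", "fit-dti", "density", "calibrate", "map",
                     "group") %in% st)
  if ("map" %in% st && !"calibrate" %in% st)
    stop("stage 'map' requires a calibration: include the 'calibrate' stage")
  if (need_maps) {
    if ("calibrate" %in% st) {
      log_msg(config, "info", "calibrate: solving alpha on subject ",
              config$calibration_subject)
      cal_sub <- cohort[[config$calibration_subject]]
      cal_run <- gratio_pipeline(cal_sub,
                                 correct_distortion = config$correct_distortion,
                                 g_reference = config$g_reference,
                                 n_echoes = config$n_echoes)
      calibration <- cal_run$calibration
      jsonlite::write_json(unclass(calibration),
                           file.path(out_dir, "calibration.json"),
                           auto_unbox = TRUE, digits = NA)
      outputs <- c(outputs, file.path(out_dir, "calibration.json"))
    }
    if ("map" %in% st || "group" %in% st) {
      log_msg(config, "info", "map: computing g-ratio maps")
      results <- lapply(cohort, function(s)
        gratio_pipeline(s, calibration = calibration,
                        correct_distortion = config$correct_distortion,
                        n_echoes = config$n_echoes))
      emit(results[[1]]$g$g_map, "sub-01_gratio.nii.gz")
      emit(inherit_affine(array(as.numeric(results[[1]]$g$validity_mask),
                                dim(results[[1]]$g$validity_mask)[1:3]),
                          results[[1]]$g$g_map),
           "sub-01_gratio_valid.nii.gz")
    }
  }
  if ("group" %in% st) {
    log_msg(config, "info", "group: cohort statistics")
    stack <- group_stack(lapply(results, function(r) r$g$g_map),
                         vapply(cohort, `[[`, "", "id"))
    gsum <- group_summary(stack)
    cmask <- cov_threshold_mask(gsum, config$cov_threshold)
    wm <- array(as.logical(cohort[[1]]$wm_mask), spec$dwi_shape)
    hist_tbl <- wm_histogram(gsum$mean_map, wm, cmask,
                             bins = config$histogram_bins)
    parc <- parcellate_cc(cohort[[1]]$cc_mask, 8L)
    roi <- roi_statistics(stack, parc)
    emit(gsum$mean_map, "group_mean_g.nii.gz")
    emit(gsum$cov_map, "group_cov_g.nii.gz")
    p <- file.path(out_dir, "cc_roi_table.tsv")
    utils::write.table(roi$table, p, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    outputs <- c(outputs, p)
    p <- file.path(out_dir, "wm_histogram.tsv")
    utils::write.table(hist_tbl, p, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    outputs <- c(outputs, p)
    group <- list(summary = gsum, cov_mask = cmask, histogram = hist_tbl,
                  cc_parcellation = parc, roi = roi)
  }

  manifest <- list(
    package = "gratiomap",
    version = as.character(utils::packageVersion("gratiomap")),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    config = unclass(config),
    outputs = lapply(outputs, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, out_dir = out_dir, cohort = cohort,
                 results = results, calibration = calibration,
                 group = group))
}
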