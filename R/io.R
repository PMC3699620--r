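# NIfTI volume I/O, configuration files and reports. All volumes are
# written as NIfTI-1 with spacing in the header; 2D volumes are stored as
# single-slice 3D for format uniformity. Arrays are index-ordered
# (column-major) with voxel centre (i - 0.5) * spacing; world coordinates
# follow the NIfTI affine.

#' Read and write NIfTI volumes
#'
#' Round trips preserve integer label volumes bit-exactly and field volumes
#' to float precision, and keep (possibly anisotropic) spacing in the
#' header.
#'
#' @param path file path (.nii or .nii.gz).
#' @param label logical; when \code{TRUE}, validate that the volume contains
#'   finite integer codes.
#' @param drop drop trailing singleton dimensions (so 2D volumes come back
#'   as matrices).
#' @return \code{readVolume}: list with \code{data} (array) and
#'   \code{spacing} (mm per axis).
#' @export
readVolume <- function(path, label = FALSE, drop = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("malformed NIfTI file: ", path,
                                           " (", conditionMessage(e), ")"))
  dat <- array(as.double(img), dim(img))
  spacing <- RNifti::pixdim(img)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("non-positive voxel spacing in header of ", path)
  if (label) {
    if (any(!is.finite(dat)))
      stop("label volume contains non-finite values: ", path)
    if (max(abs(dat - round(dat))) > 1e-6)
      stop("label volume contains non-integer values: ", path)
    dat <- array(as.integer(round(dat)), dim(dat))
  }
  if (drop) {
    d <- dim(dat)
    while (length(d) > 2 && d[length(d)] == 1L) d <- d[-length(d)]
    dim(dat) <- d
    spacing <- spacing[seq_along(d)]
  }
  list(data = dat, spacing = as.double(spacing))
}

#' @rdname readVolume
#' @param volume matrix or array to write.
#' @param spacing voxel spacing in mm per axis.
#' @export
writeVolume <- function(volume, spacing, path) {
  d <- dim(volume)
  spacing <- rep_len(as.double(spacing), length(d))
  if (any(spacing <= 0)) stop("spacing must be positive")
  if (length(d) == 2) { # store 2D as single-slice 3D
    dim(volume) <- c(d, 1L)
    spacing <- c(spacing, 1)
  }
  img <- RNifti::asNifti(volume)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a thickness field as a point table
#'
#' CSV columns: point coordinates in mm, the time point, and the thickness.
#'
#' @param thickness a [ThicknessField-class].
#' @param timepoint time index recorded in the table.
#' @param path output CSV path.
#' @export
writeThicknessCSV <- function(thickness, timepoint, path) {
  tab <- thicknessTable(thickness)
  tab <- cbind(tab[seq_len(ncol(thickness@points))],
               timepoint = timepoint,
               thickness_mm = tab$thickness_mm)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

# --- run configuration ----------------------------------------------------

.defaultConfig <- function() {
  list(
    seed = 1L,
    verbosity = 0L,
    phantom = list(
      grid_shape = c(128L, 128L), voxel_spacing = c(1, 1), n_timepoints = 5L,
      base_means = c(25, 85, 105), per_step_decline = c(0, 2, 4),
      noise_sigma = 4, pve_sigma = 1, baseline_thickness = 3,
      shrinkage_rate = 0.1, prior_blur_sigma = 2),
    evolution = list(
      nu = 0.5, lambda_s = 1, mu = 0.5, omega = 0.5,
      thickness_range = c(1, 6.5), n_inner = 50L, n_outer = 3L),
    paths = list(out_dir = "cortex4d_out"))
}

#' Read or generate a run configuration
#'
#' Structured YAML mirroring the phantom and evolution parameters; unknown
#' keys are rejected so typos fail loudly.
#'
#' @param path YAML file path.
#' @return nested configuration list.
#' @export
readConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  def <- .defaultConfig()
  checkKeys <- function(got, allowed, where) {
    bad <- setdiff(names(got), allowed)
    if (length(bad))
      stop("unknown config key(s) in ", where, ": ", paste(bad, collapse = ", "))
  }
  checkKeys(cfg, names(def), "top level")
  for (sec in intersect(names(cfg), c("phantom", "evolution", "paths")))
    checkKeys(cfg[[sec]], names(def[[sec]]), sec)
  out <- def
  for (k in names(cfg)) {
    if (is.list(def[[k]])) out[[k]][names(cfg[[k]])] <- cfg[[k]]
    else out[[k]] <- cfg[[k]]
  }
  out
}

#' @rdname readConfig
#' @export
writeDefaultConfig <- function(path) {
  yaml::write_yaml(.defaultConfig(), path)
  invisible(path)
}

.specFromConfig <- function(cfg) {
  ph <- cfg$phantom
  phantomSpec(gridShape = ph$grid_shape, voxelSpacing = ph$voxel_spacing,
              nTimepoints = ph$n_timepoints, baseMeans = ph$base_means,
              perStepDecline = ph$per_step_decline,
              noiseSigma = ph$noise_sigma, pveSigma = ph$pve_sigma,
              baselineThickness = ph$baseline_thickness,
              shrinkageRate = ph$shrinkage_rate, rngSeed = cfg$seed)
}

.paramsFromConfig <- function(cfg) {
  ev <- cfg$evolution
  evolutionParams(nu = ev$nu, lambdaS = ev$lambda_s, mu = ev$mu,
                  omega = ev$omega, range = ev$thickness_range,
                  nInner = ev$n_inner, nOuter = ev$n_outer,
                  seed = cfg$seed)
}

#' Write a JSON report
#'
#' @param report named list.
#' @param path output path.
#' @export
writeReport <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
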