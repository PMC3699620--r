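#' @import methods
NULL

# Tissue class order used everywhere in the package: background, CSF, GM, WM.
# Label codes are 0 (background), 1 (CSF), 2 (GM), 3 (WM).
.CLASSES <- c("bg", "csf", "gm", "wm")

#' Phantom specification
#'
#' Parameters of the longitudinal atrophy phantom: a nested brain-like
#' geometry (WM core, GM ribbon of known uniform thickness, CSF shell)
#' imaged over several time points with an aging intensity schedule,
#' additive Gaussian noise, partial-volume smoothing, and localized GM
#' atrophy inside a spherical region controlled by a shrinkage rate.
#'
#' @slot gridShape integer voxel counts per axis (length 2 or 3).
#' @slot voxelSpacing mm per axis.
#' @slot nTimepoints number of serial images (>= 2).
#' @slot baseMeans mean intensities of (CSF, GM, WM) at the first time point.
#' @slot perStepDecline per-time-step decrement of the (CSF, GM, WM) means.
#' @slot noiseSigma standard deviation of additive Gaussian noise (intensity).
#' @slot pveSigma Gaussian smoothing scale in mm emulating partial volume.
#' @slot wmRadius radius of the WM core in mm.
#' @slot wobbleAmp,wobbleFreq relative amplitude and angular frequency of the
#'   sinusoidal boundary perturbation of the WM core (0 gives concentric
#'   circles/spheres).
#' @slot csfShell thickness of the CSF shell in mm.
#' @slot baselineThickness GM ribbon thickness in mm, within (0, 6.5).
#' @slot atrophyCenter physical coordinate (mm) of the atrophy sphere centre.
#' @slot atrophyRadius atrophy sphere radius in mm.
#' @slot shrinkageRate fractional in-sphere GM volume loss at the final time
#'   point, in [0, 1).
#' @slot rngSeed integer seed controlling the noise streams.
#' @exportClass PhantomSpec
setClass("PhantomSpec", representation(
  gridShape = "integer",
  voxelSpacing = "numeric",
  nTimepoints = "integer",
  baseMeans = "numeric",
  perStepDecline = "numeric",
  noiseSigma = "numeric",
  pveSigma = "numeric",
  wmRadius = "numeric",
  wobbleAmp = "numeric",
  wobbleFreq = "numeric",
  csfShell = "numeric",
  baselineThickness = "numeric",
  atrophyCenter = "numeric",
  atrophyRadius = "numeric",
  shrinkageRate = "numeric",
  rngSeed = "integer"
))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  nd <- length(object@gridShape)
  if (!nd %in% 2:3) msg <- c(msg, "gridShape must have length 2 or 3")
  if (any(object@gridShape < 8L)) msg <- c(msg, "grid too small")
  if (length(object@voxelSpacing) != nd || any(object@voxelSpacing <= 0))
    msg <- c(msg, "voxelSpacing must be positive, one value per axis")
  if (object@nTimepoints < 2L) msg <- c(msg, "nTimepoints must be >= 2")
  if (length(object@baseMeans) != 3 || any(diff(object@baseMeans) <= 0))
    msg <- c(msg, "baseMeans must be strictly increasing for (CSF, GM, WM)")
  if (length(object@perStepDecline) != 3 || any(object@perStepDecline < 0))
    msg <- c(msg, "perStepDecline must be three nonnegative values")
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  if (object@pveSigma < 0) msg <- c(msg, "pveSigma must be >= 0")
  if (object@shrinkageRate < 0 || object@shrinkageRate >= 1)
    msg <- c(msg, "shrinkageRate must lie in [0, 1)")
  if (object@baselineThickness <= 0 || object@baselineThickness >= 6.5)
    msg <- c(msg, "baselineThickness must lie in (0, 6.5) mm")
  if (object@atrophyRadius <= 0) msg <- c(msg, "atrophyRadius must be > 0")
  extent <- object@gridShape * object@voxelSpacing
  if (length(object@atrophyCenter) == nd) {
    if (any(object@atrophyCenter - object@atrophyRadius < 0) ||
        any(object@atrophyCenter + object@atrophyRadius > extent))
      msg <- c(msg, "atrophy sphere must lie inside the grid")
  } else msg <- c(msg, "atrophyCenter must have one coordinate per axis")
  half <- min(extent) / 2
  if (object@wmRadius * (1 + abs(object@wobbleAmp)) + object@baselineThickness +
      object@csfShell + 2 * max(object@voxelSpacing) >= half)
    msg <- c(msg, "grid too small for the requested WM/GM/CSF shells")
  if (length(msg)) msg else TRUE
})

#' Longitudinal atrophy phantom
#'
#' @slot labels per-time-point label volumes, codes 0 = background, 1 = CSF,
#'   2 = GM, 3 = WM.
#' @slot cleanImages noise-free intensity volumes.
#' @slot images noisy, partial-volume-smoothed intensity volumes.
#' @slot gtThickness per-time-point ground-truth [ThicknessField-class] on
#'   the outer (GM/CSF) boundary.
#' @slot priors per-class prior probability volumes (bg, csf, gm, wm),
#'   blurred from the baseline ground truth.
#' @slot spec the [PhantomSpec-class] that produced the object.
#' @exportClass Phantom
setClass("Phantom", representation(
  labels = "list",
  cleanImages = "list",
  images = "list",
  gtThickness = "list",
  priors = "list",
  spec = "PhantomSpec"
))

#' Time-ordered intensity series on a common grid
#'
#' @slot images list of intensity volumes, one per time point, identical dims.
#' @slot spacing voxel spacing in mm per axis.
#' @exportClass LongitudinalSeries
setClass("LongitudinalSeries",
  representation(images = "list", spacing = "numeric"))

setValidity("LongitudinalSeries", function(object) {
  if (length(object@images) < 1) return("series must contain images")
  d0 <- dim(object@images[[1]])
  ok <- vapply(object@images, function(x) identical(dim(x), d0), logical(1))
  if (!all(ok)) return("all images must share one grid")
  if (length(object@spacing) != length(d0) || any(object@spacing <= 0))
    return("spacing must be positive, one value per axis")
  TRUE
})

#' Three nested level sets for one time point
#'
#' Signed-distance fields (mm, positive inside) whose zero levels encode the
#' WM surface (phi1), the WM+GM outer cortical surface (phi2) and the
#' WM+GM+CSF brain surface (phi3), nested as
#' region(phi1 >= 0) within region(phi2 >= 0) within region(phi3 >= 0).
#'
#' @slot phi1,phi2,phi3 scalar fields on the image grid.
#' @slot spacing mm per axis.
#' @slot timeIndex 1-based time point index.
#' @exportClass LevelSetTriple
setClass("LevelSetTriple", representation(
  phi1 = "array", phi2 = "array", phi3 = "array",
  spacing = "numeric", timeIndex = "integer"
))

setValidity("LevelSetTriple", function(object) {
  d <- dim(object@phi1)
  if (!identical(dim(object@phi2), d) || !identical(dim(object@phi3), d))
    return("phi fields must share one grid")
  if (length(object@spacing) != length(d) || any(object@spacing <= 0))
    return("spacing must be positive, one value per axis")
  TRUE
})

#' Per-voxel tissue memberships derived from a level-set triple
#'
#' Smooth region indicators for WM, GM, CSF and background built from
#' regularized Heaviside compositions; the four fields sum to one at every
#' voxel.
#'
#' @slot wm,gm,csf,bg membership fields in \[0, 1\].
#' @exportClass MembershipFields
setClass("MembershipFields",
  representation(wm = "array", gm = "array", csf = "array", bg = "array"))

#' Local Gaussian intensity model
#'
#' Kernel-weighted per-location Gaussian parameters (mean and variance) for
#' each tissue class, used by the local intensity fitting energy.
#'
#' @slot mean list of per-class local mean fields (bg, csf, gm, wm).
#' @slot var list of per-class local variance fields, floored at the
#'   configured variance floor.
#' @slot kernelSigma kernel scale in mm.
#' @exportClass LocalGaussianField
setClass("LocalGaussianField",
  representation(mean = "list", var = "list", kernelSigma = "numeric"))

#' Cortical thickness sampled on a zero-level surface
#'
#' @slot points surface point coordinates (mm), one row per point.
#' @slot thickness thickness in mm per point.
#' @slot field volumetric extension of the thickness used in penalty
#'   integrals (distance-to-inner-surface, clamped at zero).
#' @slot spacing mm per axis.
#' @exportClass ThicknessField
setClass("ThicknessField", representation(
  points = "matrix", thickness = "numeric",
  field = "array", spacing = "numeric"
))

setValidity("ThicknessField", function(object) {
  if (nrow(object@points) != length(object@thickness))
    return("one thickness value per surface point required")
  TRUE
})

#' Temporal neighborhood and anatomical correspondence
#'
#' For each time point, the neighboring time points used by the temporal
#' thickness-variation constraint (default the immediate neighbors) and the
#' displacement fields mapping current-grid coordinates into each neighbor's
#' grid. A \code{NULL} displacement denotes the identity map (pre-aligned
#' series).
#'
#' @slot neighbors list (per time point) of neighbor time indices.
#' @slot displacements list (per time point) of per-neighbor displacement
#'   arrays with dimensions c(grid, ndim) in mm, or \code{NULL} for identity.
#' @exportClass TemporalNeighborhood
setClass("TemporalNeighborhood",
  representation(neighbors = "list", displacements = "list"))

#' Evolution parameters
#'
#' Weights and numerical controls for the coupled level-set evolution. The
#' defaults are nu = 0.5 (length term), lambdaS = 1 (spatial thickness
#' constraint), mu = 0.5 (temporal thickness-variation constraint),
#' omega = 0.5 (atlas prior weight) and an admissible cortical thickness
#' range of [1, 6.5] mm.
#'
#' @slot nu length-term weight.
#' @slot lambdaS spatial thickness-constraint weight.
#' @slot mu temporal thickness-variation weight.
#' @slot omega atlas-prior weight in the data term.
#' @slot dmin,dmax admissible cortical thickness range in mm.
#' @slot dt artificial evolution time step (NA: 0.1 * min(spacing)^2).
#' @slot nInner inner gradient-descent iterations per outer loop.
#' @slot nOuter outer correspondence/segmentation alternations.
#' @slot eps Heaviside/Dirac regularization scale in mm
#'   (NA: 1.5 * min(spacing)).
#' @slot kernelSigma local Gaussian kernel scale in mm
#'   (NA: 3 * min(spacing)).
#' @slot varFloor variance floor (intensity squared).
#' @slot priorFloor probability floor used inside log(prior).
#' @slot reinitEvery reinitialize the signed distance property every this
#'   many inner iterations.
#' @slot refitEvery refit the local Gaussian model every this many inner
#'   iterations (1 = every step).
#' @slot seed integer seed (phantom noise and any stochastic initialization;
#'   the PDE solve itself is deterministic).
#' @exportClass EvolutionParams
setClass("EvolutionParams", representation(
  nu = "numeric", lambdaS = "numeric", mu = "numeric", omega = "numeric",
  dmin = "numeric", dmax = "numeric", dt = "numeric",
  nInner = "integer", nOuter = "integer", eps = "numeric",
  kernelSigma = "numeric", varFloor = "numeric", priorFloor = "numeric",
  reinitEvery = "integer", refitEvery = "integer", seed = "integer"
))

setValidity("EvolutionParams", function(object) {
  msg <- character()
  for (w in c("nu", "lambdaS", "mu", "omega"))
    if (slot(object, w) < 0) msg <- c(msg, paste(w, "must be >= 0"))
  if (!(object@dmin > 0 && object@dmin < object@dmax))
    msg <- c(msg, "thickness range must satisfy 0 < dmin < dmax")
  if (!is.na(object@dt) && object@dt <= 0) msg <- c(msg, "dt must be > 0")
  if (object@nInner < 1L || object@nOuter < 1L ||
      object@reinitEvery < 1L || object@refitEvery < 1L)
    msg <- c(msg, "iteration counts and periods must be >= 1")
  if (!is.na(object@eps) && object@eps <= 0) msg <- c(msg, "eps must be > 0")
  if (object@varFloor <= 0) msg <- c(msg, "varFloor must be > 0")
  if (length(msg)) msg else TRUE
})

#' Segmentation state across the series
#'
#' @slot triples per-time-point [LevelSetTriple-class].
#' @slot gaussians per-time-point [LocalGaussianField-class].
#' @slot energyHistory recorded total-energy values over the run.
#' @exportClass SegmentationState
setClass("SegmentationState", representation(
  triples = "list", gaussians = "list", energyHistory = "numeric"
))

#' Result of a 4D segmentation run
#'
#' @slot labels per-time-point hard label volumes (0/1/2/3).
#' @slot thickness per-time-point [ThicknessField-class] on the outer
#'   cortical surface.
#' @slot report list with the energy trace, parameter echo and (when ground
#'   truth was supplied) Dice ratios.
#' @exportClass SegmentationResult
setClass("SegmentationResult",
  representation(labels = "list", thickness = "list", report = "list"))
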