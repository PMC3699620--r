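# Longitudinal atrophy phantom.
#
# The phantom emulates the simulation protocol used to validate the
# temporal-consistency claim: a nested WM/GM/CSF geometry over 5 serial
# scans, class mean intensities starting at (25, 85, 105) for (CSF, GM, WM)
# and declining by (0, 2, 4) per time step, additive Gaussian noise,
# Gaussian partial-volume smoothing, and localized GM atrophy inside a
# sphere controlled by a shrinkage rate (r = 0.1 means 10% in-sphere GM
# volume loss at the final time point).

#' Create a phantom specification
#'
#' @param gridShape voxel counts per axis (length 2 or 3); default 2D
#'   128 x 128.
#' @param voxelSpacing mm per axis.
#' @param nTimepoints number of time points (default 5).
#' @param baseMeans first-time-point mean intensities of (CSF, GM, WM).
#' @param perStepDecline per-step decrement of the (CSF, GM, WM) means.
#' @param noiseSigma additive Gaussian noise standard deviation.
#' @param pveSigma partial-volume Gaussian smoothing scale in mm.
#' @param wmRadius WM core radius in mm (default 0.28 x the smallest grid
#'   extent).
#' @param wobbleAmp,wobbleFreq sinusoidal perturbation of the WM boundary
#'   (relative amplitude and angular frequency); 0 amplitude gives
#'   concentric shapes.
#' @param csfShell CSF shell thickness in mm.
#' @param baselineThickness GM ribbon thickness in mm.
#' @param atrophyCenter physical centre (mm) of the atrophy sphere; default
#'   on the GM ribbon.
#' @param atrophyRadius atrophy sphere radius in mm (default 0.09 x the
#'   smallest grid extent).
#' @param shrinkageRate fractional in-sphere GM loss at the final time point.
#' @param rngSeed integer seed for the noise streams.
#' @return a [PhantomSpec-class] object.
#' @examples
#' spec <- phantomSpec(gridShape = c(64, 64), rngSeed = 1)
#' spec
#' @export
phantomSpec <- function(gridShape = c(128L, 128L),
                        voxelSpacing = rep(1, length(gridShape)),
                        nTimepoints = 5L,
                        baseMeans = c(25, 85, 105),
                        perStepDecline = c(0, 2, 4),
                        noiseSigma = 4,
                        pveSigma = 1,
                        wmRadius = NULL,
                        wobbleAmp = 0.08,
                        wobbleFreq = 3,
                        csfShell = 3,
                        baselineThickness = 3,
                        atrophyCenter = NULL,
                        atrophyRadius = NULL,
                        shrinkageRate = 0.1,
                        rngSeed = 1L) {
  gridShape <- as.integer(gridShape)
  voxelSpacing <- rep_len(as.double(voxelSpacing), length(gridShape))
  extent <- gridShape * voxelSpacing
  if (is.null(wmRadius)) wmRadius <- 0.28 * min(extent)
  if (is.null(atrophyRadius)) atrophyRadius <- 0.09 * min(extent)
  if (is.null(atrophyCenter)) {
    atrophyCenter <- extent / 2
    # drop the sphere onto the GM ribbon, on the +y side of the core
    atrophyCenter[2] <- atrophyCenter[2] + wmRadius + baselineThickness / 2
  }
  new("PhantomSpec",
    gridShape = gridShape, voxelSpacing = voxelSpacing,
    nTimepoints = as.integer(nTimepoints),
    baseMeans = as.double(baseMeans),
    perStepDecline = as.double(perStepDecline),
    noiseSigma = as.double(noiseSigma), pveSigma = as.double(pveSigma),
    wmRadius = as.double(wmRadius), wobbleAmp = as.double(wobbleAmp),
    wobbleFreq = as.double(wobbleFreq), csfShell = as.double(csfShell),
    baselineThickness = as.double(baselineThickness),
    atrophyCenter = as.double(atrophyCenter),
    atrophyRadius = as.double(atrophyRadius),
    shrinkageRate = as.double(shrinkageRate),
    rngSeed = as.integer(rngSeed))
}

# pairwise physical distance field to a point, plus azimuth of the xy plane
.radialGeometry <- function(spec) {
  d <- spec@gridShape
  h <- spec@voxelSpacing
  ctr <- d * h / 2
  ax <- lapply(seq_along(d), function(a) .axisCoords(d[a], h[a]) - ctr[a])
  if (length(d) == 2) {
    dx <- matrix(ax[[1]], d[1], d[2])
    dy <- matrix(ax[[2]], d[1], d[2], byrow = TRUE)
    list(dist = sqrt(dx^2 + dy^2), theta = atan2(dy, dx))
  } else {
    dx <- array(ax[[1]], d)
    dy <- array(rep(ax[[2]], each = d[1]), d)
    dz <- array(rep(ax[[3]], each = d[1] * d[2]), d)
    list(dist = sqrt(dx^2 + dy^2 + dz^2), theta = atan2(dy, dx))
  }
}

.sphereMask <- function(dims, spacing, center, radius) {
  ax <- lapply(seq_along(dims), function(a) .axisCoords(dims[a], spacing[a]) - center[a])
  d2 <- 0
  for (a in seq_along(dims)) {
    comp <- switch(a,
      array(ax[[1]], dims),
      array(rep(ax[[2]], each = dims[1]), dims),
      array(rep(ax[[3]], each = dims[1] * dims[2]), dims))
    d2 <- d2 + comp^2
  }
  d2 <= radius^2
}

#' Build the baseline label volume
#'
#' Constructs the nested geometry by offsetting the WM core's signed
#' distance: the GM ribbon is the band within \code{baselineThickness} mm of
#' the WM boundary and the CSF shell the next \code{csfShell} mm, so the GM
#' ribbon has per-point thickness equal to \code{baselineThickness} up to
#' voxel quantization, including for perturbed (non-circular) cores.
#'
#' @param spec a [PhantomSpec-class].
#' @return a label volume with codes 0 = background, 1 = CSF, 2 = GM,
#'   3 = WM.
#' @export
makeBaselineLabels <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  geo <- .radialGeometry(spec)
  rTheta <- spec@wmRadius * (1 + spec@wobbleAmp * cos(spec@wobbleFreq * geo$theta))
  wm <- geo$dist <= rTheta
  if (!any(wm) || all(wm))
    stop("grid too small for the requested WM core")
  sdf <- sdfFromMask(wm, spec@voxelSpacing)
  lab <- array(0L, spec@gridShape)
  lab[sdf >= -(spec@baselineThickness + spec@csfShell)] <- 1L
  lab[sdf >= -spec@baselineThickness] <- 2L
  lab[wm] <- 3L
  if (length(unique(as.integer(lab))) != 4L)
    stop("grid too small: not all four tissue codes are present")
  lab
}

#' Apply localized GM atrophy over the series
#'
#' Outer-boundary thinning of the GM ribbon inside the atrophy sphere: at
#' time point t the in-sphere GM volume is reduced by
#' \code{shrinkageRate * (t - 1) / (nTimepoints - 1)} relative to baseline,
#' removing the outermost GM voxels first (they become CSF, as cortical
#' thinning exposes sulcal CSF). Labels outside the sphere are unchanged and
#' time point 1 equals the baseline.
#'
#' @param baselineLabels label volume from [makeBaselineLabels()].
#' @param spec a [PhantomSpec-class].
#' @return list of label volumes, one per time point.
#' @export
simulateAtrophy <- function(baselineLabels, spec) {
  stopifnot(is(spec, "PhantomSpec"))
  nT <- spec@nTimepoints
  sphere <- .sphereMask(dim(baselineLabels), spec@voxelSpacing,
                        spec@atrophyCenter, spec@atrophyRadius)
  idx <- which(baselineLabels == 2L & sphere)
  if (length(idx) == 0L)
    stop("atrophy sphere does not intersect the GM ribbon")
  sdf <- sdfFromMask(baselineLabels == 3L, spec@voxelSpacing)
  # outermost GM first (most negative distance to the WM core), stable order
  idx <- idx[order(sdf[idx], idx)]
  n0 <- length(idx)
  lapply(seq_len(nT), function(t) {
    k <- round(spec@shrinkageRate * (t - 1) / (nT - 1) * n0)
    lab <- baselineLabels
    if (k > 0) lab[idx[seq_len(k)]] <- 1L
    lab
  })
}

#' Noise-free intensities for one time point
#'
#' Class means follow the aging schedule: CSF constant, GM and WM declining
#' linearly per step, background 0.
#'
#' @param labels a label volume.
#' @param t time index in \code{1:nTimepoints}.
#' @param spec a [PhantomSpec-class].
#' @return an intensity volume.
#' @export
assignIntensities <- function(labels, t, spec) {
  stopifnot(is(spec, "PhantomSpec"))
  if (t < 1 || t > spec@nTimepoints) stop("time index out of range")
  means <- c(0, spec@baseMeans - spec@perStepDecline * (t - 1))
  out <- array(means[as.integer(labels) + 1L], dim(labels))
  out
}

#' Add noise and partial-volume smoothing
#'
#' Adds Gaussian noise of standard deviation \code{noiseSigma}, then smooths
#' with a Gaussian kernel of scale \code{pveSigma} mm to emulate the partial
#' volume effect. Deterministic for a given spec seed and time index; the
#' caller's RNG state is left untouched.
#'
#' @param cleanImage noise-free intensity volume.
#' @param spec a [PhantomSpec-class].
#' @param t time index selecting the noise stream.
#' @return an intensity volume.
#' @export
addNoiseAndPve <- function(cleanImage, spec, t = 1L) {
  stopifnot(is(spec, "PhantomSpec"))
  out <- cleanImage
  if (spec@noiseSigma > 0) {
    runif(1) # force RNG initialization so the state can be restored
    oldSeed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", oldSeed, envir = globalenv()))
    set.seed(.streamSeed(spec@rngSeed, t))
    out <- out + array(stats::rnorm(length(out), 0, spec@noiseSigma), dim(out))
  }
  if (spec@pveSigma > 0)
    out <- smoothField(out, spec@pveSigma, spec@voxelSpacing)
  out
}

#' Spatial priors from a label volume
#'
#' Blurred one-hot class maps, renormalized to sum to one at every voxel;
#' stands in for a population atlas.
#'
#' @param labels a label volume.
#' @param blurSigma blur scale in mm (0 gives one-hot priors).
#' @param spacing voxel spacing in mm.
#' @return list of four probability volumes named bg, csf, gm, wm.
#' @export
makePriors <- function(labels, blurSigma = 2, spacing = 1) {
  if (blurSigma < 0) stop("blurSigma must be >= 0")
  pri <- lapply(0:3, function(code) {
    m <- array(as.double(labels == code), dim(labels))
    if (blurSigma > 0) m <- smoothField(m, blurSigma, spacing) else m
  })
  tot <- Reduce(`+`, pri)
  tot[tot <= 0] <- 1
  pri <- lapply(pri, function(p) p / tot)
  names(pri) <- .CLASSES
  pri
}

#' Ground-truth cortical thickness of a label volume
#'
#' For each point on the outer (GM/CSF or GM/background) boundary, the
#' Euclidean distance in mm to the nearest point of the inner (WM/GM)
#' boundary, read off the signed distance to the WM core at face midpoints.
#'
#' @param labels a label volume containing WM and GM.
#' @param spacing voxel spacing in mm.
#' @return a [ThicknessField-class].
#' @export
groundTruthThickness <- function(labels, spacing = 1) {
  h <- .spacingFor(labels, spacing)
  wm <- labels == 3L
  if (!any(wm)) stop("label volume has no WM region")
  if (!any(labels == 2L)) stop("label volume has no GM ribbon")
  sdf <- sdfFromMask(wm, h)
  d <- dim(labels)
  pts <- NULL
  th <- NULL
  gm <- labels == 2L
  for (a in seq_along(d)) {
    for (dir in c(1L, -1L)) {
      nb <- .shift(labels, a, dir, fill = 0L)
      sel <- which(gm & (nb == 1L | nb == 0L))
      if (!length(sel)) next
      ai <- arrayInd(sel, d)
      coord <- sweep(ai - 0.5, 2, h, "*")
      coord[, a] <- coord[, a] + dir * h[a] / 2
      nbIdx <- ai
      nbIdx[, a] <- pmin(pmax(nbIdx[, a] + dir, 1L), d[a])
      lin <- nbIdx[, 1]
      mult <- 1
      for (ax in seq_along(d)[-1]) {
        mult <- mult * d[ax - 1]
        lin <- lin + (nbIdx[, ax] - 1L) * mult
      }
      tval <- -(sdf[sel] + sdf[lin]) / 2
      pts <- rbind(pts, coord)
      th <- c(th, tval)
    }
  }
  if (is.null(pts)) stop("label volume has no outer cortical boundary")
  th <- pmax(th, 1e-6)
  new("ThicknessField", points = pts, thickness = th,
      field = pmax(-sdf, 0), spacing = h)
}

#' Generate a full longitudinal phantom
#'
#' Runs the whole simulation chain: baseline geometry, atrophy series,
#' intensity schedule, noise + partial-volume smoothing, spatial priors
#' (blurred baseline truth) and ground-truth thickness. Identical spec (and
#' seed) gives a bit-identical phantom.
#'
#' @param spec a [PhantomSpec-class].
#' @param priorBlurSigma blur scale in mm for the synthetic atlas priors.
#' @return a [Phantom-class].
#' @examples
#' ph <- buildPhantom(phantomSpec(gridShape = c(64, 64), rngSeed = 3))
#' ph
#' @export
buildPhantom <- function(spec, priorBlurSigma = 2) {
  stopifnot(is(spec, "PhantomSpec"))
  baseline <- makeBaselineLabels(spec)
  labels <- simulateAtrophy(baseline, spec)
  clean <- lapply(seq_len(spec@nTimepoints), function(t)
    assignIntensities(labels[[t]], t, spec))
  images <- lapply(seq_len(spec@nTimepoints), function(t)
    addNoiseAndPve(clean[[t]], spec, t))
  gt <- lapply(labels, groundTruthThickness, spacing = spec@voxelSpacing)
  priors <- makePriors(baseline, priorBlurSigma, spec@voxelSpacing)
  new("Phantom", labels = labels, cleanImages = clean, images = images,
      gtThickness = gt, priors = priors, spec = spec)
}

#' Longitudinal series constructors
#'
#' @param images list of intensity volumes on one grid.
#' @param spacing voxel spacing in mm.
#' @return a [LongitudinalSeries-class].
#' @export
longitudinalSeries <- function(images, spacing = 1) {
  spacing <- rep_len(as.double(spacing), length(dim(images[[1]])))
  new("LongitudinalSeries", images = images, spacing = spacing)
}

#' @rdname longitudinalSeries
#' @param phantom a [Phantom-class].
#' @export
asSeries <- function(phantom) {
  stopifnot(is(phantom, "Phantom"))
  longitudinalSeries(phantom@images, phantom@spec@voxelSpacing)
}
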