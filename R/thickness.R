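# Cortical thickness from the signed-distance property, the spatial
# thickness-range constraint, and the temporal thickness-variation
# constraint across neighboring time points.

# zero crossings of phi along grid edges (each edge once, forward direction);
# returns sub-voxel point coordinates plus the interpolation weights needed
# to sample other fields at the same points
.zeroCrossings <- function(phi, spacing) {
  d <- dim(phi)
  h <- .spacingFor(phi, spacing)
  pts <- NULL; iLin <- integer(); jLin <- integer(); thetaAll <- numeric()
  pos <- phi >= 0
  for (a in seq_along(d)) {
    nbPhi <- .shiftc(phi, a, 1L)
    nbPos <- .shiftc(pos, a, 1L)
    cross <- which((pos != nbPos))
    # drop trailing-face self-comparisons (clamped shift repeats the edge)
    ai <- arrayInd(cross, d)
    keep <- ai[, a] < d[a]
    cross <- cross[keep]; ai <- ai[keep, , drop = FALSE]
    if (!length(cross)) next
    nj <- ai; nj[, a] <- nj[, a] + 1L
    lin <- nj[, 1]; mult <- 1
    for (ax in seq_along(d)[-1]) {
      mult <- mult * d[ax - 1]
      lin <- lin + (nj[, ax] - 1L) * mult
    }
    theta <- phi[cross] / (phi[cross] - phi[lin])
    coord <- sweep(ai - 0.5, 2, h, "*")
    coord[, a] <- coord[, a] + theta * h[a]
    pts <- rbind(pts, coord)
    iLin <- c(iLin, cross); jLin <- c(jLin, lin)
    thetaAll <- c(thetaAll, theta)
  }
  list(points = pts, i = iLin, j = jLin, theta = thetaAll)
}

#' Measure cortical thickness between two nested level sets
#'
#' At each zero-crossing point of the outer field, the thickness is the
#' magnitude of the inner signed-distance field there (sub-voxel
#' interpolated): because a signed distance function stores the Euclidean
#' distance to its zero-level surface, \eqn{|\phi_{inner}|} on the outer
#' surface is exactly the closest distance to the inner surface.
#'
#' @param phiInner,phiOuter reinitialized signed-distance fields with the
#'   inner region nested in the outer region.
#' @param spacing voxel spacing in mm.
#' @return a [ThicknessField-class]; its \code{field} slot carries the
#'   volumetric extension \eqn{\max(-\phi_{inner}, 0)}.
#' @examples
#' m <- matrix(FALSE, 61, 61)
#' xy <- expand.grid(x = 1:61, y = 1:61)
#' inner <- (xy$x - 31)^2 + (xy$y - 31)^2 <= 20^2
#' outer <- (xy$x - 31)^2 + (xy$y - 31)^2 <= 23^2
#' tf <- measureThickness(sdfFromMask(matrix(inner, 61), 1),
#'                        sdfFromMask(matrix(outer, 61), 1), 1)
#' mean(thicknessValues(tf)) # about 3 mm
#' @export
measureThickness <- function(phiInner, phiOuter, spacing = 1) {
  h <- .spacingFor(phiInner, spacing)
  if (any(phiOuter < phiInner - 1e-6))
    stop("inner surface is not nested inside the outer surface")
  zc <- .zeroCrossings(phiOuter, h)
  if (is.null(zc$points)) stop("outer field has no zero crossing")
  inn <- phiInner[zc$i] + zc$theta * (phiInner[zc$j] - phiInner[zc$i])
  th <- pmax(-inn, 1e-6)
  new("ThicknessField", points = zc$points, thickness = th,
      field = pmax(-phiInner, 0), spacing = h)
}

# one-sided quadratic thickness-range penalty shared by the energy and the
# flow. Thickness extensions are clamped at zero so the penalty has no
# gradient deep inside WM or outside the brain, and each penalty is gated to
# a band around its own surface (W2 near the outer zero level for the
# outer-measured thickness, W1 near the inner zero level for the
# inner-measured one) so the slow Cauchy tails of the regularized Heaviside
# cannot leak the penalty onto the other surface. Returns the energy
# density and the exact per-voxel gradients with respect to phi1 and phi2
# (lambda not yet applied).
.thicknessPenalty <- function(phi1, phi2, dmin, dmax, eps, W1 = 1, W2 = 1) {
  Touter <- pmax(-phi1, 0); i1 <- as.double(phi1 < 0)
  Tinner <- pmax(phi2, 0); i2 <- as.double(phi2 > 0)
  h1 <- heavisideEps(phi1, eps); h2 <- heavisideEps(phi2, eps)
  d1 <- diracEps(phi1, eps); d2 <- diracEps(phi2, eps)
  ppO <- pmax(Touter - dmax, 0); pmO <- pmax(dmin - Touter, 0)
  ppI <- pmax(Tinner - dmax, 0); pmI <- pmax(dmin - Tinner, 0)
  density <- W2 * (ppO^2 * h2 + pmO^2 * (1 - h2)) +
             W1 * (ppI^2 * (1 - h1) + pmI^2 * h1)
  g2 <- W2 * d2 * (ppO^2 - pmO^2) +
        W1 * i2 * (2 * ppI * (1 - h1) - 2 * pmI * h1)
  g1 <- -W2 * i1 * (2 * ppO * h2 - 2 * pmO * (1 - h2)) +
        W1 * d1 * (pmI^2 - ppI^2)
  list(density = density, g1 = g1, g2 = g2)
}

#' Spatial cortical-thickness range force
#'
#' Normal forces keeping the measured thickness within \code{[dmin, dmax]}:
#' zero wherever the thickness is in range, deflating the outer surface
#' (and inflating the inner) where the cortex is too thick, pushing the
#' surfaces apart where it is too thin, with magnitude proportional to
#' \code{lambdaS} times the violation. Zero inside the exclusion mask.
#'
#' @param phi1,phi2 inner/outer signed-distance fields.
#' @param range admissible thickness range in mm, \code{c(dmin, dmax)}.
#' @param lambdaS weight, >= 0.
#' @param eps Heaviside regularization scale in mm.
#' @param spacing voxel spacing in mm.
#' @param exclusionMask optional logical volume where the constraint is not
#'   imposed (ventricular CSF / subcortical GM on real data).
#' @return list of force fields \code{f1}, \code{f2} (descent directions:
#'   the evolution adds \code{dt * f}).
#' @export
spatialThicknessForce <- function(phi1, phi2, range = c(1, 6.5), lambdaS = 1,
                                  eps = 1.5, spacing = 1,
                                  exclusionMask = NULL) {
  stopifnot(lambdaS >= 0, range[1] > 0, range[1] < range[2])
  h <- .spacingFor(phi1, spacing)
  W <- if (is.null(exclusionMask)) 1 else as.double(!exclusionMask)
  # each penalty is meaningful only near its own surface: the outer-measured
  # thickness extension (-phi1) degenerates to zero at the inner surface and
  # the inner-measured one (phi2) at the outer surface
  W1 <- W * (abs(phi1) <= 2 * min(h))
  W2 <- W * (abs(phi2) <= 2 * min(h))
  pen <- .thicknessPenalty(phi1, phi2, range[1], range[2], eps, W1, W2)
  list(f1 = -lambdaS * pen$g1, f2 = -lambdaS * pen$g2)
}

#' Temporal cortical-thickness difference field
#'
#' Sum of thickness differences between the current time point and its
#' temporal neighbors, \eqn{D_t(x) = \sum_{s \in N(t)} (T_t(x) -
#' T_s(w_{t\to s}(x)))}, with the neighbor thickness sampled through the
#' anatomical correspondence. Positive values mean the current cortex is
#' thicker than its neighbors. Series endpoints use the single available
#' neighbor (unnormalized sum).
#'
#' @param Tt thickness field of the current time point (a
#'   [ThicknessField-class] or its volumetric extension array).
#' @param Tneighbors list of neighbor thickness fields.
#' @param displacements list parallel to \code{Tneighbors}; each entry a
#'   displacement array of dimensions \code{c(grid, ndim)} in mm mapping
#'   current-grid coordinates into the neighbor's grid, or \code{NULL} for
#'   identity. Points mapped outside the neighbor grid are clamped to its
#'   border.
#' @param spacing voxel spacing in mm.
#' @return the \eqn{D_t} field.
#' @export
thicknessDifference <- function(Tt, Tneighbors, displacements = NULL,
                                spacing = 1) {
  asField <- function(x) if (is(x, "ThicknessField")) x@field else x
  Tt <- asField(Tt)
  h <- .spacingFor(Tt, spacing)
  D <- array(0, dim(Tt))
  for (k in seq_along(Tneighbors)) {
    Ts <- asField(Tneighbors[[k]])
    disp <- if (is.null(displacements)) NULL else displacements[[k]]
    if (is.null(disp)) {
      D <- D + (Tt - Ts)
    } else {
      d <- dim(Tt); nd <- length(d)
      ctr <- arrayInd(seq_along(Tt), d)
      pts <- sweep(ctr - 0.5, 2, h, "*")
      dispMat <- matrix(disp, ncol = nd)
      pts <- pts + dispMat
      ext <- d * h
      if (any(pts < 0) || any(sweep(pts, 2, ext, ">") ))
        message("correspondence maps points outside the neighbor grid; clamping to the border")
      D <- D + (Tt - array(sampleField(Ts, pts, h), d))
    }
  }
  D
}

#' Temporal thickness-variation force
#'
#' Where \eqn{D_t > 0} (current cortex thicker than its temporal neighbors)
#' the force deflates the outer surface and inflates the inner one,
#' decreasing the thickness toward the neighbors' level; where
#' \eqn{D_t < 0} it acts oppositely. Magnitude is \code{mu * |D_t|} times
#' the Dirac band weight around each zero level; \eqn{D_t} itself is held
#' frozen (computed from the initialization of the current outer
#' iteration), which keeps it a fixed target during the inner evolution.
#'
#' @param D the difference field from [thicknessDifference()].
#' @param triple the [LevelSetTriple-class] whose zero levels receive the
#'   force.
#' @param mu weight, >= 0.
#' @param eps Heaviside regularization scale in mm.
#' @param exclusionMask optional logical volume where the constraint is not
#'   imposed.
#' @return list of force fields \code{f1}, \code{f2} (descent directions).
#' @export
temporalThicknessForce <- function(D, triple, mu, eps = 1.5,
                                   exclusionMask = NULL) {
  stopifnot(mu >= 0, is(triple, "LevelSetTriple"))
  W <- if (is.null(exclusionMask)) 1 else as.double(!exclusionMask)
  list(f1 = mu * W * D * diracEps(triple@phi1, eps),
       f2 = -mu * W * D * diracEps(triple@phi2, eps))
}

#' Temporal neighborhood constructors
#'
#' \code{identityCorrespondence} builds the default neighborhood for a
#' pre-aligned series: immediate temporal neighbors \{t-1, t+1\} (truncated
#' at the ends) with identity displacement fields. Externally computed
#' displacement fields (e.g. from a deformable registration) can be plugged
#' in through \code{temporalNeighborhood}.
#'
#' @param series a [LongitudinalSeries-class] on a common grid.
#' @return a [TemporalNeighborhood-class].
#' @export
identityCorrespondence <- function(series) {
  stopifnot(is(series, "LongitudinalSeries"))
  nT <- length(series@images)
  nb <- lapply(seq_len(nT), function(t)
    Filter(function(s) s >= 1 && s <= nT, c(t - 1L, t + 1L)))
  disp <- lapply(nb, function(v) vector("list", length(v)))
  new("TemporalNeighborhood", neighbors = nb, displacements = disp)
}

#' @rdname identityCorrespondence
#' @param neighbors list (per time point) of neighbor indices.
#' @param displacements list (per time point) of per-neighbor displacement
#'   arrays or \code{NULL}s.
#' @export
temporalNeighborhood <- function(neighbors, displacements) {
  new("TemporalNeighborhood",
      neighbors = lapply(neighbors, as.integer),
      displacements = displacements)
}
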