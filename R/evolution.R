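# Assembly of the 4D energy, the gradient-descent flows, and the alternating
# correspondence/segmentation outer loop.
#
# Per time point the energy is
#   E_t = sum_x [ sum_i d_i M_i ]                     (data competition)
#       + nu * sum_k delta_eps(phi_k) |grad phi_k|    (length terms)
#       + lambdaS * spatial thickness penalty
#       + mu * D2 * H(phi2)                           (temporal, D2 frozen)
# The temporal constraint acts on the outer cortical surface (phi2), whose
# deflation/inflation is what changes the measured thickness; D2 is the
# frozen outer-surface thickness-difference field of the outer iteration.
# all times the voxel volume. The flows below are the exact gradients of
# this discrete sum with the local Gaussian parameters, the D fields and the
# band mask held frozen, which is what makes the numerical gradient check
# meaningful.

#' Create evolution parameters
#'
#' @param nu length-term weight (default 0.5).
#' @param lambdaS spatial thickness-constraint weight (default 1).
#' @param mu temporal thickness-variation weight (default 0.5); 0 reduces
#'   the 4D method to independent per-time-point segmentation.
#' @param omega atlas-prior weight (default 0.5).
#' @param range admissible cortical thickness range in mm (default
#'   \code{c(1, 6.5)}).
#' @param dt artificial time step; \code{NA} resolves to
#'   \code{0.1 * min(spacing)^2}.
#' @param nInner inner iterations per outer loop (default 50).
#' @param nOuter outer correspondence/segmentation alternations (default 3).
#' @param eps Heaviside scale in mm; \code{NA} resolves to
#'   \code{1.5 * min(spacing)}.
#' @param kernelSigma local Gaussian kernel scale in mm; \code{NA} resolves
#'   to \code{3 * min(spacing)}.
#' @param varFloor variance floor (default 1 intensity^2).
#' @param priorFloor probability floor inside log(prior) (default 1e-4).
#' @param reinitEvery reinitialization period in inner iterations
#'   (default 1, i.e. every iteration).
#' @param refitEvery local-Gaussian refit period in inner iterations
#'   (default 1).
#' @param seed integer seed echoed into reports.
#' @return an [EvolutionParams-class].
#' @export
evolutionParams <- function(nu = 0.5, lambdaS = 1, mu = 0.5, omega = 0.5,
                            range = c(1, 6.5), dt = NA_real_, nInner = 50L,
                            nOuter = 3L, eps = NA_real_,
                            kernelSigma = NA_real_, varFloor = 1,
                            priorFloor = 1e-4, reinitEvery = 1L,
                            refitEvery = 1L, seed = 1L) {
  new("EvolutionParams",
    nu = as.double(nu), lambdaS = as.double(lambdaS), mu = as.double(mu),
    omega = as.double(omega), dmin = as.double(range[1]),
    dmax = as.double(range[2]), dt = as.double(dt),
    nInner = as.integer(nInner), nOuter = as.integer(nOuter),
    eps = as.double(eps), kernelSigma = as.double(kernelSigma),
    varFloor = as.double(varFloor), priorFloor = as.double(priorFloor),
    reinitEvery = as.integer(reinitEvery),
    refitEvery = as.integer(refitEvery), seed = as.integer(seed))
}

# fill spacing-dependent defaults and enforce the curvature stability bound
.resolveParams <- function(params, spacing) {
  stopifnot(is(params, "EvolutionParams"))
  hmin <- min(spacing)
  if (is.na(params@dt)) params@dt <- 0.1 * hmin^2
  if (is.na(params@eps)) params@eps <- 1.5 * hmin
  if (is.na(params@kernelSigma)) params@kernelSigma <- 3 * hmin
  if (params@nu > 0 && params@dt > 0.25 * hmin^2 / params@nu)
    stop("dt violates the curvature stability bound 0.25 * min(spacing)^2 / nu")
  params
}

#' Hard labels from a level-set triple
#'
#' WM where \code{phi1 >= 0}; GM where \code{phi2 >= 0} and \code{phi1 < 0};
#' CSF where \code{phi3 >= 0} and \code{phi2 < 0}; background elsewhere.
#' Boundary ties (phi exactly 0) go to the inner class.
#'
#' @param triple a nested [LevelSetTriple-class].
#' @return a label volume with codes 0/1/2/3.
#' @export
labelsFromState <- function(triple) {
  stopifnot(is(triple, "LevelSetTriple"))
  lab <- array(0L, dim(triple@phi1))
  lab[triple@phi3 >= 0] <- 1L
  lab[triple@phi2 >= 0] <- 2L
  lab[triple@phi1 >= 0] <- 3L
  lab
}

# normalize the priors argument: either one shared set (named bg/csf/gm/wm)
# or a list of per-time-point sets
.priorsFor <- function(priors, t) {
  if (!is.null(names(priors)) && identical(names(priors), .CLASSES)) priors
  else priors[[t]]
}

#' Initial 3D segmentation of one time point
#'
#' Prior-only warm start (memberships taken from the atlas priors), one fit
#' of the local Gaussian model, then a hard per-voxel assignment by the
#' smallest prior-weighted local data field, converted to nested masks and
#' signed distances. Deterministic. If the assignment misses a class, the
#' prior-only assignment is used instead (with a warning).
#'
#' @param image intensity volume.
#' @param priors per-class prior list (bg, csf, gm, wm).
#' @param params an [EvolutionParams-class].
#' @param spacing voxel spacing in mm.
#' @param timeIndex time point index recorded in the triple.
#' @return a [LevelSetTriple-class].
#' @export
initialize3d <- function(image, priors, params, spacing = 1, timeIndex = 1L) {
  h <- .spacingFor(image, spacing)
  p <- .resolveParams(params, h)
  gauss <- fitLocalGaussians(image, priors, p, h)
  e <- localFitEnergy(image, gauss, p, h)
  d <- dataForce(e, priors, p)
  lab <- .argminLabels(d)
  masks <- list(wm = lab == 3L, wmgm = lab >= 2L, head = lab >= 1L)
  degenerate <- any(vapply(masks, function(m) !any(m) || all(m), logical(1)))
  if (degenerate) {
    warning("data-driven initialization missed a class; falling back to the prior-only assignment")
    lab <- .argminLabels(lapply(priors, function(pr) -pr))
    masks <- list(wm = lab == 3L, wmgm = lab >= 2L, head = lab >= 1L)
    if (any(vapply(masks, function(m) !any(m) || all(m), logical(1))))
      stop("priors do not support all tissue classes; cannot initialize")
  }
  tripleFromMasks(masks$wm, masks$wmgm, masks$head, h, timeIndex)
}

# frozen per-outer-iteration context: temporal difference fields (anchored
# to the initialization of the outer iteration) and the penalty band mask
.makeFrozen <- function(triples, neighborhood, exclusionMask, p) {
  nT <- length(triples)
  h <- triples[[1]]@spacing
  bandWidth <- 3 * min(h)
  Touter <- lapply(triples, function(tr) pmax(-tr@phi1, 0))
  penBand <- 2 * min(h)
  lapply(seq_len(nT), function(t) {
    nb <- neighborhood@neighbors[[t]]
    disp <- neighborhood@displacements[[t]]
    D2 <- thicknessDifference(Touter[[t]], Touter[nb], disp, h)
    W <- (abs(triples[[t]]@phi1) <= bandWidth) |
         (abs(triples[[t]]@phi2) <= bandWidth)
    W1 <- abs(triples[[t]]@phi1) <= penBand
    W2 <- abs(triples[[t]]@phi2) <= penBand
    if (!is.null(exclusionMask)) {
      W <- W & !exclusionMask
      W1 <- W1 & !exclusionMask
      W2 <- W2 & !exclusionMask
    }
    list(D2 = D2, W = array(as.double(W), dim(D2)),
         W1 = array(as.double(W1), dim(D2)),
         W2 = array(as.double(W2), dim(D2)))
  })
}

.zeroFrozen <- function(triple) {
  z <- array(0, dim(triple@phi1))
  one <- array(1, dim(triple@phi1))
  list(D2 = z, W = one, W1 = one, W2 = one)
}

# effective data fields from a fitted local Gaussian model and the priors.
# The pointwise minimum across classes is subtracted: because the
# memberships sum to one identically, this shifts the data energy by a
# phi-independent constant and leaves every gradient bit-identical, while
# keeping the reported energy well conditioned (no huge cross-class
# mismatch terms from the slow Heaviside tails).
.dataFields <- function(image, gauss, priors, p, h) {
  d <- dataForce(localFitEnergy(image, gauss, p, h), priors, p)
  m <- pmin(d[[1]], d[[2]], d[[3]], d[[4]])
  # robust truncation: competition is decided by differences of order the
  # squared class contrast over the variance (O(1-20) at real boundaries);
  # capping removes the enormous cross-class mismatches that the slow
  # Heaviside tails would otherwise accumulate far from any interface
  dcap <- 50
  lapply(d, function(x) pmin(x - m, dcap))
}

# energy and (density-scale) gradients for one time point, everything except
# phi held frozen. Returns energy (including the voxel volume factor) and
# per-voxel gradient densities g1, g2, g3.
.tpEnergyGrad <- function(triple, dfield, frozen, p, wantGrad = TRUE) {
  h <- triple@spacing
  vol <- prod(h)
  eps <- p@eps
  h1 <- heavisideEps(triple@phi1, eps)
  h2 <- heavisideEps(triple@phi2, eps)
  h3 <- heavisideEps(triple@phi3, eps)
  del1 <- diracEps(triple@phi1, eps)
  del2 <- diracEps(triple@phi2, eps)
  del3 <- diracEps(triple@phi3, eps)

  Edata <- sum(dfield$bg * (1 - h3) + dfield$csf * (h3 - h2) +
               dfield$gm * (h2 - h1) + dfield$wm * h1)
  Elen <- 0
  if (p@nu > 0) {
    Elen <- sum(.lengthEnergyDensity(triple@phi1, h, eps)) +
            sum(.lengthEnergyDensity(triple@phi2, h, eps)) +
            sum(.lengthEnergyDensity(triple@phi3, h, eps))
  }
  pen <- .thicknessPenalty(triple@phi1, triple@phi2, p@dmin, p@dmax, eps,
                           frozen$W1, frozen$W2)
  Esp <- sum(pen$density)
  Etmp <- sum(frozen$W * frozen$D2 * h2)
  energy <- (Edata + p@nu * Elen + p@lambdaS * Esp + p@mu * Etmp) * vol
  if (!wantGrad)
    return(list(energy = energy))

  g1 <- del1 * (dfield$wm - dfield$gm) + p@lambdaS * pen$g1
  g2 <- del2 * (dfield$gm - dfield$csf) +
        p@lambdaS * pen$g2 + p@mu * frozen$W * frozen$D2 * del2
  g3 <- del3 * (dfield$csf - dfield$bg)
  if (p@nu > 0) {
    g1 <- g1 + p@nu * .lengthGrad(triple@phi1, h, eps)
    g2 <- g2 + p@nu * .lengthGrad(triple@phi2, h, eps)
    g3 <- g3 + p@nu * .lengthGrad(triple@phi3, h, eps)
  }
  list(energy = energy, g1 = g1, g2 = g2, g3 = g3)
}

#' Total 4D energy of a segmentation state
#'
#' Sum over time points of the local fitting energy, the weighted length
#' terms, the spatial thickness penalty, and the temporal thickness
#' variation penalty (with the frozen difference fields of the current
#' outer iteration). With \code{mu = 0} the energy decomposes into
#' independent per-time-point 3D energies.
#'
#' @param state a [SegmentationState-class].
#' @param series a [LongitudinalSeries-class].
#' @param priors shared prior list or per-time-point list of prior lists.
#' @param params an [EvolutionParams-class].
#' @param frozen optional frozen context from the current outer iteration
#'   (internal); when missing it is rebuilt from the state with identity
#'   correspondence.
#' @return a scalar energy value.
#' @export
totalEnergy <- function(state, series, priors, params, frozen = NULL) {
  p <- .resolveParams(params, series@spacing)
  if (is.null(frozen))
    frozen <- .makeFrozen(state@triples, identityCorrespondence(series),
                          NULL, p)
  tot <- 0
  for (t in seq_along(state@triples)) {
    dfield <- .dataFields(series@images[[t]], state@gaussians[[t]],
                          .priorsFor(priors, t), p, series@spacing)
    tot <- tot + .tpEnergyGrad(state@triples[[t]], dfield,
                               frozen[[t]], p, wantGrad = FALSE)$energy
  }
  tot
}

#' Exact gradient of the total energy for one time point
#'
#' The per-voxel derivative of [totalEnergy()] with respect to the three
#' level-set fields of time point \code{t}, holding the local Gaussian
#' parameters, the temporal difference fields and the band mask frozen.
#' Used by the evolution and by the numerical gradient check.
#'
#' @inheritParams totalEnergy
#' @param t time point index.
#' @return list of gradient fields \code{g1}, \code{g2}, \code{g3}
#'   (same discretization as the energy, including the voxel volume
#'   factor).
#' @export
energyGradient <- function(state, series, priors, params, t, frozen = NULL) {
  p <- .resolveParams(params, series@spacing)
  if (is.null(frozen))
    frozen <- .makeFrozen(state@triples, identityCorrespondence(series),
                          NULL, p)
  dfield <- .dataFields(series@images[[t]], state@gaussians[[t]],
                        .priorsFor(priors, t), p, series@spacing)
  eg <- .tpEnergyGrad(state@triples[[t]], dfield, frozen[[t]], p,
                      wantGrad = TRUE)
  vol <- prod(series@spacing)
  list(g1 = eg$g1 * vol, g2 = eg$g2 * vol, g3 = eg$g3 * vol)
}

# one inner evolution pass for one time point; returns the updated triple,
# gaussians, the energy trace and the (possibly reduced) time step
.evolveTimepoint <- function(triple, image, priors, frozen, p, dt0,
                             verbose = FALSE) {
  h <- triple@spacing
  hmin <- min(h)
  dt <- dt0
  dtFloor <- dt0 / 64
  energies <- numeric(p@nInner)
  incRun <- 0L
  lastE <- Inf
  gauss <- NULL
  dfield <- NULL
  for (it in seq_len(p@nInner)) {
    if ((it - 1L) %% p@refitEvery == 0L) {
      gauss <- fitLocalGaussians(image, memberships(triple, p@eps), p, h)
      dfield <- .dataFields(image, gauss, priors, p, h)
    }
    eg <- .tpEnergyGrad(triple, dfield, frozen, p)
    energies[it] <- eg$energy
    if (eg$energy > lastE * (1 + 1e-12)) {
      incRun <- incRun + 1L
      if (incRun >= 10L) {
        dt <- dt / 2
        incRun <- 0L
        if (verbose) message("energy increasing; halving dt to ", dt)
        if (dt < dtFloor)
          stop("evolution diverged: dt fell below ", signif(dtFloor, 3),
               " after repeated energy increases")
      }
    } else incRun <- 0L
    lastE <- eg$energy
    # CFL-style cap from the interface band (the far field is rebuilt by
    # reinitialization anyway)
    band <- abs(triple@phi1) <= 3 * hmin | abs(triple@phi2) <= 3 * hmin |
            abs(triple@phi3) <= 3 * hmin
    gmax <- max(abs(eg$g1[band]), abs(eg$g2[band]), abs(eg$g3[band]))
    dtEff <- min(dt, 0.45 * hmin / max(gmax, 1e-12))
    phi1 <- triple@phi1 - dtEff * eg$g1
    phi2 <- triple@phi2 - dtEff * eg$g2
    phi3 <- triple@phi3 - dtEff * eg$g3
    # nesting projection keeps the region algebra valid
    phi2 <- pmax(phi2, phi1)
    phi3 <- pmax(phi3, phi2)
    if (it %% p@reinitEvery == 0L) {
      phi1 <- reinitialize(phi1, h)
      phi2 <- reinitialize(phi2, h)
      phi3 <- reinitialize(phi3, h)
      phi2 <- pmax(phi2, phi1)
      phi3 <- pmax(phi3, phi2)
    }
    triple <- new("LevelSetTriple", phi1 = phi1, phi2 = phi2, phi3 = phi3,
                  spacing = h, timeIndex = triple@timeIndex)
  }
  list(triple = triple, gauss = gauss, energies = energies, dt = dt)
}

#' Run the 4D segmentation
#'
#' Initializes every time point separately (3D coupled level sets with the
#' atlas prior), then alternates: refresh the anatomical correspondence and
#' the frozen temporal thickness-difference fields, evolve every time point
#' for \code{nInner} gradient-descent steps with reinitialization, repeat
#' \code{nOuter} times. Returns hard labels, per-time-point outer-surface
#' thickness, and a report with the energy trace (plus Dice ratios when
#' ground-truth labels are supplied).
#'
#' @param series a [LongitudinalSeries-class] (pre-aligned), or a
#'   [Phantom-class] (its images, priors and ground truth are used).
#' @param priors shared prior list (bg, csf, gm, wm) or per-time-point list;
#'   taken from the phantom when \code{series} is a [Phantom-class].
#' @param params an [EvolutionParams-class].
#' @param correspondenceProvider function mapping the series to a
#'   [TemporalNeighborhood-class]; default [identityCorrespondence()].
#' @param exclusionMask optional logical volume inside which the thickness
#'   constraints are not imposed (the data term still acts).
#' @param gtLabels optional list of ground-truth label volumes for Dice
#'   reporting.
#' @param verbose print progress.
#' @return a [SegmentationResult-class].
#' @export
run4d <- function(series, priors = NULL, params = evolutionParams(),
                  correspondenceProvider = identityCorrespondence,
                  exclusionMask = NULL, gtLabels = NULL, verbose = FALSE) {
  if (is(series, "Phantom")) {
    if (is.null(priors)) priors <- series@priors
    if (is.null(gtLabels)) gtLabels <- series@labels
    series <- asSeries(series)
  }
  stopifnot(is(series, "LongitudinalSeries"))
  h <- series@spacing
  p <- .resolveParams(params, h)
  nT <- length(series@images)

  triples <- lapply(seq_len(nT), function(t)
    initialize3d(series@images[[t]], .priorsFor(priors, t), p, h, t))
  gaussians <- lapply(seq_len(nT), function(t)
    fitLocalGaussians(series@images[[t]],
                      memberships(triples[[t]], p@eps), p, h))
  state <- new("SegmentationState", triples = triples,
               gaussians = gaussians, energyHistory = numeric())

  dts <- rep(p@dt, nT)
  outerEnergy <- numeric(p@nOuter)
  allEnergies <- list()
  warnings <- character()
  for (outer in seq_len(p@nOuter)) {
    neighborhood <- correspondenceProvider(series)
    frozen <- .makeFrozen(state@triples, neighborhood, exclusionMask, p)
    pOut <- p
    stepEnergies <- matrix(NA_real_, p@nInner, nT)
    for (t in seq_len(nT)) {
      if (verbose) message("outer ", outer, ", time point ", t)
      ev <- .evolveTimepoint(state@triples[[t]], series@images[[t]],
                             .priorsFor(priors, t), frozen[[t]], pOut, dts[t],
                             verbose)
      state@triples[[t]] <- ev$triple
      state@gaussians[[t]] <- ev$gauss
      dts[t] <- ev$dt
      stepEnergies[, t] <- ev$energies
    }
    outerEnergy[outer] <- sum(stepEnergies[p@nInner, ])
    allEnergies[[outer]] <- stepEnergies
    state@energyHistory <- c(state@energyHistory, rowSums(stepEnergies))
  }
  if (p@nOuter > 1) {
    rel <- diff(outerEnergy) / abs(outerEnergy[-p@nOuter])
    if (any(rel > 0.05)) {
      warnings <- c(warnings, "outer-loop energy increased by more than 5%")
      warning(warnings[length(warnings)])
    }
  }

  labels <- lapply(state@triples, labelsFromState)
  thickness <- lapply(state@triples, function(tr)
    measureThickness(tr@phi1, tr@phi2, h))
  report <- list(
    params = .paramsEcho(p),
    energyTrace = state@energyHistory,
    outerEnergy = outerEnergy,
    finalEnergy = outerEnergy[p@nOuter],
    initialEnergy = state@energyHistory[1],
    warnings = warnings)
  if (!is.null(gtLabels)) {
    report$dice <- .diceTable(labels, gtLabels)
  }
  new("SegmentationResult", labels = labels, thickness = thickness,
      report = report)
}

#' Independent per-time-point 3D segmentation
#'
#' Segments every time point of the series separately with the same coupled
#' level-set machinery and no temporal coupling; the reference the 4D run
#' with \code{mu = 0} must reproduce voxel-exactly.
#'
#' @inheritParams run4d
#' @return a [SegmentationResult-class].
#' @export
run3d <- function(series, priors = NULL, params = evolutionParams(),
                  exclusionMask = NULL, gtLabels = NULL, verbose = FALSE) {
  if (is(series, "Phantom")) {
    if (is.null(priors)) priors <- series@priors
    if (is.null(gtLabels)) gtLabels <- series@labels
    series <- asSeries(series)
  }
  nT <- length(series@images)
  parts <- lapply(seq_len(nT), function(t) {
    sub <- longitudinalSeries(series@images[t], series@spacing)
    run4d(sub, priors = .priorsFor(priors, t), params = params,
          exclusionMask = exclusionMask,
          gtLabels = if (is.null(gtLabels)) NULL else gtLabels[t],
          verbose = verbose)
  })
  labels <- lapply(parts, function(x) x@labels[[1]])
  thickness <- lapply(parts, function(x) x@thickness[[1]])
  report <- list(
    params = parts[[1]]@report$params,
    energyTrace = unlist(lapply(parts, function(x) x@report$energyTrace)),
    finalEnergy = sum(vapply(parts, function(x) x@report$finalEnergy, 0)),
    initialEnergy = sum(vapply(parts, function(x) x@report$initialEnergy, 0)),
    warnings = unlist(lapply(parts, function(x) x@report$warnings)))
  if (!is.null(gtLabels)) report$dice <- .diceTable(labels, gtLabels)
  new("SegmentationResult", labels = labels, thickness = thickness,
      report = report)
}

.paramsEcho <- function(p) {
  list(nu = p@nu, lambdaS = p@lambdaS, mu = p@mu, omega = p@omega,
       range = c(p@dmin, p@dmax), dt = p@dt, nInner = p@nInner,
       nOuter = p@nOuter, eps = p@eps, kernelSigma = p@kernelSigma,
       varFloor = p@varFloor, priorFloor = p@priorFloor,
       reinitEvery = p@reinitEvery, refitEvery = p@refitEvery,
       seed = p@seed)
}

.diceTable <- function(labels, gtLabels) {
  rows <- list()
  for (t in seq_along(labels)) {
    for (cls in c("csf", "gm", "wm")) {
      code <- match(cls, .CLASSES) - 1L
      rows[[length(rows) + 1L]] <- data.frame(
        timepoint = t, class = cls,
        dice = dice(labels[[t]] == code, gtLabels[[t]] == code))
    }
  }
  do.call(rbind, rows)
}
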