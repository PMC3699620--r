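# Local Gaussian intensity model: per-location class means/variances fitted
# through a Gaussian kernel, the local intensity fitting energy, and its
# MAP combination with the spatial atlas prior.

#' Fit per-location Gaussian intensity models
#'
#' For each tissue class i, kernel-weighted local statistics
#' \eqn{u_i = K_\sigma * (M_i I) / (K_\sigma * M_i)} and
#' \eqn{\sigma_i^2 = K_\sigma * (M_i I^2) / (K_\sigma * M_i) - u_i^2},
#' floored at \code{varFloor}. Where the local class mass is negligible the
#' class's global weighted statistics are substituted; a class absent
#' everywhere falls back to global image statistics with a warning.
#'
#' @param image intensity volume.
#' @param memb a [MembershipFields-class] (or list of four fields named
#'   bg, csf, gm, wm).
#' @param params an [EvolutionParams-class] (uses kernelSigma, varFloor).
#' @param spacing voxel spacing in mm.
#' @return a [LocalGaussianField-class].
#' @export
fitLocalGaussians <- function(image, memb, params, spacing = 1) {
  h <- .spacingFor(image, spacing)
  p <- .resolveParams(params, h)
  m <- if (is(memb, "MembershipFields")) .membList(memb) else memb
  massThresh <- 1e-4
  means <- vars <- vector("list", 4L)
  for (i in seq_len(4L)) {
    mi <- m[[i]]
    tot <- sum(mi)
    if (tot < 1e-8) {
      warning("class '", .CLASSES[i],
              "' has no support anywhere; using global image statistics")
      gMean <- mean(image)
      gVar <- max(stats::var(as.vector(image)), p@varFloor)
    } else {
      gMean <- sum(mi * image) / tot
      gVar <- max(sum(mi * image^2) / tot - gMean^2, p@varFloor)
    }
    sm <- smoothField(mi, p@kernelSigma, h)
    su <- smoothField(mi * image, p@kernelSigma, h)
    sv <- smoothField(mi * image^2, p@kernelSigma, h)
    ok <- sm > massThresh
    u <- array(gMean, dim(image))
    v <- array(gVar, dim(image))
    u[ok] <- su[ok] / sm[ok]
    v[ok] <- pmax(sv[ok] / sm[ok] - u[ok]^2, p@varFloor)
    means[[i]] <- u
    vars[[i]] <- v
  }
  names(means) <- names(vars) <- .CLASSES
  new("LocalGaussianField", mean = means, var = vars,
      kernelSigma = p@kernelSigma)
}

#' Local intensity fitting energy
#'
#' Per-class energy fields
#' \deqn{e_i(x) = \int K_\sigma(y - x)\left[\log\sigma_i(y) +
#'   \frac{(I(x) - u_i(y))^2}{2\sigma_i^2(y)}\right] dy,}
#' evaluated by expanding the square into kernel convolutions. The variance
#' floor keeps every field finite.
#'
#' @param image intensity volume.
#' @param gaussians a [LocalGaussianField-class].
#' @param params an [EvolutionParams-class].
#' @param spacing voxel spacing in mm.
#' @return list of four energy fields named bg, csf, gm, wm.
#' @export
localFitEnergy <- function(image, gaussians, params, spacing = 1) {
  h <- .spacingFor(image, spacing)
  p <- .resolveParams(params, h)
  sig <- gaussians@kernelSigma
  e <- vector("list", 4L)
  for (i in seq_len(4L)) {
    u <- gaussians@mean[[i]]
    v <- gaussians@var[[i]]
    A <- smoothField(0.5 / v, sig, h)
    B <- smoothField(u / v, sig, h)
    C <- smoothField(0.5 * u^2 / v, sig, h)
    L <- smoothField(0.5 * log(v), sig, h)
    e[[i]] <- L + image^2 * A - image * B + C
  }
  names(e) <- .CLASSES
  e
}

#' Combine local fitting energies with the atlas prior
#'
#' MAP composition \eqn{d_i(x) = e_i(x) - \omega \log(p_i(x) + floor)}:
#' with \code{omega = 0} the pure local model is recovered; uniform priors
#' shift all classes equally and leave the competition unchanged.
#'
#' @param e list of per-class energy fields from [localFitEnergy()].
#' @param priors list of per-class prior probability fields (bg, csf, gm,
#'   wm), normalized per voxel.
#' @param params an [EvolutionParams-class] (uses omega, priorFloor).
#' @return list of four effective data fields.
#' @export
dataForce <- function(e, priors, params) {
  d <- lapply(seq_len(4L), function(i)
    e[[i]] - params@omega * log(priors[[i]] + params@priorFloor))
  names(d) <- .CLASSES
  d
}

# hard per-voxel assignment by the smallest effective data field,
# returning label codes 0..3
.argminLabels <- function(d) {
  lab <- array(0L, dim(d[[1]]))
  best <- d[[1]]
  for (i in 2:4) {
    sel <- d[[i]] < best
    best[sel] <- d[[i]][sel]
    lab[sel] <- i - 1L
  }
  lab
}
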