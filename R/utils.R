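# Internal array helpers shared by all modules. Volumes are plain R arrays
# (2D matrices or 3D arrays) in column-major order; voxel i (1-based) has its
# centre at (i - 0.5) * spacing along each axis, all distances in mm.

.spacingFor <- function(x, spacing) {
  d <- dim(x)
  if (is.null(d)) stop("volume must be a matrix or array")
  rep_len(as.double(spacing), length(d))
}

.gaussKernel1d <- function(sigma_vox) {
  if (!is.finite(sigma_vox) || sigma_vox <= 0) return(1)
  r <- max(1L, as.integer(ceiling(3 * sigma_vox)))
  k <- exp(-0.5 * ((-r:r) / sigma_vox)^2)
  k / sum(k)
}

# Separable Gaussian smoothing with mass-preserving (renormalized) boundary
# handling: constants are reproduced exactly.
smoothField <- function(x, sigma_mm, spacing = 1) {
  d <- dim(x)
  h <- .spacingFor(x, spacing)
  sig <- rep_len(as.double(sigma_mm), length(d))
  if (all(sig <= 0)) return(x)
  kernels <- lapply(seq_along(d), function(a) .gaussKernel1d(sig[a] / h[a]))
  out <- .cpp_sepconv(as.double(x), as.integer(d), kernels)
  dim(out) <- d
  out
}

# shift with zero (or constant) fill: result[p] = x[p + by] along `axis`
.shift <- function(x, axis, by, fill = 0) {
  d <- dim(x)
  n <- d[axis]
  if (abs(by) >= n) return(array(fill, d))
  out <- array(fill, d)
  src <- lapply(d, seq_len)
  dst <- src
  if (by > 0) {
    src[[axis]] <- (1L + by):n
    dst[[axis]] <- 1L:(n - by)
  } else {
    src[[axis]] <- 1L:(n + by)
    dst[[axis]] <- (1L - by):n
  }
  do.call(`[<-`, c(list(out), dst, list(value = do.call(`[`, c(list(x), src)))))
}

# shift with edge replication: result[p] = x[clamp(p + by)]
.shiftc <- function(x, axis, by) {
  d <- dim(x)
  idx <- lapply(d, seq_len)
  idx[[axis]] <- pmin(pmax(idx[[axis]] + by, 1L), d[axis])
  do.call(`[`, c(list(x), idx))
}

# forward differences with a zero-gradient last sample (the discretization
# whose exact adjoint is the backward divergence used in the length flow)
.fwdGrad <- function(x, spacing) {
  d <- dim(x)
  h <- .spacingFor(x, spacing)
  lapply(seq_along(d), function(a) (.shiftc(x, a, 1L) - x) / h[a])
}

.centralGrad <- function(x, spacing) {
  d <- dim(x)
  h <- .spacingFor(x, spacing)
  lapply(seq_along(d), function(a) (.shiftc(x, a, 1L) - .shiftc(x, a, -1L)) / (2 * h[a]))
}

# physical coordinates of voxel centres along each axis
.axisCoords <- function(dimlen, h) (seq_len(dimlen) - 0.5) * h

# multilinear interpolation of `field` at points (N x d matrix, mm);
# coordinates are clamped to the grid
sampleField <- function(field, pts, spacing = 1) {
  d <- dim(field)
  h <- .spacingFor(field, spacing)
  nd <- length(d)
  pts <- matrix(as.double(pts), ncol = nd)
  u <- sweep(pts, 2, h, "/") + 0.5 # continuous 1-based index
  for (a in seq_len(nd)) u[, a] <- pmin(pmax(u[, a], 1), d[a])
  i0 <- pmin(floor(u), matrix(rep(d - 1L, each = nrow(u)), ncol = nd))
  i0 <- pmax(i0, 1)
  fr <- u - i0
  out <- numeric(nrow(pts))
  for (corner in seq_len(2^nd) - 1L) {
    off <- as.integer(intToBits(corner))[seq_len(nd)]
    w <- rep(1, nrow(pts))
    idx <- i0
    for (a in seq_len(nd)) {
      if (off[a] == 1L) {
        idx[, a] <- pmin(i0[, a] + 1L, d[a])
        w <- w * fr[, a]
      } else {
        w <- w * (1 - fr[, a])
      }
    }
    lin <- idx[, 1]
    mult <- 1
    for (a in seq_len(nd)[-1]) {
      mult <- mult * d[a - 1]
      lin <- lin + (idx[, a] - 1L) * mult
    }
    out <- out + w * field[lin]
  }
  out
}

.voxelVolume <- function(x, spacing) prod(.spacingFor(x, spacing))

# deterministic sub-stream seed (kept well below 2^31)
.streamSeed <- function(seed, k) (as.integer(seed) %% 1000003L) * 1009L + 7919L * as.integer(k)
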