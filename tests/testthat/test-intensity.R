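params2 <- function(...) evolutionParams(...)

test_that("constant image gives constant local means and floored variance", {
  img <- array(42, c(32, 32))
  memb <- list(bg = array(0.25, c(32, 32)), csf = array(0.25, c(32, 32)),
               gm = array(0.25, c(32, 32)), wm = array(0.25, c(32, 32)))
  g <- fitLocalGaussians(img, memb, params2(), 1)
  for (i in 1:4) {
    expect_lt(max(abs(g@mean[[i]] - 42)), 1e-9)
    expect_equal(unique(as.vector(g@var[[i]])), 1) # varFloor
  }
})

test_that("large kernel recovers global class statistics", {
  set.seed(11)
  img <- array(rnorm(64 * 64, 80, 5), c(64, 64))
  memb <- list(bg = array(1, c(64, 64)), csf = array(0, c(64, 64)),
               gm = array(0, c(64, 64)), wm = array(0, c(64, 64)))
  g <- suppressWarnings(
    fitLocalGaussians(img, memb, params2(kernelSigma = 500), 1))
  gmean <- mean(img)
  expect_lt(max(abs(g@mean$bg - gmean)) / gmean, 0.01)
})

test_that("piecewise-constant image is fitted exactly away from the interface", {
  img <- array(85, c(64, 64))
  img[, 33:64] <- 105
  memb <- list(bg = array(0, c(64, 64)), csf = array(0, c(64, 64)),
               gm = array(as.double(col(img) <= 32), c(64, 64)),
               wm = array(as.double(col(img) > 32), c(64, 64)))
  p <- params2()
  g <- suppressWarnings(fitLocalGaussians(img, memb, p, 1)) # bg/csf empty
  far <- abs(col(img) - 32.5) > 9 # beyond 3 sigma of the kernel
  expect_lt(max(abs((g@mean$gm - 85))[far & col(img) <= 32]), 1e-6)
  expect_lt(max(abs((g@mean$wm - 105))[far & col(img) > 32]), 1e-6)

  # direct kernel-weighted oracle at sampled voxels
  kern <- Cortex4D:::.gaussKernel1d(3)
  r <- (length(kern) - 1) / 2
  off <- -r:r
  K2 <- outer(kern, kern)
  for (k in 1:20) {
    set.seed(k)
    i <- sample(seq(r + 1, 64 - r), 1)
    j <- sample(seq(r + 1, 64 - r), 1)
    sub <- img[i + off, j + off]
    msub <- memb$wm[i + off, j + off]
    num <- sum(K2 * msub * sub)
    den <- sum(K2 * msub)
    expected <- if (den > 1e-4) num / den else NA
    if (!is.na(expected))
      expect_equal(g@mean$wm[i, j], expected, tolerance = 1e-8)
  }
})

test_that("local fit energy separates a two-class image", {
  img <- array(85, c(64, 64))
  img[, 33:64] <- 105
  memb <- list(bg = array(0, c(64, 64)), csf = array(0, c(64, 64)),
               gm = array(as.double(col(img) <= 32), c(64, 64)),
               wm = array(as.double(col(img) > 32), c(64, 64)))
  p <- params2()
  g <- suppressWarnings(fitLocalGaussians(img, memb, p, 1)) # bg/csf empty
  e <- localFitEnergy(img, g, p, 1)
  away <- abs(col(img) - 32.5) > 9
  amin <- ifelse(e$gm < e$wm, "gm", "wm")
  truth <- ifelse(col(img) <= 32, "gm", "wm")
  expect_true(all(amin[away] == truth[away]))
  # all fields finite
  for (f in e) expect_true(all(is.finite(f)))

  # brute-force double-sum oracle at sampled voxels
  kern <- Cortex4D:::.gaussKernel1d(3)
  r <- (length(kern) - 1) / 2
  K2 <- outer(kern, kern)
  off <- -r:r
  set.seed(5)
  for (k in 1:25) {
    i <- sample(seq(r + 1, 64 - r), 1)
    j <- sample(seq(r + 1, 64 - r), 1)
    u <- g@mean$gm[i + off, j + off]
    v <- g@var$gm[i + off, j + off]
    expected <- sum(K2 * (0.5 * log(v) + (img[i, j] - u)^2 / (2 * v)))
    expect_equal(e$gm[i, j], expected, tolerance = 1e-8)
  }
})

test_that("energies are shift-equivariant when the model is refit", {
  ph <- cachedPhantom(2)
  spec <- phantomSpecOf(ph)
  img <- ph@images[[1]]
  memb <- makePriors(ph@labels[[1]], 0, spec@voxelSpacing)
  p <- params2()
  g0 <- fitLocalGaussians(img, memb, p, spec@voxelSpacing)
  e0 <- localFitEnergy(img, g0, p, spec@voxelSpacing)
  g1 <- fitLocalGaussians(img + 100, memb, p, spec@voxelSpacing)
  e1 <- localFitEnergy(img + 100, g1, p, spec@voxelSpacing)
  for (i in 1:4) expect_lt(max(abs(e0[[i]] - e1[[i]])), 1e-6)
})

test_that("prior composition behaves as a MAP weight", {
  e <- list(bg = array(5, c(8, 8)), csf = array(4, c(8, 8)),
            gm = array(3, c(8, 8)), wm = array(3.5, c(8, 8)))
  uni <- lapply(1:4, function(i) array(0.25, c(8, 8)))
  names(uni) <- c("bg", "csf", "gm", "wm")
  # omega = 0: data only
  d0 <- dataForce(e, uni, params2(omega = 0))
  for (i in 1:4) expect_equal(d0[[i]], e[[i]])
  # uniform priors shift all classes identically
  dU <- dataForce(e, uni, params2(omega = 0.5))
  shift <- dU$gm - e$gm
  for (i in 1:4) expect_equal(dU[[i]] - e[[i]], shift)
  # a one-hot prior dominates comparable energies
  hot <- list(bg = array(0, c(8, 8)), csf = array(0, c(8, 8)),
              gm = array(0, c(8, 8)), wm = array(1, c(8, 8)))
  dH <- dataForce(e, hot, params2(omega = 0.5))
  expect_true(all(dH$wm < dH$gm & dH$wm < dH$csf & dH$wm < dH$bg))
})

test_that("noise-free phantom is classified correctly away from interfaces", {
  spec <- phantomSpec(rngSeed = 9, noiseSigma = 0)
  ph <- buildPhantom(spec)
  p <- params2()
  img <- ph@images[[1]]
  memb <- makePriors(ph@labels[[1]], 0, spec@voxelSpacing)
  g <- fitLocalGaussians(img, memb, p, spec@voxelSpacing)
  e <- localFitEnergy(img, g, p, spec@voxelSpacing)
  d <- dataForce(e, ph@priors, p)
  lab <- Cortex4D:::.argminLabels(d)
  # voxels further than 2 voxels from any class interface
  gt <- ph@labels[[1]]
  interface <- array(FALSE, dim(gt))
  for (a in 1:2) for (s in c(-1, 1))
    interface <- interface | (Cortex4D:::.shiftc(gt, a, s) != gt)
  far <- !interface
  for (a in 1:2) for (s in c(-2L, -1L, 1L, 2L))
    far <- far & !Cortex4D:::.shiftc(interface, a, s)
  expect_gt(mean(lab[far] == gt[far]), 0.99)
})
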