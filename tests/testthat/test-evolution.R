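# small synthetic instance used by the null-dynamics and gradient tests:
# nested circles on a tiny grid with a matching intensity image
tinyInstance <- function(n = 16, shift = 0, seed = 1) {
  wm <- circleMask(n, n / 2, n / 2, 3 + shift)
  wmgm <- circleMask(n, n / 2, n / 2, 5 + shift)
  head <- circleMask(n, n / 2, n / 2, 7)
  lab <- array(0L, c(n, n))
  lab[head] <- 1L; lab[wmgm] <- 2L; lab[wm] <- 3L
  set.seed(seed)
  img <- array(c(0, 25, 85, 105)[lab + 1L] + rnorm(n * n, 0, 3), c(n, n))
  list(triple = tripleFromMasks(wm, wmgm, head, 1),
       image = img, labels = lab,
       priors = makePriors(lab, 1.5, 1))
}

test_that("3D initialization recovers the noise-free phantom and is deterministic", {
  spec <- phantomSpec(rngSeed = 11, noiseSigma = 0)
  ph <- buildPhantom(spec)
  p <- evolutionParams()
  tr <- initialize3d(ph@images[[1]], ph@priors, p, spec@voxelSpacing, 1L)
  lab <- labelsFromState(tr)
  expect_gt(dice(lab == 3L, ph@labels[[1]] == 3L), 0.95)
  expect_gt(dice(lab == 2L, ph@labels[[1]] == 2L), 0.95)
  tr2 <- initialize3d(ph@images[[1]], ph@priors, p, spec@voxelSpacing, 1L)
  expect_identical(tr@phi1, tr2@phi1)
  expect_identical(tr@phi2, tr2@phi2)
})

test_that("dominant one-hot priors reproduce the ground truth exactly", {
  inst <- tinyInstance()
  oneHot <- makePriors(inst$labels, 0, 1)
  p <- evolutionParams(omega = 1000)
  tr <- initialize3d(inst$image, oneHot, p, 1, 1L)
  expect_identical(labelsFromState(tr), inst$labels)
})

test_that("total energy decomposes over time points when mu = 0", {
  ph <- buildPhantom(smallSpec(seed = 12))
  series <- asSeries(ph)
  p <- evolutionParams(mu = 0)
  pR <- Cortex4D:::.resolveParams(p, series@spacing)
  triples <- lapply(1:3, function(t)
    initialize3d(series@images[[t]], ph@priors, p, series@spacing, t))
  gaussians <- lapply(1:3, function(t)
    fitLocalGaussians(series@images[[t]],
                      memberships(triples[[t]], pR@eps), pR, series@spacing))
  state <- new("SegmentationState", triples = triples, gaussians = gaussians,
               energyHistory = numeric())
  tot <- totalEnergy(state, series, ph@priors, p)
  parts <- vapply(1:3, function(t) {
    sub <- longitudinalSeries(series@images[t], series@spacing)
    st <- new("SegmentationState", triples = triples[t],
              gaussians = gaussians[t], energyHistory = numeric())
    totalEnergy(st, sub, ph@priors, p)
  }, 0)
  expect_equal(tot, sum(parts), tolerance = 1e-9)
})

test_that("energy ordering of two states is invariant to an intensity shift", {
  ph <- buildPhantom(smallSpec(seed = 13))
  series <- asSeries(ph)
  p <- evolutionParams(mu = 0)
  pR <- Cortex4D:::.resolveParams(p, series@spacing)
  mkState <- function(images, shift) {
    triples <- lapply(seq_along(images), function(t) {
      l <- ph@labels[[t]]
      if (shift == "worse") { # deliberately degraded masks
        tripleFromMasks(Cortex4D:::.shiftc(l == 3L, 1, 2L), l >= 2L, l >= 1L,
                        series@spacing, t)
      } else tripleFromMasks(l == 3L, l >= 2L, l >= 1L, series@spacing, t)
    })
    gaussians <- lapply(seq_along(images), function(t)
      fitLocalGaussians(images[[t]], memberships(triples[[t]], pR@eps), pR,
                        series@spacing))
    new("SegmentationState", triples = triples, gaussians = gaussians,
        energyHistory = numeric())
  }
  eGood <- totalEnergy(mkState(series@images, "good"), series, ph@priors, p)
  eBad <- totalEnergy(mkState(series@images, "worse"), series, ph@priors, p)
  shifted <- lapply(series@images, `+`, 100)
  sSeries <- longitudinalSeries(shifted, series@spacing)
  eGoodS <- totalEnergy(mkState(shifted, "good"), sSeries, ph@priors, p)
  eBadS <- totalEnergy(mkState(shifted, "worse"), sSeries, ph@priors, p)
  expect_lt(eGood, eBad)
  expect_lt(eGoodS, eBadS)
})

test_that("zero forces leave the level sets unchanged", {
  n <- 24
  inst <- tinyInstance(n = 24)
  img <- array(50, c(n, n)) # constant image: all classes identical
  p <- Cortex4D:::.resolveParams(
    evolutionParams(nu = 0, lambdaS = 0, mu = 0, omega = 0, nInner = 3L,
                    reinitEvery = 100L), c(1, 1))
  frozen <- Cortex4D:::.zeroFrozen(inst$triple)
  uni <- lapply(1:4, function(i) array(0.25, c(n, n)))
  names(uni) <- c("bg", "csf", "gm", "wm")
  ev <- Cortex4D:::.evolveTimepoint(inst$triple, img, uni, frozen, p, p@dt)
  expect_equal(ev$triple@phi1, inst$triple@phi1, tolerance = 1e-12)
  expect_equal(ev$triple@phi2, inst$triple@phi2, tolerance = 1e-12)
})

test_that("the length term alone shrinks a circle monotonically", {
  n <- 48
  tr <- tripleFromMasks(circleMask(n, 24, 24, 6), circleMask(n, 24, 24, 10),
                        circleMask(n, 24, 24, 15), 1)
  img <- array(50, c(n, n))
  uni <- lapply(1:4, function(i) array(0.25, c(n, n)))
  names(uni) <- c("bg", "csf", "gm", "wm")
  p <- Cortex4D:::.resolveParams(
    evolutionParams(nu = 0.5, lambdaS = 0, mu = 0, omega = 0, nInner = 40L),
    c(1, 1))
  frozen <- Cortex4D:::.zeroFrozen(tr)
  areas <- sum(tr@phi2 >= 0)
  ev <- Cortex4D:::.evolveTimepoint(tr, img, uni, frozen, p, p@dt)
  areasAfter <- sum(ev$triple@phi2 >= 0)
  expect_lt(areasAfter, areas)
})

test_that("implemented flow matches numerical differentiation of the energy", {
  # tiny two-time-point instance; everything except phi frozen
  instA <- tinyInstance(16, shift = 0, seed = 21)
  instB <- tinyInstance(16, shift = 0.6, seed = 22)
  series <- longitudinalSeries(list(instA$image, instB$image), 1)
  p <- evolutionParams(nInner = 1L)
  pR <- Cortex4D:::.resolveParams(p, c(1, 1))
  triples <- list(instA$triple, instB$triple)
  gaussians <- lapply(1:2, function(t)
    fitLocalGaussians(series@images[[t]],
                      memberships(triples[[t]], pR@eps), pR, 1))
  state <- new("SegmentationState", triples = triples, gaussians = gaussians,
               energyHistory = numeric())
  frozen <- Cortex4D:::.makeFrozen(triples, identityCorrespondence(series),
                                   NULL, pR)
  ana <- energyGradient(state, series, instA$priors, p, t = 1L,
                        frozen = frozen)
  hstep <- 1e-3
  checkField <- function(slotName, gname) {
    phi <- slot(state@triples[[1]], slotName)
    band <- which(abs(phi) <= 3)
    set.seed(31)
    band <- band[sample(length(band), min(45, length(band)))]
    num <- ana_s <- numeric(length(band))
    for (k in seq_along(band)) {
      for (sgn in c(1, -1)) {
        st2 <- state
        tr2 <- st2@triples[[1]]
        f <- slot(tr2, slotName)
        f[band[k]] <- f[band[k]] + sgn * hstep
        slot(tr2, slotName) <- f
        st2@triples[[1]] <- tr2
        e <- totalEnergy(st2, series, instA$priors, p, frozen = frozen)
        num[k] <- num[k] + sgn * e
      }
      num[k] <- num[k] / (2 * hstep)
      ana_s[k] <- ana[[gname]][band[k]]
    }
    scale <- pmax(abs(num), abs(ana_s))
    relerr <- abs(num - ana_s) / pmax(scale, 1e-4)
    expect_lt(unname(quantile(relerr, 0.95)), 0.05)
  }
  checkField("phi1", "g1")
  checkField("phi2", "g2")
  checkField("phi3", "g3")
})

test_that("mu = 0 reproduces the independent 3D pipeline voxel-exactly (small)", {
  ph <- buildPhantom(smallSpec(seed = 14))
  p <- evolutionParams(mu = 0, nInner = 8L, nOuter = 2L, refitEvery = 2L)
  r4 <- run4d(ph, params = p)
  r3 <- run3d(ph, params = p)
  for (t in 1:3) {
    expect_identical(resultLabels(r4)[[t]], resultLabels(r3)[[t]])
    expect_identical(thicknessValues(resultThickness(r4)[[t]]),
                     thicknessValues(resultThickness(r3)[[t]]))
  }
})

test_that("run4d reports descend in energy and echo the parameters", {
  ph <- buildPhantom(smallSpec(seed = 15))
  p <- evolutionParams(nInner = 10L, nOuter = 2L, refitEvery = 1L)
  res <- run4d(ph, params = p)
  rep <- resultReport(res)
  expect_lt(rep$finalEnergy, rep$initialEnergy)
  expect_true(all(is.finite(rep$energyTrace)))
  expect_equal(rep$params$nu, 0.5)
  expect_equal(rep$params$range, c(1, 6.5))
  # per-step energies within each outer block are non-increasing up to a
  # 0.1% per-step tolerance for the reinitialization and model-refit
  # perturbations, once past the first step (which absorbs the jump from
  # the initialization's model to the first refit)
  nIn <- p@nInner
  for (blk in seq_len(p@nOuter)) {
    tr <- rep$energyTrace[((blk - 1) * nIn + 2):(blk * nIn)]
    expect_true(all(diff(tr) <= 1e-3 * abs(tr[-length(tr)])))
  }
  # triples remain nested in the result: labels obey the region algebra
  for (lab in resultLabels(res))
    expect_true(all(lab %in% 0:3))
})

test_that("exclusion mask suppresses thickness forces but not the data term", {
  ph <- buildPhantom(smallSpec(seed = 16))
  p <- evolutionParams(nInner = 6L, nOuter = 1L, refitEvery = 2L)
  excl <- array(TRUE, dim(ph@images[[1]]))
  resM <- run4d(ph, params = p, exclusionMask = excl)
  res0 <- run4d(ph, params = evolutionParams(
    lambdaS = 0, mu = 0, nInner = 6L, nOuter = 1L, refitEvery = 2L))
  # with the full-domain exclusion mask, lambdaS/mu have no effect
  for (t in 1:3)
    expect_identical(resultLabels(resM)[[t]], resultLabels(res0)[[t]])
})
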