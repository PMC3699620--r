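test_that("baseline geometry has nested shells with the requested GM thickness", {
  spec <- phantomSpec(gridShape = c(128L, 128L), baselineThickness = 3,
                      rngSeed = 1)
  lab <- makeBaselineLabels(spec)
  expect_setequal(unique(as.integer(lab)), 0:3)
  tf <- groundTruthThickness(lab, spec@voxelSpacing)
  expect_true(all(abs(thicknessValues(tf) - 3) <= 0.5))
  # determinism
  expect_identical(lab, makeBaselineLabels(spec))
})

test_that("impossible shell geometry is rejected", {
  expect_error(phantomSpec(gridShape = c(32L, 32L), baselineThickness = 6,
                           csfShell = 6, rngSeed = 1),
               "too small")
})

test_that("atrophy reduces in-sphere GM volume by the shrinkage schedule", {
  spec <- phantomSpec(rngSeed = 2, shrinkageRate = 0.2)
  base <- makeBaselineLabels(spec)
  labs <- simulateAtrophy(base, spec)
  sph <- Cortex4D:::.sphereMask(dim(base), spec@voxelSpacing,
                                spec@atrophyCenter, spec@atrophyRadius)
  v <- vapply(labs, function(l) sum(l == 2L & sph), 0L)
  n0 <- v[1]
  # linear interpolation of the reduction, voxel-count oracle
  expect_equal(v / n0, c(1, 0.95, 0.90, 0.85, 0.80), tolerance = 1.5 / n0 * 5)
  # removed GM becomes CSF; outside the sphere nothing changes
  for (l in labs) {
    expect_true(all(l[!sph] == base[!sph]))
    expect_true(all(l[base == 2L & l != 2L] == 1L))
  }
  # time point 1 is the baseline; volumes are non-increasing
  expect_identical(labs[[1]], base)
  expect_true(all(diff(v) <= 0))
})

test_that("zero shrinkage leaves every time point identical to baseline", {
  spec <- smallSpec(seed = 3, shrinkageRate = 0)
  base <- makeBaselineLabels(spec)
  labs <- simulateAtrophy(base, spec)
  for (l in labs) expect_identical(l, base)
})

test_that("atrophy sphere missing the ribbon is a configuration error", {
  spec <- smallSpec(seed = 3)
  base <- makeBaselineLabels(spec)
  spec@atrophyCenter <- c(5, 5) # far corner, outside the ribbon
  spec@atrophyRadius <- 2
  expect_error(simulateAtrophy(base, spec), "does not intersect")
})

test_that("intensity schedule follows the aging protocol", {
  spec <- smallSpec(seed = 1, nTimepoints = 5L)
  lab <- makeBaselineLabels(spec)
  i1 <- assignIntensities(lab, 1, spec)
  expect_equal(unique(i1[lab == 1L]), 25)
  expect_equal(unique(i1[lab == 2L]), 85)
  expect_equal(unique(i1[lab == 3L]), 105)
  expect_equal(unique(i1[lab == 0L]), 0)
  i5 <- assignIntensities(lab, 5, spec)
  expect_equal(unique(i5[lab == 1L]), 25)  # CSF constant
  expect_equal(unique(i5[lab == 2L]), 85 - 2 * 4)
  expect_equal(unique(i5[lab == 3L]), 105 - 4 * 4)
  expect_error(assignIntensities(lab, 6, spec), "out of range")
  # all-zero declines give identical clean images
  spec0 <- smallSpec(seed = 1, perStepDecline = c(0, 0, 0))
  lab0 <- makeBaselineLabels(spec0)
  expect_identical(assignIntensities(lab0, 1, spec0),
                   assignIntensities(lab0, 3, spec0))
})

test_that("noise and PVE behave as the stated model", {
  specId <- smallSpec(seed = 4, noiseSigma = 0, pveSigma = 0)
  img <- assignIntensities(makeBaselineLabels(specId), 1, specId)
  expect_identical(addNoiseAndPve(img, specId, 1), img)

  # law of large numbers on a constant volume
  specN <- phantomSpec(gridShape = c(128L, 128L), noiseSigma = 5,
                       pveSigma = 0, rngSeed = 5)
  const <- array(85, c(128, 128))
  out <- addNoiseAndPve(const, specN, 1)
  n <- length(out)
  expect_lt(abs(mean(out) - 85), 3 * 5 / sqrt(n))
  expect_lt(abs(sd(out) - 5), 3 * 5 / sqrt(2 * n))

  # determinism and RNG-state hygiene
  a <- addNoiseAndPve(const, specN, 1)
  set.seed(99); before <- runif(3)
  b <- addNoiseAndPve(const, specN, 1)
  set.seed(99)
  expect_identical(before, runif(3))
  expect_identical(a, b)
})

test_that("priors are normalized probability maps", {
  spec <- smallSpec(seed = 6)
  lab <- makeBaselineLabels(spec)
  pri0 <- makePriors(lab, 0, spec@voxelSpacing)
  for (cls in seq_along(pri0))
    expect_equal(pri0[[cls]], array(as.double(lab == cls - 1L), dim(lab)))
  pri <- makePriors(lab, 2, spec@voxelSpacing)
  tot <- Reduce(`+`, pri)
  expect_lt(max(abs(tot - 1)), 1e-6)
  expect_true(all(vapply(pri, function(p) all(p >= 0 & p <= 1), TRUE)))
  # strong blur mixes every class in the interior
  priB <- makePriors(lab, 8, spec@voxelSpacing)
  interior <- Cortex4D:::.sphereMask(dim(lab), spec@voxelSpacing,
                                     dim(lab) * spec@voxelSpacing / 2, 20)
  for (p in priB) expect_true(all(p[interior] > 0 & p[interior] < 1))
})

test_that("ground-truth thickness matches geometry for eccentric annuli", {
  n <- 81
  inner <- circleMask(n, 40.5, 41.5, 20) # shifted 1 mm
  outer <- circleMask(n, 40.5, 40.5, 23)
  lab <- array(0L, c(n, n))
  lab[outer] <- 2L
  lab[inner] <- 3L
  tf <- groundTruthThickness(lab, 1)
  pts <- surfacePoints(tf)
  # brute-force oracle: nearest inner-boundary point for each outer point
  innSdf <- sdfFromMask(inner, 1)
  zcInn <- Cortex4D:::.zeroCrossings(innSdf, c(1, 1))$points
  for (k in sample(nrow(pts), 40)) {
    bf <- min(sqrt((zcInn[, 1] - pts[k, 1])^2 + (zcInn[, 2] - pts[k, 2])^2))
    expect_lt(abs(thicknessValues(tf)[k] - bf), 1)
  }
  # near/far side structure (2 mm vs 4 mm)
  far <- pts[, 2] < 25
  near <- pts[, 2] > 56
  expect_lt(abs(mean(thicknessValues(tf)[near]) - 2), 0.5)
  expect_lt(abs(mean(thicknessValues(tf)[far]) - 4), 0.5)
})

test_that("phantom reproducibility and conservation invariants hold", {
  spec <- smallSpec(seed = 8)
  ph1 <- buildPhantom(spec)
  ph2 <- buildPhantom(spec)
  expect_identical(ph1@images, ph2@images)
  expect_identical(ph1@labels, ph2@labels)
  # volume conservation outside the sphere
  sph <- Cortex4D:::.sphereMask(spec@gridShape, spec@voxelSpacing,
                                spec@atrophyCenter, spec@atrophyRadius)
  for (t in 2:spec@nTimepoints)
    expect_identical(ph1@labels[[t]][!sph], ph1@labels[[1]][!sph])
  # in-sphere mean ground-truth thickness declines with atrophy
  msph <- vapply(ph1@gtThickness, function(tf) {
    pts <- surfacePoints(tf)
    sel <- sqrt(rowSums(sweep(pts, 2, spec@atrophyCenter)^2)) <=
      spec@atrophyRadius
    mean(thicknessValues(tf)[sel])
  }, 0)
  expect_true(all(diff(msph) < 0))
})
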