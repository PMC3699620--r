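# Shared fixtures. Heavier phantom runs are computed lazily and cached for
# the session so several tests can share one battery of segmentations.

.fixtures <- new.env(parent = emptyenv())

# analytic circle SDF on an n x n unit-spacing grid
circleSdf <- function(n, cx, cy, R) {
  x <- matrix(seq_len(n) - 0.5, n, n)
  y <- matrix(seq_len(n) - 0.5, n, n, byrow = TRUE)
  R - sqrt((x - cx)^2 + (y - cy)^2)
}

circleMask <- function(n, cx, cy, R) circleSdf(n, cx, cy, R) >= 0

smallSpec <- function(seed = 1L, nTimepoints = 3L, ...) {
  phantomSpec(gridShape = c(64L, 64L), nTimepoints = nTimepoints,
              rngSeed = seed, ...)
}

cachedPhantom <- function(seed = 1L) {
  key <- paste0("phantom", seed)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- buildPhantom(phantomSpec(rngSeed = seed))
  .fixtures[[key]]
}

# battery parameters shared by the consistency/accuracy suites: the default
# weights and thickness range with a desk-scale iteration budget
batteryParams <- function(mu) {
  evolutionParams(mu = mu, nInner = 15L, refitEvery = 3L)
}

# one phantom + a mu = 0 and a mu = 0.5 segmentation, cached per seed
batteryRun <- function(seed) {
  key <- paste0("battery", seed)
  if (is.null(.fixtures[[key]])) {
    ph <- buildPhantom(phantomSpec(rngSeed = seed))
    out <- list(phantom = ph)
    for (mu in c(0, 0.5)) {
      res <- run4d(ph, params = batteryParams(mu))
      mth <- vapply(resultThickness(res),
                    function(tf) mean(thicknessValues(tf)), 0)
      spec <- phantomSpecOf(ph)
      inSphere <- vapply(resultThickness(res), function(tf) {
        pts <- surfacePoints(tf)
        sel <- sqrt(rowSums(sweep(pts, 2, spec@atrophyCenter)^2)) <=
          spec@atrophyRadius
        mean(thicknessValues(tf)[sel])
      }, 0)
      d <- resultReport(res)$dice
      out[[paste0("mu", mu)]] <- list(
        result = res,
        meanThickness = mth,
        inSphereThickness = inSphere,
        tv = temporalVariation(mth),
        diceGM = mean(d$dice[d$class == "gm"]),
        diceWM = mean(d$dice[d$class == "wm"]),
        report = resultReport(res))
    }
    .fixtures[[key]] <- out
  }
  .fixtures[[key]]
}

batterySeeds <- function() 1:20
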