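test_that("jitter-free lattice has exact spacing and matching point count", {
  # s = sqrt(2/(sqrt(3) * 461.88)) = 0.05 deg exactly
  expect_equal(latticeSpacing(461.88), 0.05, tolerance = 1e-5)
  m <- generatePointPattern(MosaicSpec(densityDeg2 = 461.88,
                                       jitterFraction = 0, seed = 2))
  p <- mosaicPoints(m)
  d <- as.matrix(dist(p)); diag(d) <- Inf
  nn <- apply(d, 1, min)
  expect_equal(unname(nn), rep(0.05, nrow(p)), tolerance = 1e-6)

  m500 <- generatePointPattern(MosaicSpec(densityDeg2 = 500,
                                          jitterFraction = 0, seed = 1))
  expected <- 500 * 0.55^2
  expect_lt(abs(nCells(m500) - expected) / expected, 0.05)
})

test_that("point pattern generation is deterministic and seed-sensitive", {
  spec <- MosaicSpec(densityDeg2 = 500, seed = 42)
  a <- generatePointPattern(spec)
  b <- generatePointPattern(spec)
  expect_identical(mosaicPoints(a), mosaicPoints(b))
  c <- generatePointPattern(MosaicSpec(densityDeg2 = 500, seed = 43))
  expect_false(identical(mosaicPoints(a), mosaicPoints(c)))
})

test_that("unresolvable density and invalid specs are refused", {
  expect_error(generatePointPattern(
    MosaicSpec(densityDeg2 = 5e4, scalePxPerDeg = 200)), "unresolvable")
  expect_error(MosaicSpec(densityDeg2 = -1), "densityDeg2")
  expect_error(MosaicSpec(densityDeg2 = 500, jitterFraction = 0.6), "jitter")
  expect_error(MosaicSpec(), "either densityDeg2 or eccentricityDeg")
})

test_that("expected point count tracks density times area over many seeds", {
  L <- 0.55; density <- 500
  counts <- vapply(1:100, function(sd)
    nCells(generatePointPattern(MosaicSpec(densityDeg2 = density, seed = sd))),
    numeric(1))
  s <- latticeSpacing(density)
  expected <- density * L^2
  edgeBound <- 4 * L / s  # O(perimeter/spacing)
  expect_lt(abs(mean(counts) - expected), edgeBound)
  # and much closer in the mean than any single draw is required to be
  expect_lt(abs(mean(counts) - expected) / expected, 0.03)
})

test_that("rendering embeds ground truth as degrees times scale, exactly", {
  m <- generatePointPattern(MosaicSpec(densityDeg2 = 500, seed = 3))
  img <- renderSplitDetection(m, RenderSpec(), seed = 1)
  expect_equal(unname(img@truthPx), unname(mosaicPoints(m) * 200))
  expect_equal(imageScale(img), 200)
})

test_that("single-cell render is antisymmetric about the cell's vertical line", {
  # one cell at the ROI center, no noise, no quantization loss at 16 bit
  spec <- MosaicSpec(densityDeg2 = 500, jitterFraction = 0, seed = 1)
  m <- generatePointPattern(spec)
  onePoint <- mosaicPoints(m)[1, , drop = FALSE]
  onePoint[1, ] <- c(0.275, 0.275)
  m@points <- onePoint
  img <- renderSplitDetection(m, RenderSpec(noiseSD = 0, bitDepth = 16), seed = 1)
  px <- imagePixels(img) - mean(imagePixels(img))
  n <- ncol(px)
  # reflect columns about the cell x-position (ROI center): I(x) = -I(-x)
  expect_equal(px, -px[, n:1], tolerance = 1e-3)
  # left half (bright lobe) brighter than right half
  expect_gt(mean(px[, 1:(n/2)]), mean(px[, (n/2 + 1):n]))
})

test_that("empty mosaic renders a constant background image", {
  spec <- MosaicSpec(densityDeg2 = 500, jitterFraction = 0, seed = 1)
  m <- generatePointPattern(spec)
  m@points <- matrix(numeric(), 0, 2)
  img <- renderSplitDetection(m, RenderSpec(noiseSD = 0), seed = 1)
  expect_equal(diff(range(imagePixels(img))), 0)
})

test_that("observer corrections are only shifts under perfect detection", {
  m <- generatePointPattern(MosaicSpec(densityDeg2 = 500, seed = 4))
  truthPx <- mosaicPoints(m) * 200
  det <- CellSet(truthPx)
  corr <- simulateObserverCorrections(
    m, det, ObserverModel(falseAddRate = 0, shiftFraction = 0.2, seed = 1))
  expect_true(all(corr$op == "shift"))
  corr2 <- simulateObserverCorrections(
    m, det, ObserverModel(falseAddRate = 0, shiftFraction = 0, seed = 1))
  expect_identical(nrow(corr2), 0L)
})

test_that("correction counts match binomial/Poisson expectations", {
  # degrade detection by dropping truth cells and adding clutter, then check
  # add/remove rates across images against the model means (3 SE)
  nImg <- 60
  pAdd <- 0.9; pRemove <- 0.9; lambdaSpur <- 2
  adds <- removes <- nMissed <- nFP <- numeric(nImg)
  for (i in seq_len(nImg)) {
    m <- generatePointPattern(MosaicSpec(densityDeg2 = 500, seed = i))
    truthPx <- mosaicPoints(m) * 200
    n <- nrow(truthPx)
    set.seed(i)
    drop <- sample(n, 8)
    clutterSide <- runif(12, 0, 110)
    det <- CellSet(rbind(truthPx[-drop, ], cbind(clutterSide, runif(12, 0, 110))))
    mt <- matchCellSets(truthPx, det, tolPx = latticeSpacing(500) * 200 / 2)
    nMissed[i] <- n - mt$truePositives
    nFP[i] <- nrow(cellCoords(det)) - mt$truePositives
    corr <- simulateObserverCorrections(
      m, det, ObserverModel(missCorrectionRate = pAdd, falseAddRate = lambdaSpur,
                            removeRate = pRemove, shiftFraction = 0, seed = i))
    adds[i] <- sum(corr$op == "add")
    removes[i] <- sum(corr$op == "remove")
  }
  expAdd <- mean(nMissed) * pAdd + lambdaSpur
  seAdd <- sqrt((mean(nMissed) * pAdd * (1 - pAdd) + lambdaSpur) / nImg)
  expect_lt(abs(mean(adds) - expAdd), 3 * seAdd + 0.5)
  expRem <- mean(nFP) * pRemove
  seRem <- sqrt(mean(nFP) * pRemove * (1 - pRemove) / nImg)
  expect_lt(abs(mean(removes) - expRem), 3 * seRem + 0.5)
})

test_that("measurement table has the stated design and variance structure", {
  spec <- MeasurementTableSpec(nImages = 12, seed = 3)
  tab <- simulateMeasurementTable(spec)
  expect_identical(nrow(tab), 12L * 5L * 3L)
  expect_setequal(names(tab), c("image_id", "observer_id", "repeat", "density_deg2"))

  # zero within-observer noise: repeats identical, downstream RC = 0
  z <- simulateMeasurementTable(MeasurementTableSpec(nImages = 8, withinSD = 0,
                                                     seed = 2))
  spread <- tapply(z$density_deg2,
                   interaction(z$image_id, z$observer_id), function(x) diff(range(x)))
  expect_equal(max(spread), 0)
  sw <- withinSubjectSD(z, "obs1")
  expect_equal(repeatabilityMetrics(sw$sw, sw$grandMean, 8, 3)$repeatabilityCoefficient, 0)
})

test_that("pooled within-observer variance estimator is unbiased", {
  sigw <- 5
  ests <- vapply(1:200, function(sd) {
    tab <- simulateMeasurementTable(MeasurementTableSpec(
      nImages = 30, nObservers = 1, withinSD = sigw, seed = sd))
    withinSubjectSD(tab, "obs1")$sw^2
  }, numeric(1))
  # chi-square: var of per-seed estimate is 2 sigma^4 / df, df = n(m-1)
  se <- sqrt(2 * sigw^4 / (30 * 2)) / sqrt(200)
  expect_lt(abs(mean(ests) - sigw^2), 2 * se)
})

test_that("eye-pair generator honours the log-ratio noise model", {
  # zero interocular noise: ratios exactly 1, Bland-Altman bias 0
  ep0 <- simulateEyePairs(EyePairSpec(interocularLogSD = 0, seed = 1))
  expect_equal(ep0$od_density_deg2 / ep0$os_density_deg2,
               rep(1, nrow(ep0)))
  ba <- blandAltmanDifference(ep0)
  expect_equal(ba$bias, 0)
  expect_equal(nrow(ep0), 5L * 15L)

  # log-ratio mean -> 0 and SD -> sigma as n grows
  big <- simulateEyePairs(EyePairSpec(nAnimals = 200, interocularLogSD = 0.06,
                                      seed = 8))
  lr <- log(big$od_density_deg2 / big$os_density_deg2)
  expect_lt(abs(mean(lr)), 3 * 0.06 / sqrt(nrow(big)))
  expect_equal(sd(lr), 0.06, tolerance = 0.05)
})

test_that("default density profile peaks 11 degrees inferior to the ONH", {
  locs <- seq(-9, 19, by = 2)
  expect_equal(locs[which.max(densityProfileDefault(locs))], 11)
  ep <- simulateEyePairs(EyePairSpec(seed = 5))
  prof <- buildDensityProfile(data.frame(
    animal_id = rep(ep$animal_id, 2),
    eccentricity_deg = rep(ep$eccentricity_deg, 2),
    density_deg2 = c(ep$od_density_deg2, ep$os_density_deg2)))
  peaks <- attr(prof, "peakEccentricityDeg")
  expect_true(all(peaks == 11))
})
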