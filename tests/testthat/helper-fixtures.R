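# Shared fixtures, built in code at test time.

# Long-format table with specified per-cell values: images x observers x repeats
makeTable <- function(values, imageIds, observerIds, repeats) {
  grid <- expand.grid(r = repeats, o = observerIds, i = imageIds,
                      stringsAsFactors = FALSE)
  out <- data.frame(image_id = grid$i, observer_id = grid$o, rep = grid$r,
                    density_deg2 = values, check.names = FALSE)
  names(out)[3] <- "repeat"
  out
}

# A rendered jittered mosaic with its truth, spacing, and spec
makeRenderedMosaic <- function(density = 500, jitter = 0.05, seed = 5,
                               render = RenderSpec(noiseSD = 0)) {
  spec <- MosaicSpec(densityDeg2 = density, jitterFraction = jitter, seed = seed)
  mosaic <- generatePointPattern(spec)
  img <- renderSplitDetection(mosaic, render, seed = seed)
  list(spec = spec, mosaic = mosaic, img = img,
       spacingPx = latticeSpacing(trueDensity(mosaic)) * spec@scalePxPerDeg)
}

# Exact Friedman statistic from first principles (tie-corrected), used as an
# independent oracle against the package implementation.
friedmanOracle <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  r <- t(apply(mat, 1, rank))
  Rj <- colSums(r)
  num <- (k - 1) * (sum(Rj^2) - n^2 * k * (k + 1)^2 / 4)
  den <- sum(r^2) - n * k * (k + 1)^2 / 4
  if (den == 0) 0 else num / den
}
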