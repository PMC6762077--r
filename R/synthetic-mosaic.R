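#' Built-in vertical-meridian density profile
#'
#' Piecewise-linear cone density along the vertical meridian of a
#' cone-dominant ground squirrel retina: low density superior to the optic
#' nerve head, a visual-streak peak 11 degrees inferior, and a decline beyond
#' it. Interpolates through (-9, 300), (+11, 820), (+19, 650) cells/degree^2
#' and clamps outside that range.
#'
#' @param eccentricityDeg signed eccentricity in degrees (negative superior,
#'   positive inferior).
#' @return density in cells/degree^2.
#' @export
#' @examples
#' densityProfileDefault(c(-9, 0, 11, 19))
densityProfileDefault <- function(eccentricityDeg) {
  stats::approx(x = c(-9, 11, 19), y = c(300, 820, 650),
                xout = eccentricityDeg, rule = 2)$y
}

#' Generate a jittered triangular cone lattice
#'
#' Lays down a triangular (hexagonal-packing) lattice with spacing
#' \eqn{s = \sqrt{2/(\sqrt{3}\,d)}} for target density \eqn{d}, applies
#' isotropic Gaussian positional jitter of SD \code{jitterFraction * s}, and
#' keeps the points falling inside the ROI. The lattice phase is randomized so
#' the expected point count equals density x area up to edge effects.
#' Deterministic given the spec's seed.
#'
#' @param spec a \code{\link{MosaicSpec}}.
#' @return a \code{\link{ConeMosaic}}.
#' @export
#' @examples
#' m <- generatePointPattern(MosaicSpec(densityDeg2 = 500, seed = 7))
#' nCells(m)
generatePointPattern <- function(spec) {
  stopifnot(is(spec, "MosaicSpec"))
  validObject(spec)
  s <- latticeSpacing(spec@densityDeg2)
  if (s * spec@scalePxPerDeg < 2)
    stop("unresolvable mosaic: lattice spacing ", round(s * spec@scalePxPerDeg, 2),
         " px is below 2 px at this scale")
  L <- spec@roiSizeDeg
  dy <- s * sqrt(3) / 2
  margin <- s  # jitter < 0.5 s, so one spacing of slack suffices
  pts <- withSeed(spec@seed, {
    phase <- c(stats::runif(1, 0, s), stats::runif(1, 0, dy))
    rowIdx <- seq(floor((-margin - phase[2]) / dy),
                  ceiling((L + margin - phase[2]) / dy))
    ys <- phase[2] + rowIdx * dy
    xs0 <- lapply(rowIdx, function(i) {
      off <- phase[1] + (i %% 2) * s / 2
      colIdx <- seq(floor((-margin - off) / s), ceiling((L + margin - off) / s))
      off + colIdx * s
    })
    x <- unlist(xs0)
    y <- rep(ys, lengths(xs0))
    if (spec@jitterFraction > 0) {
      x <- x + stats::rnorm(length(x), 0, spec@jitterFraction * s)
      y <- y + stats::rnorm(length(y), 0, spec@jitterFraction * s)
    }
    keep <- x >= 0 & x <= L & y >= 0 & y <= L
    cbind(x_deg = x[keep], y_deg = y[keep])
  })
  new("ConeMosaic", points = pts, trueDensityDeg2 = hexLatticeDensity(s),
      spec = spec)
}

#' Render a split-detection-like image of a mosaic
#'
#' Each cell contributes a positive Gaussian lobe at (x - delta, y) and a
#' negative lobe at (x + delta, y), with delta set by the render spec as a
#' fraction of the lattice spacing — the paired bright/dark appearance of
#' photoreceptor inner segments in non-confocal split detection. The summed
#' field is optionally blurred, Gaussian noise is added, and intensities are
#' rescaled linearly and quantized to the requested bit depth. The ground
#' truth travels with the image in pixel coordinates (degrees x scale,
#' exactly).
#'
#' @param mosaic a \code{\link{ConeMosaic}}.
#' @param render a \code{\link{RenderSpec}}.
#' @param seed RNG seed for the additive noise.
#' @param imageId identifier stored in the result.
#' @return a \code{\link{ROIImage}} with \code{truthPx} filled in.
#' @export
renderSplitDetection <- function(mosaic, render = RenderSpec(), seed = 1L,
                                 imageId = "roi") {
  stopifnot(is(mosaic, "ConeMosaic"), is(render, "RenderSpec"))
  validObject(render)
  spec <- mosaic@spec
  scale <- spec@scalePxPerDeg
  N <- round(spec@roiSizeDeg * scale)
  sPx <- latticeSpacing(mosaic@trueDensityDeg2) * scale
  sigma <- render@lobeSigmaFraction * sPx
  delta <- render@lobeOffsetFraction * sPx
  truthPx <- mosaic@points * scale
  colnames(truthPx) <- c("x_px", "y_px")

  img <- matrix(0, N, N)
  cx <- seq_len(N) - 0.5  # pixel-center coordinates, 0-based frame
  if (nrow(truthPx)) {
    win <- ceiling(4 * sigma + delta)
    for (p in seq_len(nrow(truthPx))) {
      x0 <- truthPx[p, 1]; y0 <- truthPx[p, 2]
      jr <- max(1, floor(x0 - win)):min(N, ceiling(x0 + win))
      ir <- max(1, floor(y0 - win)):min(N, ceiling(y0 + win))
      if (!length(jr) || !length(ir)) next
      gy <- exp(-(cx[ir] - y0)^2 / (2 * sigma^2))
      gxp <- exp(-(cx[jr] - (x0 - delta))^2 / (2 * sigma^2))
      gxm <- exp(-(cx[jr] - (x0 + delta))^2 / (2 * sigma^2))
      img[ir, jr] <- img[ir, jr] + outer(gy, gxp - gxm)
    }
  }
  if (render@blurSigmaPx > 0) img <- EBImage::gblur(img, render@blurSigmaPx)
  if (render@noiseSD > 0) {
    rng <- diff(range(img))
    if (rng == 0) rng <- 1
    img <- img + withSeed(seed, matrix(stats::rnorm(N * N, 0, render@noiseSD * rng), N, N))
  }
  rng <- diff(range(img))
  img <- if (rng == 0) matrix(0.5, N, N) else (img - min(img)) / rng
  maxval <- 2^render@bitDepth - 1
  img <- round(img * maxval) / maxval
  ROIImage(pixels = img, scalePxPerDeg = scale,
           eccentricityDeg = spec@eccentricityDeg, imageId = imageId,
           bitDepth = render@bitDepth, truthPx = truthPx)
}

#' Simulate observer corrections of a detection result
#'
#' Matches the detected cells against ground truth, then emits the correction
#' operations a human observer would make: \emph{add} for a Bernoulli subset
#' of the truly missed cells (at their true position), a Poisson number of
#' spurious \emph{add}s at uniform positions, \emph{remove} for detector false
#' positives with the given probability, and \emph{shift} for a random subset
#' of matched cells (displaced by isotropic Gaussian noise). Deterministic
#' given the model's seed.
#'
#' @param truth a \code{\link{ConeMosaic}} (converted to the pixel frame via
#'   its spec) or a \code{\link{CellSet}} of true positions in pixels.
#' @param detected a \code{\link{CellSet}} in the same pixel frame.
#' @param model an \code{\link{ObserverModel}}.
#' @param spacingPx expected cell spacing in pixels; defaults to the lattice
#'   spacing implied by the mosaic when \code{truth} is a ConeMosaic.
#' @param roiSizePx ROI edge in pixels (bounds for spurious adds).
#' @return a data.frame of corrections with columns
#'   \code{op, x_px, y_px, new_x_px, new_y_px}, in application order.
#' @export
simulateObserverCorrections <- function(truth, detected, model,
                                        spacingPx = NULL, roiSizePx = NULL) {
  stopifnot(is(model, "ObserverModel"))
  validObject(model)
  if (is(truth, "ConeMosaic")) {
    sc <- truth@spec@scalePxPerDeg
    if (is.null(spacingPx))
      spacingPx <- latticeSpacing(truth@trueDensityDeg2) * sc
    if (is.null(roiSizePx)) roiSizePx <- truth@spec@roiSizeDeg * sc
    truthXY <- truth@points * sc
  } else {
    truthXY <- asCoords(truth)
    if (is.null(spacingPx)) stop("spacingPx required when truth is not a ConeMosaic")
    if (is.null(roiSizePx)) roiSizePx <- max(truthXY, cellCoords(detected))
  }
  det <- cellCoords(detected)
  mt <- matchCellSets(truthXY, det, tolPx = spacingPx / 2)
  missed <- setdiff(seq_len(nrow(truthXY)), mt$matches$idxA)
  falsePos <- setdiff(seq_len(nrow(det)), mt$matches$idxB)
  matchedDet <- mt$matches$idxB

  withSeed(model@seed, {
    corr <- list()
    addIdx <- missed[stats::runif(length(missed)) < model@missCorrectionRate]
    if (length(addIdx))
      corr$add <- data.frame(op = "add", x_px = truthXY[addIdx, 1],
                             y_px = truthXY[addIdx, 2],
                             new_x_px = NA_real_, new_y_px = NA_real_)
    nSpur <- stats::rpois(1, model@falseAddRate)
    if (nSpur > 0)
      corr$spur <- data.frame(op = "add",
                              x_px = stats::runif(nSpur, 0, roiSizePx),
                              y_px = stats::runif(nSpur, 0, roiSizePx),
                              new_x_px = NA_real_, new_y_px = NA_real_)
    rmIdx <- falsePos[stats::runif(length(falsePos)) < model@removeRate]
    if (length(rmIdx))
      corr$rm <- data.frame(op = "remove", x_px = det[rmIdx, 1],
                            y_px = det[rmIdx, 2],
                            new_x_px = NA_real_, new_y_px = NA_real_)
    nShift <- round(model@shiftFraction * length(matchedDet))
    if (nShift > 0) {
      shIdx <- sample(matchedDet, nShift)
      corr$shift <- data.frame(
        op = "shift", x_px = det[shIdx, 1], y_px = det[shIdx, 2],
        new_x_px = det[shIdx, 1] + stats::rnorm(nShift, 0, model@shiftSDPx),
        new_y_px = det[shIdx, 2] + stats::rnorm(nShift, 0, model@shiftSDPx))
    }
    out <- do.call(rbind, corr)
    if (is.null(out))
      out <- data.frame(op = character(), x_px = numeric(), y_px = numeric(),
                        new_x_px = numeric(), new_y_px = numeric())
    rownames(out) <- NULL
    out
  })
}

#' Simulate a hierarchical observer measurement table
#'
#' Long-format repeated measures: density(i, j, k) = mu_i + beta_j + eps_ijk,
#' with per-image means uniform on the spec's range, Gaussian per-observer
#' biases, and Gaussian within-observer noise with per-observer SD. This is
#' the variance structure underlying within-observer SD (Sw) and the
#' repeatability coefficient.
#'
#' @param spec a \code{\link{MeasurementTableSpec}}.
#' @return data.frame with columns \code{image_id, observer_id, repeat,
#'   density_deg2}.
#' @export
#' @examples
#' tab <- simulateMeasurementTable(MeasurementTableSpec(nImages = 10, seed = 3))
#' nrow(tab)  # 10 x 5 x 3
simulateMeasurementTable <- function(spec) {
  stopifnot(is(spec, "MeasurementTableSpec"))
  validObject(spec)
  n <- spec@nImages; k <- spec@nObservers; m <- spec@nRepeats
  withSeed(spec@seed, {
    mu <- stats::runif(n, spec@imageMeanRange[1], spec@imageMeanRange[2])
    beta <- stats::rnorm(k, 0, spec@observerBiasSD)
    grid <- expand.grid(rep = seq_len(m), obs = seq_len(k), img = seq_len(n))
    eps <- stats::rnorm(nrow(grid), 0, spec@withinSD[grid$obs])
    out <- data.frame(
      image_id = sprintf("img%03d", grid$img),
      observer_id = sprintf("obs%d", grid$obs),
      rep = grid$rep,
      density_deg2 = mu[grid$img] + beta[grid$obs] + eps,
      check.names = FALSE)
    names(out)[names(out) == "rep"] <- "repeat"
    out
  })
}

#' Simulate fellow-eye density pairs
#'
#' Per-animal density profiles with multiplicative between-animal scatter and
#' ratio-scale interocular noise: OD = mu e^{eta/2}, OS = mu e^{-eta/2}.
#'
#' @param spec an \code{\link{EyePairSpec}}.
#' @return data.frame with columns \code{animal_id, eccentricity_deg,
#'   od_density_deg2, os_density_deg2}.
#' @export
simulateEyePairs <- function(spec) {
  stopifnot(is(spec, "EyePairSpec"))
  validObject(spec)
  nA <- spec@nAnimals
  locs <- spec@locationsDeg
  withSeed(spec@seed, {
    animalScale <- exp(stats::rnorm(nA, 0, spec@animalScaleSD))
    grid <- expand.grid(loc = locs, animal = seq_len(nA))
    mu <- spec@profile(grid$loc) * animalScale[grid$animal]
    eta <- stats::rnorm(nrow(grid), 0, spec@interocularLogSD)
    data.frame(animal_id = sprintf("animal%d", grid$animal),
               eccentricity_deg = grid$loc,
               od_density_deg2 = mu * exp(eta / 2),
               os_density_deg2 = mu * exp(-eta / 2))
  })
}
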