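#' Detection parameters
#'
#' Constants of the automated cell detector. The pipeline is: spectral spacing
#' estimate (unless \code{spacingPx} is given), difference-of-Gaussians
#' band-pass centered at the mosaic spacing, regional maxima with a minimum
#' separation, an amplitude gate against weak noise maxima, and 3 x 3
#' center-of-mass sub-pixel refinement.
#'
#' @param spacingPx expected cell spacing in pixels (estimated from the image
#'   power spectrum when NULL).
#' @param bandFraction relative bandwidth of the band-pass filter in (0, 1).
#' @param minDistanceFraction minimum peak separation as a fraction of spacing,
#'   in (0, 1].
#' @param contrastQuantile amplitude floor: maxima weaker than this fraction of
#'   the strongest maximum are dropped.
#' @return a list of class parameters for \code{\link{detectCells}}.
#' @export
detectionParams <- function(spacingPx = NULL, bandFraction = 0.5,
                            minDistanceFraction = 0.65,
                            contrastQuantile = 0.05) {
  stopifnot(bandFraction > 0, bandFraction < 1,
            minDistanceFraction > 0, minDistanceFraction <= 1,
            contrastQuantile >= 0, contrastQuantile < 1)
  list(spacingPx = spacingPx, bandFraction = bandFraction,
       minDistanceFraction = minDistanceFraction,
       contrastQuantile = contrastQuantile)
}

#' Estimate mosaic spacing from the radial power spectrum
#'
#' Finds the radial frequency f* of the maximum of the radially averaged power
#' spectrum (Hann-windowed, mean-subtracted), excluding DC and frequencies
#' below 1/(edge/2). For a triangular mosaic the spectral ring sits at the row
#' spacing, \eqn{\sqrt{3}/2} of the center-to-center spacing, so the estimate
#' is returned hex-corrected as \eqn{(2/\sqrt{3})/f^*} pixels. A spectrum
#' without an interior peak (e.g. white noise) is rejected.
#'
#' @param image a \code{\link{ROIImage}} or numeric matrix, at least 32 x 32.
#' @param minPeakRatio peak-to-median power ratio below which the spectrum is
#'   declared peakless.
#' @return estimated center-to-center spacing in pixels.
#' @export
estimateSpacing <- function(image, minPeakRatio = 3) {
  px <- if (is(image, "ROIImage")) imagePixels(image) else image
  if (min(dim(px)) < 32) stop("image must be at least 32 x 32 px")
  rp <- radialPowerSpectrum(px)
  N <- min(dim(px))
  keep <- rp$freq > 2 / N & rp$freq <= 0.5
  rp <- rp[keep, , drop = FALSE]
  if (!nrow(rp) || max(rp$power) < minPeakRatio * stats::median(rp$power))
    stop("spacing not estimable: no interior spectral peak")
  (2 / sqrt(3)) / rp$freq[which.max(rp$power)]
}

#' Detect cells in a split-detection ROI
#'
#' Filters the image with a laterally offset difference of Gaussians matched
#' to the split-detection dipole (a positive Gaussian a quarter-spacing left
#' of center minus a negative one a quarter-spacing right, SD set by
#' \code{bandFraction}), so the band-passed response peaks at the cell center
#' rather than on the bright lobe. Regional maxima separated by at least
#' \code{minDistanceFraction} x spacing are kept, maxima weaker than the
#' amplitude gate are dropped, and each survivor is refined to sub-pixel
#' precision by center of mass in its 3 x 3 neighbourhood. Plateau ties keep
#' the lexicographically smallest (row, col) pixel, so detection is
#' deterministic.
#'
#' @param image a \code{\link{ROIImage}}.
#' @param params a \code{\link{detectionParams}} list.
#' @return a \code{\link{CellSet}} with \code{source = "algorithm"}.
#' @export
detectCells <- function(image, params = detectionParams()) {
  stopifnot(is(image, "ROIImage"))
  px <- imagePixels(image)
  if (diff(range(px)) == 0)
    return(CellSet(matrix(numeric(), 0, 2)))
  spacing <- params$spacingPx
  if (is.null(spacing)) spacing <- estimateSpacing(image)

  f <- dipoleBandPass(px, spacing, params$bandFraction)

  pk <- regionalMaxima(f)
  if (!nrow(pk)) return(CellSet(matrix(numeric(), 0, 2)))
  # strongest-first greedy min-distance pruning
  ord <- order(-pk$value, pk$row, pk$col)
  pk <- pk[ord, , drop = FALSE]
  minD <- params$minDistanceFraction * spacing
  keep <- rep(TRUE, nrow(pk))
  for (i in seq_len(nrow(pk))[-1]) {
    prev <- which(keep[seq_len(i - 1)])
    if (length(prev)) {
      d2 <- (pk$row[prev] - pk$row[i])^2 + (pk$col[prev] - pk$col[i])^2
      if (any(d2 < minD^2)) keep[i] <- FALSE
    }
  }
  pk <- pk[keep, , drop = FALSE]
  pk <- pk[pk$value >= params$contrastQuantile * max(pk$value), , drop = FALSE]
  if (!nrow(pk)) return(CellSet(matrix(numeric(), 0, 2)))

  # 3x3 center-of-mass refinement on the band-passed image (window clamped
  # at the image border)
  nr <- nrow(f); nc <- ncol(f)
  coords <- t(vapply(seq_len(nrow(pk)), function(i) {
    r <- pk$row[i]; cc <- pk$col[i]
    rs <- max(1, r - 1):min(nr, r + 1)
    cs <- max(1, cc - 1):min(nc, cc + 1)
    w <- f[rs, cs, drop = FALSE]
    w <- w - min(w)
    if (sum(w) == 0) w[] <- 1
    dr <- sum(w * (rs - r)) / sum(w)
    dc <- sum(t(w) * (cs - cc)) / sum(w)
    c((cc + dc) - 0.5, (r + dr) - 0.5)  # (x, y), 0-based pixel centers
  }, numeric(2)))
  CellSet(coords)
}

## Split-detection matched band-pass: correlation with a laterally offset
## difference of Gaussians (positive lobe at -spacing/4, negative at
## +spacing/4, SD = bandFraction * spacing / 2). Zero-mean by antisymmetry;
## peak response sits at the dipole center. The image is mean-centered and
## zero-padded, and the response divided by the fraction of kernel mass
## falling inside the image, so cells whose dipole is clipped by the image
## border keep a full-amplitude response.
dipoleBandPass <- function(px, spacing, bandFraction) {
  sigma <- bandFraction * spacing / 2
  delta <- spacing / 4
  half <- ceiling(3 * sigma + delta)
  u <- -half:half
  g <- function(x) exp(-x^2 / (2 * sigma^2))
  # filter2 convolves (mirrors the kernel), so the template is built
  # pre-flipped: after mirroring it matches bright-left/dark-right
  kern <- outer(g(u), g(u - delta) - g(u + delta))  # rows y, cols x
  kern <- kern / sum(abs(kern))
  resp <- EBImage::filter2(px - mean(px), kern, boundary = 0)
  wt <- EBImage::filter2(matrix(1, nrow(px), ncol(px)), abs(kern),
                         boundary = 0)
  resp / pmax(wt, 0.25)
}

## Regional maxima of a matrix over the 8-neighbourhood; out-of-image
## neighbours count as -Inf so border cells remain detectable. On plateaus
## the lexicographically smallest (row, col) pixel wins: strict > is required
## against the 4 neighbours that precede in raster order, >= against the 4
## that follow.
regionalMaxima <- function(f) {
  nr <- nrow(f); nc <- ncol(f)
  fp <- matrix(-Inf, nr + 2, nc + 2)
  fp[2:(nr + 1), 2:(nc + 1)] <- f
  i <- 2:(nr + 1); j <- 2:(nc + 1)
  v <- fp[i, j]
  isMax <-
    v >  fp[i - 1, j - 1] & v >  fp[i - 1, j] & v >  fp[i - 1, j + 1] &
    v >  fp[i,     j - 1] & v >= fp[i,     j + 1] &
    v >= fp[i + 1, j - 1] & v >= fp[i + 1, j] & v >= fp[i + 1, j + 1]
  w <- which(isMax, arr.ind = TRUE)
  data.frame(row = w[, 1], col = w[, 2], value = v[isMax])
}

#' Apply observer corrections to a cell set
#'
#' Applies a correction list in order: \emph{add} appends a cell (adds landing
#' within 1 px of an existing cell are suppressed to keep centers distinct);
#' \emph{remove} deletes the nearest cell within spacing/2 of the stated
#' coordinate; \emph{shift} moves the nearest cell to its new coordinate.
#' Removes or shifts with no cell within tolerance are recorded as dangling
#' and skipped.
#'
#' @param cells a \code{\link{CellSet}}.
#' @param corrections data.frame as produced by
#'   \code{\link{simulateObserverCorrections}}.
#' @param spacingPx cell spacing in pixels (sets the matching tolerance).
#' @param observerId,repeatIdx provenance recorded on the result.
#' @return a \code{\link{CellSet}} with \code{source = "observer"};
#'   \code{attr(, "dangling")} counts skipped corrections and
#'   \code{attr(, "suppressedAdds")} adds suppressed by the 1-px rule.
#' @export
applyCorrections <- function(cells, corrections, spacingPx,
                             observerId = NA_character_, repeatIdx = NA_real_) {
  stopifnot(is(cells, "CellSet"), spacingPx > 0)
  xy <- cellCoords(cells)
  tol <- spacingPx / 2
  dangling <- 0L
  suppressed <- 0L
  if (nrow(corrections)) for (r in seq_len(nrow(corrections))) {
    op <- corrections$op[r]
    p <- c(corrections$x_px[r], corrections$y_px[r])
    if (op == "add") {
      if (nrow(xy)) {
        d2 <- (xy[, 1] - p[1])^2 + (xy[, 2] - p[2])^2
        if (min(d2) < 1) { suppressed <- suppressed + 1L; next }
      }
      xy <- rbind(xy, p)
    } else if (op %in% c("remove", "shift")) {
      if (!nrow(xy)) { dangling <- dangling + 1L; next }
      d2 <- (xy[, 1] - p[1])^2 + (xy[, 2] - p[2])^2
      i <- which.min(d2)
      if (d2[i] > tol^2) { dangling <- dangling + 1L; next }
      if (op == "remove") xy <- xy[-i, , drop = FALSE]
      else xy[i, ] <- c(corrections$new_x_px[r], corrections$new_y_px[r])
    } else stop("unknown correction op: ", op)
  }
  out <- CellSet(xy, source = "observer", observerId = observerId,
                 repeatIdx = repeatIdx)
  attr(out, "dangling") <- dangling
  attr(out, "suppressedAdds") <- suppressed
  out
}

#' Match two cell sets by greedy mutual-nearest pairing
#'
#' Candidate pairs within tolerance are sorted by distance and accepted
#' greedily while both members are unmatched, giving a one-to-one matching.
#' Precision is TP/|b| and recall TP/|a| (a is treated as the reference set).
#'
#' @param a,b \code{\link{CellSet}}s or n x 2 coordinate matrices (a =
#'   reference/truth, b = detected).
#' @param tolPx maximum pairing distance in pixels.
#' @return list with \code{nTrue, nDetected, truePositives, precision, recall,
#'   meanLocalizationErrorPx, matches} (data.frame idxA, idxB, dist) and
#'   \code{undefinedPrecision} (TRUE when b is empty).
#' @export
matchCellSets <- function(a, b, tolPx) {
  stopifnot(tolPx > 0)
  A <- asCoords(a); B <- asCoords(b)
  nA <- nrow(A); nB <- nrow(B)
  matches <- data.frame(idxA = integer(), idxB = integer(), dist = numeric())
  if (nA && nB) {
    d <- crossDist(A, B)
    cand <- which(d <= tolPx, arr.ind = TRUE)
    if (nrow(cand)) {
      dv <- d[cand]
      ord <- order(dv, cand[, 1], cand[, 2])
      usedA <- logical(nA); usedB <- logical(nB)
      ia <- cand[ord, 1]; ib <- cand[ord, 2]; dd <- dv[ord]
      sel <- logical(length(ord))
      for (q in seq_along(ord)) {
        if (!usedA[ia[q]] && !usedB[ib[q]]) {
          usedA[ia[q]] <- TRUE; usedB[ib[q]] <- TRUE; sel[q] <- TRUE
        }
      }
      matches <- data.frame(idxA = ia[sel], idxB = ib[sel], dist = dd[sel])
    }
  }
  tp <- nrow(matches)
  list(nTrue = nA, nDetected = nB, truePositives = tp,
       precision = if (nB) tp / nB else 0,
       recall = if (nA) tp / nA else 0,
       meanLocalizationErrorPx = if (tp) mean(matches$dist) else NA_real_,
       matches = matches,
       undefinedPrecision = nB == 0)
}
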