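#' Cone density from bound Voronoi cells
#'
#' Tessellates the cell coordinates (Voronoi/Dirichlet) and computes density
#' as the number of \emph{bound} Voronoi cells divided by their summed area.
#' A cell is bound iff its polygon is finite and lies entirely inside the ROI
#' rectangle \code{[0, roiSizeDeg]^2} (a vertex on the boundary counts as
#' contained, tolerance 1e-9 deg). Polygon areas use the shoelace formula on
#' the tile vertices. Restricting to bound cells removes the edge bias of
#' clipped or unbounded polygons.
#'
#' @param cells a \code{\link{CellSet}} or n x 2 matrix of pixel coordinates.
#' @param roiSizeDeg ROI edge length in degrees.
#' @param scalePxPerDeg pixels per degree (converts coordinates and areas).
#' @param imageId,observerId,repeatIdx provenance carried into the result.
#' @return list with \code{nTotal, nBound, summedAreaDeg2, densityDeg2}
#'   (NA with \code{undefined = TRUE} when no cell is bound),
#'   \code{boundIndex} and \code{degenerateAdjusted}.
#' @export
#' @examples
#' m <- generatePointPattern(MosaicSpec(densityDeg2 = 461.88, jitterFraction = 0))
#' r <- voronoiDensity(mosaicPoints(m) * 200, 0.55, 200)
#' r$densityDeg2  # ~ 2 / (sqrt(3) * 0.05^2)
voronoiDensity <- function(cells, roiSizeDeg, scalePxPerDeg,
                           imageId = NA_character_, observerId = NA_character_,
                           repeatIdx = NA_real_) {
  stopifnot(roiSizeDeg > 0, scalePxPerDeg > 0)
  xy <- asCoords(cells) / scalePxPerDeg
  n <- nrow(xy)
  if (n < 4) stop("degenerate tessellation: need at least 4 points")
  if (qr(sweep(xy, 2, colMeans(xy)))$rank < 2)
    stop("degenerate tessellation: points are collinear")
  L <- roiSizeDeg
  rw <- c(min(xy[, 1]) - L, max(xy[, 1]) + L, min(xy[, 2]) - L, max(xy[, 2]) + L)
  degen <- FALSE
  dd <- tryCatch(
    deldir::deldir(xy[, 1], xy[, 2], rw = rw, suppressMsge = TRUE),
    error = function(e) NULL)
  if (is.null(dd)) {
    # deterministic sub-precision nudge for cocircular/duplicate inputs
    degen <- TRUE
    spacingGuess <- sqrt(2 / (sqrt(3) * n / L^2))
    eps <- 1e-9 * spacingGuess
    xy <- xy + eps * cbind(sin(1e4 * seq_len(n)), cos(1e4 * seq_len(n)))
    dd <- deldir::deldir(xy[, 1], xy[, 2], rw = rw, suppressMsge = TRUE)
  }
  tiles <- deldir::tile.list(dd)
  tol <- 1e-9
  bound <- vapply(tiles, function(tl) {
    !any(tl$bp) &&
      all(tl$x >= -tol & tl$x <= L + tol & tl$y >= -tol & tl$y <= L + tol)
  }, logical(1))
  areas <- vapply(tiles[bound], function(tl) shoelaceArea(tl$x, tl$y), numeric(1))
  nBound <- sum(bound)
  undefined <- nBound == 0
  list(nTotal = n, nBound = nBound,
       summedAreaDeg2 = sum(areas),
       densityDeg2 = if (undefined) NA_real_ else nBound / sum(areas),
       undefined = undefined, boundIndex = which(bound),
       degenerateAdjusted = degen,
       imageId = imageId, observerId = observerId, repeatIdx = repeatIdx)
}

#' Convert angular density to areal density
#'
#' @param densityDeg2 density in cells/degree^2.
#' @param rmfUmPerDeg retinal magnification factor, microns of retina per
#'   degree of visual angle (100 um/deg is the ground-squirrel convention).
#' @return density in cells/mm^2: \code{densityDeg2 * (1000 / rmf)^2}.
#' @export
#' @examples
#' convertDensity(500, 100)  # 50,000 cells/mm^2
convertDensity <- function(densityDeg2, rmfUmPerDeg = 100) {
  stopifnot(rmfUmPerDeg > 0)
  densityDeg2 * (1000 / rmfUmPerDeg)^2
}

#' Density-versus-eccentricity profile
#'
#' Averages density over eyes (and observers/repeats, if present) per
#' (animal, eccentricity), sorts by eccentricity, and reports each animal's
#' peak location.
#'
#' @param results data.frame with columns \code{animal_id, eccentricity_deg,
#'   density_deg2} and optionally \code{eye, observer_id, repeat}.
#' @return data.frame \code{animal_id, eccentricity_deg, mean_density_deg2, n},
#'   sorted by animal then eccentricity, with
#'   \code{attr(, "peakEccentricityDeg")} naming each animal's argmax location.
#' @export
buildDensityProfile <- function(results) {
  need <- c("animal_id", "eccentricity_deg", "density_deg2")
  if (!nrow(results)) {
    out <- data.frame(animal_id = character(), eccentricity_deg = numeric(),
                      mean_density_deg2 = numeric(), n = integer())
    attr(out, "peakEccentricityDeg") <- numeric()
    return(out)
  }
  stopifnot(all(need %in% names(results)))
  key <- interaction(results$animal_id, results$eccentricity_deg, drop = TRUE)
  agg <- data.frame(
    animal_id = tapply(as.character(results$animal_id), key, `[`, 1),
    eccentricity_deg = tapply(results$eccentricity_deg, key, `[`, 1),
    mean_density_deg2 = tapply(results$density_deg2, key, mean),
    n = as.integer(tapply(results$density_deg2, key, length)))
  agg <- agg[order(agg$animal_id, agg$eccentricity_deg), ]
  rownames(agg) <- NULL
  peaks <- vapply(split(agg, agg$animal_id), function(d)
    d$eccentricity_deg[which.max(d$mean_density_deg2)], numeric(1))
  attr(agg, "peakEccentricityDeg") <- peaks
  agg
}
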