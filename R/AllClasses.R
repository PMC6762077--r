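#' @import methods
NULL

## ---------------------------------------------------------------------------
## Specification objects (parameter containers with validity checks)
## ---------------------------------------------------------------------------

#' Mosaic generation parameters
#'
#' Describes a square region of interest (ROI) and the triangular cone lattice
#' to simulate inside it. Either a target density or a signed retinal
#' eccentricity may be given; an eccentricity is converted to a density through
#' \code{\link{densityProfileDefault}}, the package's built-in vertical-meridian
#' density profile (negative eccentricities are superior to the optic nerve
#' head, positive inferior).
#'
#' @slot roiSizeDeg edge length of the square ROI, degrees (study ROIs are
#'   0.55 x 0.55 degrees).
#' @slot scalePxPerDeg image scale, pixels per degree.
#' @slot densityDeg2 target cone density, cells/degree^2.
#' @slot eccentricityDeg signed eccentricity used to look up the density when
#'   \code{densityDeg2} is not given (\code{NA} otherwise).
#' @slot jitterFraction SD of isotropic positional jitter as a fraction of the
#'   lattice spacing.
#' @slot seed RNG seed for lattice phase and jitter.
#' @export
setClass("MosaicSpec", representation(
  roiSizeDeg = "numeric", scalePxPerDeg = "numeric", densityDeg2 = "numeric",
  eccentricityDeg = "numeric", jitterFraction = "numeric", seed = "numeric"
))

setValidity("MosaicSpec", function(object) {
  msg <- character()
  if (object@roiSizeDeg <= 0) msg <- c(msg, "roiSizeDeg must be > 0")
  if (object@scalePxPerDeg <= 0) msg <- c(msg, "scalePxPerDeg must be > 0")
  if (!is.na(object@densityDeg2) && object@densityDeg2 <= 0)
    msg <- c(msg, "densityDeg2 must be > 0")
  if (object@jitterFraction < 0 || object@jitterFraction >= 0.5)
    msg <- c(msg, "jitterFraction must be in [0, 0.5)")
  if (length(msg)) msg else TRUE
})

#' @rdname MosaicSpec-class
#' @param roiSizeDeg,scalePxPerDeg,densityDeg2,eccentricityDeg,jitterFraction,seed
#'   see slots.
#' @return a \code{MosaicSpec}.
#' @export
#' @examples
#' MosaicSpec(densityDeg2 = 500)
#' MosaicSpec(eccentricityDeg = 11)  # visual-streak density from the profile
MosaicSpec <- function(roiSizeDeg = 0.55, scalePxPerDeg = 200,
                       densityDeg2 = NA_real_, eccentricityDeg = NA_real_,
                       jitterFraction = 0.12, seed = 1L) {
  if (is.na(densityDeg2)) {
    if (is.na(eccentricityDeg))
      stop("give either densityDeg2 or eccentricityDeg")
    densityDeg2 <- densityProfileDefault(eccentricityDeg)
  }
  new("MosaicSpec", roiSizeDeg = roiSizeDeg, scalePxPerDeg = scalePxPerDeg,
      densityDeg2 = densityDeg2, eccentricityDeg = eccentricityDeg,
      jitterFraction = jitterFraction, seed = as.numeric(seed))
}

#' Split-detection rendering parameters
#'
#' Split-detection AOSLO renders each photoreceptor inner segment as a paired
#' bright/dark horizontal lobe. Each simulated cell contributes a positive
#' Gaussian lobe left of its center and a negative lobe right of it; blur and
#' additive noise act as image-quality knobs.
#'
#' @slot lobeSigmaFraction Gaussian lobe SD as a fraction of lattice spacing.
#' @slot lobeOffsetFraction half-distance between the bright and dark lobes as
#'   a fraction of spacing.
#' @slot blurSigmaPx post-render Gaussian blur SD, pixels (0 = none).
#' @slot noiseSD additive Gaussian noise SD as a fraction of dynamic range.
#' @slot bitDepth 8 or 16.
#' @export
setClass("RenderSpec", representation(
  lobeSigmaFraction = "numeric", lobeOffsetFraction = "numeric",
  blurSigmaPx = "numeric", noiseSD = "numeric", bitDepth = "numeric"
))

setValidity("RenderSpec", function(object) {
  msg <- character()
  if (object@lobeSigmaFraction < 0 || object@lobeOffsetFraction < 0 ||
      object@blurSigmaPx < 0 || object@noiseSD < 0)
    msg <- c(msg, "all fractions must be >= 0")
  if (!object@bitDepth %in% c(8, 16)) msg <- c(msg, "bitDepth must be 8 or 16")
  if (length(msg)) msg else TRUE
})

#' @rdname RenderSpec-class
#' @param lobeSigmaFraction,lobeOffsetFraction,blurSigmaPx,noiseSD,bitDepth see
#'   slots.
#' @export
RenderSpec <- function(lobeSigmaFraction = 0.22, lobeOffsetFraction = 0.25,
                       blurSigmaPx = 0, noiseSD = 0.02, bitDepth = 8) {
  new("RenderSpec", lobeSigmaFraction = lobeSigmaFraction,
      lobeOffsetFraction = lobeOffsetFraction, blurSigmaPx = blurSigmaPx,
      noiseSD = noiseSD, bitDepth = bitDepth)
}

#' Observer correction behaviour
#'
#' Parameterizes how a simulated observer corrects an automated detection:
#' adding cells the detector missed, removing detector false positives, adding
#' spurious cells, and shifting cell centers. Defaults reflect a careful
#' observer; the shift fraction default sits mid-range of the 5--22\% of cells
#' observers typically re-center.
#'
#' @slot missCorrectionRate probability a truly missed cell is added.
#' @slot falseAddRate expected number of spurious additions per image (Poisson).
#' @slot removeRate probability a detector false positive is removed.
#' @slot shiftFraction fraction of matched cells whose center is shifted.
#' @slot shiftSDPx SD of the shift displacement, pixels.
#' @slot seed RNG seed.
#' @export
setClass("ObserverModel", representation(
  missCorrectionRate = "numeric", falseAddRate = "numeric",
  removeRate = "numeric", shiftFraction = "numeric", shiftSDPx = "numeric",
  seed = "numeric"
))

setValidity("ObserverModel", function(object) {
  msg <- character()
  rates <- c(object@missCorrectionRate, object@removeRate, object@shiftFraction)
  if (any(rates < 0 | rates > 1)) msg <- c(msg, "rates must lie in [0, 1]")
  if (object@falseAddRate < 0) msg <- c(msg, "falseAddRate must be >= 0")
  if (object@shiftSDPx < 0) msg <- c(msg, "shiftSDPx must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname ObserverModel-class
#' @param missCorrectionRate,falseAddRate,removeRate,shiftFraction,shiftSDPx,seed
#'   see slots.
#' @export
ObserverModel <- function(missCorrectionRate = 0.9, falseAddRate = 0.5,
                          removeRate = 0.9, shiftFraction = 0.12,
                          shiftSDPx = 1, seed = 1L) {
  new("ObserverModel", missCorrectionRate = missCorrectionRate,
      falseAddRate = falseAddRate, removeRate = removeRate,
      shiftFraction = shiftFraction, shiftSDPx = shiftSDPx,
      seed = as.numeric(seed))
}

#' Hierarchical measurement-table parameters
#'
#' Describes the repeated-measures design of the observer study: each of
#' \code{nImages} images is measured \code{nRepeats} times by each of
#' \code{nObservers} observers, with density
#' \eqn{d_{ijk} = \mu_i + \beta_j + \epsilon_{ijk}} where per-image means
#' \eqn{\mu_i} are uniform on \code{imageMeanRange}, observer biases
#' \eqn{\beta_j} are Gaussian, and within-observer noise has per-observer SD
#' \code{withinSD}. Defaults reproduce the study design (214 images, 5
#' observers, 3 repeats, means spanning 166--885 cells/degree^2) with
#' within-observer SDs implied by the observers' published repeatability
#' coefficients (RC/2.77).
#'
#' @slot nImages,nObservers,nRepeats design sizes.
#' @slot imageMeanRange length-2 numeric, low/high of per-image true density.
#' @slot observerBiasSD SD of the additive per-observer bias, cells/degree^2.
#' @slot withinSD per-observer within-observer SD (recycled to nObservers).
#' @slot seed RNG seed.
#' @export
setClass("MeasurementTableSpec", representation(
  nImages = "numeric", nObservers = "numeric", nRepeats = "numeric",
  imageMeanRange = "numeric", observerBiasSD = "numeric", withinSD = "numeric",
  seed = "numeric"
))

setValidity("MeasurementTableSpec", function(object) {
  msg <- character()
  if (any(c(object@nImages, object@nObservers, object@nRepeats) < 1))
    msg <- c(msg, "nImages, nObservers, nRepeats must all be >= 1")
  if (length(object@imageMeanRange) != 2 ||
      object@imageMeanRange[1] >= object@imageMeanRange[2])
    msg <- c(msg, "imageMeanRange must be c(low, high) with low < high")
  if (any(object@withinSD < 0) || object@observerBiasSD < 0)
    msg <- c(msg, "SDs must be >= 0")
  if (length(object@withinSD) != object@nObservers)
    msg <- c(msg, "withinSD must have one value per observer")
  if (length(msg)) msg else TRUE
})

#' @rdname MeasurementTableSpec-class
#' @param nImages,nObservers,nRepeats,imageMeanRange,observerBiasSD,withinSD,seed
#'   see slots.
#' @export
MeasurementTableSpec <- function(nImages = 214, nObservers = 5, nRepeats = 3,
                                 imageMeanRange = c(166, 885),
                                 observerBiasSD = 5,
                                 withinSD = c(3.40, 4.87, 4.78, 9.28, 3.83),
                                 seed = 1L) {
  withinSD <- rep_len(withinSD, nObservers)
  new("MeasurementTableSpec", nImages = nImages, nObservers = nObservers,
      nRepeats = nRepeats, imageMeanRange = imageMeanRange,
      observerBiasSD = observerBiasSD, withinSD = withinSD,
      seed = as.numeric(seed))
}

#' Interocular pair simulation parameters
#'
#' Fellow-eye densities share a per-animal profile value; interocular asymmetry
#' is multiplicative: \eqn{OD = \mu e^{\eta/2}}, \eqn{OS = \mu e^{-\eta/2}}
#' with \eqn{\eta \sim N(0, \sigma_{log}^2)}, so \eqn{\log(OD/OS) = \eta}.
#'
#' @slot nAnimals number of animals with both eyes imaged.
#' @slot locationsDeg signed eccentricities sampled along the vertical meridian.
#' @slot profile function eccentricity -> density, cells/degree^2.
#' @slot animalScaleSD SD of the per-animal log scale factor.
#' @slot interocularLogSD SD of log(OD/OS).
#' @slot seed RNG seed.
#' @export
setClass("EyePairSpec", representation(
  nAnimals = "numeric", locationsDeg = "numeric", profile = "function",
  animalScaleSD = "numeric", interocularLogSD = "numeric", seed = "numeric"
))

setValidity("EyePairSpec", function(object) {
  msg <- character()
  if (object@interocularLogSD < 0) msg <- c(msg, "interocularLogSD must be >= 0")
  if (object@animalScaleSD < 0) msg <- c(msg, "animalScaleSD must be >= 0")
  if (anyDuplicated(object@locationsDeg)) msg <- c(msg, "locations must be distinct")
  if (object@nAnimals < 1) msg <- c(msg, "nAnimals must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname EyePairSpec-class
#' @param nAnimals,locationsDeg,profile,animalScaleSD,interocularLogSD,seed see
#'   slots.
#' @export
EyePairSpec <- function(nAnimals = 5, locationsDeg = seq(-9, 19, by = 2),
                        profile = densityProfileDefault, animalScaleSD = 0.12,
                        interocularLogSD = 0.06, seed = 1L) {
  new("EyePairSpec", nAnimals = nAnimals, locationsDeg = locationsDeg,
      profile = profile, animalScaleSD = animalScaleSD,
      interocularLogSD = interocularLogSD, seed = as.numeric(seed))
}

## ---------------------------------------------------------------------------
## Data containers
## ---------------------------------------------------------------------------

#' Ground-truth cone mosaic
#'
#' Simulated cone positions in degrees inside the ROI, together with the
#' density implied by the generating lattice.
#'
#' @slot points n x 2 matrix of (x, y), degrees, within [0, roiSizeDeg]^2.
#' @slot trueDensityDeg2 density implied by the lattice spacing.
#' @slot spec the \code{\link{MosaicSpec}} used.
#' @export
setClass("ConeMosaic", representation(
  points = "matrix", trueDensityDeg2 = "numeric", spec = "MosaicSpec"
))

setValidity("ConeMosaic", function(object) {
  p <- object@points
  L <- object@spec@roiSizeDeg
  if (ncol(p) != 2) return("points must be an n x 2 matrix")
  if (nrow(p) && (min(p) < 0 || max(p) > L))
    return("all points must lie inside the ROI")
  TRUE
})

#' Region-of-interest image
#'
#' A single-channel ROI with its scale and acquisition metadata. Pixel
#' intensities are stored normalized to [0, 1] at the stated bit depth.
#' Coordinates used throughout the package are continuous, 0-based, origin at
#' the top-left corner, +y down; the center of matrix pixel (i, j) is at
#' (j - 0.5, i - 0.5).
#'
#' @slot pixels numeric matrix of intensities in [0, 1].
#' @slot scalePxPerDeg pixels per degree.
#' @slot eccentricityDeg signed eccentricity (negative superior, positive
#'   inferior to the optic nerve head).
#' @slot eye "OD", "OS" or NA.
#' @slot animalId,state,imageId metadata strings.
#' @slot bitDepth 8 or 16.
#' @slot truthPx ground-truth cell positions in pixel coordinates (0-row matrix
#'   when unknown).
#' @export
setClass("ROIImage", representation(
  pixels = "matrix", scalePxPerDeg = "numeric", eccentricityDeg = "numeric",
  eye = "character", animalId = "character", state = "character",
  imageId = "character", bitDepth = "numeric", truthPx = "matrix"
))

setValidity("ROIImage", function(object) {
  msg <- character()
  if (!length(object@pixels)) msg <- c(msg, "pixel grid must be non-empty")
  if (object@scalePxPerDeg <= 0) msg <- c(msg, "scalePxPerDeg must be > 0")
  if (!object@bitDepth %in% c(8, 16)) msg <- c(msg, "bitDepth must be 8 or 16")
  if (!object@eye %in% c("OD", "OS", NA_character_))
    msg <- c(msg, "eye must be OD, OS or NA")
  if (length(msg)) msg else TRUE
})

#' @rdname ROIImage-class
#' @param pixels,scalePxPerDeg,eccentricityDeg,eye,animalId,state,imageId,bitDepth,truthPx
#'   see slots.
#' @export
ROIImage <- function(pixels, scalePxPerDeg, eccentricityDeg = NA_real_,
                     eye = NA_character_, animalId = NA_character_,
                     state = NA_character_, imageId = "roi", bitDepth = 8,
                     truthPx = matrix(numeric(), 0, 2)) {
  new("ROIImage", pixels = pixels, scalePxPerDeg = scalePxPerDeg,
      eccentricityDeg = eccentricityDeg, eye = eye, animalId = animalId,
      state = state, imageId = imageId, bitDepth = bitDepth,
      truthPx = truthPx)
}

#' Set of cell coordinates
#'
#' Detected or corrected cell centers in continuous 0-based pixel coordinates,
#' with provenance.
#'
#' @slot coords n x 2 matrix of (x, y) pixel positions.
#' @slot source "algorithm" or "observer".
#' @slot observerId observer label (NA for algorithm output).
#' @slot repeatIdx repeat number (NA when not applicable).
#' @export
setClass("CellSet", representation(
  coords = "matrix", source = "character", observerId = "character",
  repeatIdx = "numeric"
))

setValidity("CellSet", function(object) {
  if (ncol(object@coords) != 2) return("coords must be an n x 2 matrix")
  if (!object@source %in% c("algorithm", "observer"))
    return("source must be 'algorithm' or 'observer'")
  TRUE
})

#' @rdname CellSet-class
#' @param coords,source,observerId,repeatIdx see slots.
#' @export
CellSet <- function(coords, source = "algorithm", observerId = NA_character_,
                    repeatIdx = NA_real_) {
  coords <- matrix(as.numeric(coords), ncol = 2,
                   dimnames = list(NULL, c("x_px", "y_px")))
  new("CellSet", coords = coords, source = source, observerId = observerId,
      repeatIdx = repeatIdx)
}

## ---------------------------------------------------------------------------
## Generics, accessors, show methods
## ---------------------------------------------------------------------------

#' @rdname ConeMosaic-class
#' @param object a ConeMosaic.
#' @export
setGeneric("mosaicPoints", function(object) standardGeneric("mosaicPoints"))
#' @rdname ConeMosaic-class
#' @export
setMethod("mosaicPoints", "ConeMosaic", function(object) object@points)

#' @rdname ConeMosaic-class
#' @export
setGeneric("trueDensity", function(object) standardGeneric("trueDensity"))
#' @rdname ConeMosaic-class
#' @export
setMethod("trueDensity", "ConeMosaic", function(object) object@trueDensityDeg2)

#' @rdname ROIImage-class
#' @param object a ROIImage.
#' @export
setGeneric("imagePixels", function(object) standardGeneric("imagePixels"))
#' @rdname ROIImage-class
#' @export
setMethod("imagePixels", "ROIImage", function(object) object@pixels)

#' @rdname ROIImage-class
#' @export
setGeneric("imageScale", function(object) standardGeneric("imageScale"))
#' @rdname ROIImage-class
#' @export
setMethod("imageScale", "ROIImage", function(object) object@scalePxPerDeg)

#' @rdname CellSet-class
#' @param object a CellSet.
#' @export
setGeneric("cellCoords", function(object) standardGeneric("cellCoords"))
#' @rdname CellSet-class
#' @export
setMethod("cellCoords", "CellSet", function(object) object@coords)

#' @rdname CellSet-class
#' @export
setGeneric("nCells", function(object) standardGeneric("nCells"))
#' @rdname CellSet-class
#' @export
setMethod("nCells", "CellSet", function(object) nrow(object@coords))
#' @rdname ConeMosaic-class
#' @export
setMethod("nCells", "ConeMosaic", function(object) nrow(object@points))

setMethod("show", "ConeMosaic", function(object) {
  cat(sprintf("ConeMosaic: %d cells in a %.2f x %.2f deg ROI (true density %.1f cells/deg^2)\n",
              nrow(object@points), object@spec@roiSizeDeg,
              object@spec@roiSizeDeg, object@trueDensityDeg2))
})

setMethod("show", "ROIImage", function(object) {
  cat(sprintf("ROIImage '%s': %d x %d px, %.0f px/deg, %d-bit",
              object@imageId, nrow(object@pixels), ncol(object@pixels),
              object@scalePxPerDeg, as.integer(object@bitDepth)))
  if (!is.na(object@eccentricityDeg))
    cat(sprintf(", eccentricity %+.1f deg", object@eccentricityDeg))
  if (nrow(object@truthPx)) cat(sprintf(", %d ground-truth cells", nrow(object@truthPx)))
  cat("\n")
})

setMethod("show", "CellSet", function(object) {
  cat(sprintf("CellSet: %d cells (source: %s%s)\n", nrow(object@coords),
              object@source,
              if (!is.na(object@observerId)) paste0(", ", object@observerId) else ""))
})

setMethod("show", "MosaicSpec", function(object) {
  cat(sprintf("MosaicSpec: %.2f deg ROI at %.0f px/deg, density %.1f cells/deg^2, jitter %.2f, seed %d\n",
              object@roiSizeDeg, object@scalePxPerDeg, object@densityDeg2,
              object@jitterFraction, as.integer(object@seed)))
})
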