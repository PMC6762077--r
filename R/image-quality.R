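#' Radially averaged power spectrum
#'
#' Mean-subtracts and Hann-windows the image (cropped centrally to a square if
#' needed), computes the 2-D FFT power, and averages it over one-pixel-wide
#' annuli of radial frequency. Frequencies are in cycles/pixel.
#'
#' @param mat numeric matrix.
#' @return data.frame with \code{freq}, \code{power} (annular mean) and
#'   \code{n} (pixels per annulus), DC bin included as freq 0.
#' @export
radialPowerSpectrum <- function(mat) {
  stopifnot(is.matrix(mat), min(dim(mat)) >= 2)
  N <- min(dim(mat))
  if (!all(dim(mat) == N)) {  # central square crop
    r0 <- floor((nrow(mat) - N) / 2)
    c0 <- floor((ncol(mat) - N) / 2)
    mat <- mat[r0 + seq_len(N), c0 + seq_len(N)]
  }
  h <- 0.5 * (1 - cos(2 * pi * (seq_len(N) - 1) / (N - 1)))  # Hann
  w <- outer(h, h)
  p <- Mod(stats::fft((mat - mean(mat)) * w))^2
  fr <- c(0:(floor(N / 2)), -((ceiling(N / 2) - 1):1)) / N
  rad <- sqrt(outer(fr^2, fr^2, "+"))
  bin <- round(rad * N)
  mp <- tapply(as.vector(p), as.vector(bin), mean)
  cnt <- tapply(as.vector(p), as.vector(bin), length)
  k <- as.integer(names(mp))
  data.frame(freq = k / N, power = as.numeric(mp), n = as.integer(cnt))
}

#' Image-quality metrics for one ROI
#'
#' The four quality measures used to characterize split-detection ROI sets:
#' \itemize{
#'   \item \emph{focus score} — normalized intensity variance Var(I)/Mean(I),
#'     an autofocus-style blur measure;
#'   \item \emph{power log-log slope} — OLS slope of log10 radially averaged
#'     power on log10 radial frequency over (2/edge, 0.8 x Nyquist]; blurrier
#'     images lose high-frequency power and slope more steeply negative;
#'   \item \emph{std intensity} — SD of pixel intensities;
#'   \item \emph{MAD intensity} — raw median absolute deviation (no 1.4826
#'     consistency factor).
#' }
#' Intensities are expected in [0, 1] (as stored by \code{\link{ROIImage}}), so
#' the metrics are bit-depth independent.
#'
#' @param image a \code{\link{ROIImage}} or numeric matrix in [0, 1].
#' @return list with \code{focusScore, powerLogLogSlope, stdIntensity,
#'   madIntensity, imageId, undefinedSlope}.
#' @export
#' @examples
#' img <- renderSplitDetection(generatePointPattern(MosaicSpec(densityDeg2 = 500)))
#' measureImageQuality(img)$focusScore
measureImageQuality <- function(image) {
  id <- NA_character_
  if (is(image, "ROIImage")) {
    id <- image@imageId
    px <- imagePixels(image)
  } else px <- image
  stopifnot(is.matrix(px), length(px) > 0)
  v <- as.vector(px)
  focus <- if (mean(v) == 0) 0 else stats::var(v) / mean(v)
  stdI <- stats::sd(v)
  madI <- stats::median(abs(v - stats::median(v)))
  slope <- NA_real_
  undef <- TRUE
  if (stats::var(v) > 0) {
    rp <- radialPowerSpectrum(px)
    N <- min(dim(px))
    sel <- rp$freq > 2 / N & rp$freq <= 0.4 & rp$power > 0
    if (sum(sel) >= 3) {
      fit <- stats::lm(log10(power) ~ log10(freq), data = rp[sel, ])
      slope <- unname(stats::coef(fit)[2])
      undef <- FALSE
    }
  }
  list(focusScore = focus, powerLogLogSlope = slope, stdIntensity = stdI,
       madIntensity = madI, imageId = id, undefinedSlope = undef)
}
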