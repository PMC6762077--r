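## Readers and writers for the package's artifact formats, plus the pipeline
## driver. All tables are UTF-8 CSV with a header row; images are single
## channel 8/16-bit TIFF or PNG with a JSON sidecar manifest carrying the
## scale and acquisition metadata.

#' Write an ROI image with its manifest
#'
#' Writes the normalized pixel grid as 8- or 16-bit grayscale TIFF or PNG
#' (chosen by the file extension) and the metadata (scale, eccentricity, eye,
#' animal, state, image id, bit depth) to a JSON sidecar.
#'
#' @param image a \code{\link{ROIImage}}.
#' @param path output path ending in .tif/.tiff or .png.
#' @param manifestPath sidecar path (default \code{paste0(path, ".json")}).
#' @return \code{path}, invisibly.
#' @export
writeROIImage <- function(image, path, manifestPath = paste0(path, ".json")) {
  stopifnot(is(image, "ROIImage"))
  ext <- tolower(tools::file_ext(path))
  px <- imagePixels(image)
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(px, path, bits.per.sample = as.integer(image@bitDepth))
  } else if (ext == "png") {
    png::writePNG(px, path)
  } else stop("unsupported image format: .", ext)
  meta <- list(scale_px_per_deg = image@scalePxPerDeg,
               eccentricity_deg = image@eccentricityDeg,
               eye = image@eye, animal_id = image@animalId,
               state = image@state, image_id = image@imageId,
               bit_depth = image@bitDepth)
  jsonlite::write_json(meta, manifestPath, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Read an ROI image and its manifest
#'
#' @param path image path (.tif/.tiff/.png, single channel, 8 or 16 bit).
#' @param manifestPath JSON sidecar with at least \code{scale_px_per_deg}.
#' @return a \code{\link{ROIImage}} (16-bit data read without precision loss).
#' @export
readROIImage <- function(path, manifestPath = paste0(path, ".json")) {
  ext <- tolower(tools::file_ext(path))
  px <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
        else if (ext == "png") png::readPNG(path)
        else stop("unsupported image format: .", ext)
  if (length(dim(px)) == 3) {
    if (dim(px)[3] > 1) stop("multi-channel image not supported: ", path)
    px <- px[, , 1]
  }
  if (!file.exists(manifestPath)) stop("manifest not found: ", manifestPath)
  meta <- jsonlite::read_json(manifestPath)
  if (is.null(meta$scale_px_per_deg))
    stop("manifest missing required field: scale_px_per_deg")
  asChr <- function(x) if (is.null(x)) NA_character_ else as.character(x)
  asNum <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  ROIImage(pixels = px, scalePxPerDeg = as.numeric(meta$scale_px_per_deg),
           eccentricityDeg = asNum(meta$eccentricity_deg),
           eye = asChr(meta$eye), animalId = asChr(meta$animal_id),
           state = asChr(meta$state),
           imageId = if (is.null(meta$image_id)) "roi" else as.character(meta$image_id),
           bitDepth = if (is.null(meta$bit_depth)) 8 else as.numeric(meta$bit_depth))
}

#' Write / read cell coordinate CSV
#'
#' Columns: \code{x_px, y_px, source, observer_id, repeat}.
#'
#' @param cells a \code{\link{CellSet}}.
#' @param path CSV path.
#' @return \code{path} invisibly (write); a \code{CellSet} (read).
#' @export
writeCellSet <- function(cells, path) {
  stopifnot(is(cells, "CellSet"))
  xy <- cellCoords(cells)
  df <- data.frame(x_px = xy[, 1], y_px = xy[, 2], source = cells@source,
                   observer_id = cells@observerId, "repeat" = cells@repeatIdx,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCellSet
#' @export
readCellSet <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("x_px", "y_px", "source")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  CellSet(cbind(df$x_px, df$y_px), source = df$source[1],
          observerId = if ("observer_id" %in% names(df))
            as.character(df$observer_id[1]) else NA_character_,
          repeatIdx = if ("repeat" %in% names(df))
            as.numeric(df[["repeat"]][1]) else NA_real_)
}

#' Write / read a correction list CSV
#'
#' Columns: \code{op, x_px, y_px, new_x_px, new_y_px} with
#' \code{op} in add/remove/shift.
#'
#' @param corrections correction data.frame.
#' @param path CSV path.
#' @export
writeCorrections <- function(corrections, path) {
  utils::write.csv(corrections, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCorrections
#' @export
readCorrections <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("op", "x_px", "y_px", "new_x_px", "new_y_px")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$op), c("add", "remove", "shift"))
  if (length(bad)) stop("unknown op(s): ", paste(bad, collapse = ", "))
  df
}

#' Write / read a long-format measurement table
#'
#' The canonical layout is \code{image_id, observer_id, repeat, density_deg2}.
#' \code{columnMap} renames foreign headers on read (a named character vector,
#' \code{c(canonical = "foreign")}), which accommodates exported observer
#' spreadsheets without hard-coding their layout. Duplicate
#' (image, observer, repeat) keys and non-numeric densities are rejected with
#' row-addressed errors.
#'
#' @param table repeated-measures data.frame.
#' @param path CSV path.
#' @param columnMap optional named character vector mapping canonical names to
#'   the file's headers.
#' @return \code{path} invisibly (write); validated data.frame (read).
#' @export
writeMeasurementTable <- function(table, path) {
  checkRepeatedMeasures(table)
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMeasurementTable
#' @export
readMeasurementTable <- function(path, columnMap = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!is.null(columnMap)) {
    for (canon in names(columnMap)) {
      i <- match(columnMap[[canon]], names(df))
      if (is.na(i)) stop("columnMap: no column named '", columnMap[[canon]], "'")
      names(df)[i] <- canon
    }
  }
  need <- c("image_id", "observer_id", "repeat", "density_deg2")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  dens <- suppressWarnings(as.numeric(df$density_deg2))
  bad <- which(is.na(dens) & !is.na(df$density_deg2))
  if (length(bad))
    stop("non-numeric density_deg2 at row(s): ", paste(bad, collapse = ", "))
  df$density_deg2 <- dens
  key <- paste(df$image_id, df$observer_id, df[["repeat"]], sep = "|")
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicate (image, observer, repeat) key(s): ",
         paste(unique(key[dup]), collapse = "; "))
  df[need]
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file of nested configuration blocks (see
#'   \code{\link{runPipeline}}).
#' @return a nested list.
#' @export
readPipelineConfig <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Run the full synthetic pipeline
#'
#' Chains simulate -> render -> detect -> correct -> density -> statistics on
#' synthetic data and writes per-stage CSVs plus a JSON metrics summary. The
#' config is a nested list with optional blocks \code{mosaics} (nImages,
#' densityRange, blurMax, nObservers), \code{table} (arguments of
#' \code{\link{MeasurementTableSpec}}) and \code{eyes} (arguments of
#' \code{\link{EyePairSpec}}); omitted values fall back to the package
#' defaults. Every output records the seed, and the summary JSON is
#' byte-identical across re-runs with the same config and seed.
#'
#' @param config nested list or path to a JSON config.
#' @param outDir output directory (created if needed).
#' @param seed master seed; per-stage seeds are derived from it.
#' @return the summary list, invisibly; files are written under \code{outDir}.
#' @export
runPipeline <- function(config = list(), outDir, seed = 1L) {
  if (is.character(config)) config <- readPipelineConfig(config)
  stopifnot(is.list(config))
  cm <- config$mosaics; ct <- config$table; ce <- config$eyes
  getOr <- function(x, nm, def) if (!is.null(x[[nm]])) x[[nm]] else def

  nObsCfg <- getOr(ct, "nObservers", 5)
  if (nObsCfg < 1) stop("config error: table.nObservers must be >= 1")
  nImgCfg <- getOr(ct, "nImages", 214)
  if (nImgCfg < 1) stop("config error: table.nImages must be >= 1")

  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)

  ## ---- stage 1: mosaics (simulate -> render -> detect -> correct -> density)
  nMosaic <- getOr(cm, "nImages", 6)
  densRange <- getOr(cm, "densityRange", c(300, 820))
  blurMax <- getOr(cm, "blurMax", 2)
  nObsMosaic <- getOr(cm, "nObservers", 2)
  mosaicRows <- list()
  withSeed(seed + 1L, {
    dens <- stats::runif(nMosaic, densRange[1], densRange[2])
    blurs <- stats::runif(nMosaic, 0, blurMax)
  })
  for (i in seq_len(nMosaic)) {
    mspec <- MosaicSpec(densityDeg2 = dens[i], seed = seed + 100L + i)
    mosaic <- generatePointPattern(mspec)
    img <- renderSplitDetection(mosaic,
                                RenderSpec(blurSigmaPx = blurs[i]),
                                seed = seed + 200L + i,
                                imageId = sprintf("sim%02d", i))
    sPx <- latticeSpacing(mosaic@trueDensityDeg2) * mspec@scalePxPerDeg
    det <- detectCells(img, detectionParams(spacingPx = sPx))
    q <- measureImageQuality(img)
    for (o in seq_len(nObsMosaic)) {
      corr <- simulateObserverCorrections(
        mosaic, det, ObserverModel(seed = seed + 1000L + i * 10L + o))
      corrected <- applyCorrections(det, corr, sPx,
                                    observerId = sprintf("obs%d", o))
      dres <- voronoiDensity(corrected, mspec@roiSizeDeg, mspec@scalePxPerDeg,
                             imageId = img@imageId)
      mosaicRows[[length(mosaicRows) + 1L]] <- data.frame(
        image_id = img@imageId, observer_id = sprintf("obs%d", o),
        true_density_deg2 = trueDensity(mosaic),
        density_deg2 = dres$densityDeg2, n_bound = dres$nBound,
        blur_sigma_px = blurs[i], focus_score = q$focusScore,
        power_loglog_slope = q$powerLogLogSlope,
        std_intensity = q$stdIntensity, mad_intensity = q$madIntensity)
    }
  }
  mosaicTab <- do.call(rbind, mosaicRows)
  utils::write.csv(mosaicTab, file.path(outDir, "mosaic_densities.csv"),
                   row.names = FALSE)

  ## ---- stage 2: measurement table and reliability statistics
  tspec <- MeasurementTableSpec(
    nImages = nImgCfg, nObservers = nObsCfg,
    nRepeats = getOr(ct, "nRepeats", 3),
    imageMeanRange = getOr(ct, "imageMeanRange", c(166, 885)),
    observerBiasSD = getOr(ct, "observerBiasSD", 5),
    withinSD = getOr(ct, "withinSD", c(3.40, 4.87, 4.78, 9.28, 3.83)),
    seed = seed + 2L)
  tab <- simulateMeasurementTable(tspec)
  writeMeasurementTable(tab, file.path(outDir, "measurements.csv"))
  study <- analyzeObserverStudy(tab)
  utils::write.csv(study$repeatability,
                   file.path(outDir, "repeatability.csv"), row.names = FALSE)

  ## ---- stage 3: fellow eyes and Bland-Altman agreement
  espec <- EyePairSpec(
    nAnimals = getOr(ce, "nAnimals", 5),
    locationsDeg = getOr(ce, "locationsDeg", seq(-9, 19, by = 2)),
    animalScaleSD = getOr(ce, "animalScaleSD", 0.12),
    interocularLogSD = getOr(ce, "interocularLogSD", 0.06),
    seed = seed + 3L)
  pairs <- simulateEyePairs(espec)
  utils::write.csv(pairs, file.path(outDir, "eye_pairs.csv"), row.names = FALSE)
  baD <- blandAltmanDifference(pairs)
  baR <- blandAltmanRatio(pairs)
  prof <- buildDensityProfile(data.frame(
    animal_id = rep(pairs$animal_id, 2),
    eccentricity_deg = rep(pairs$eccentricity_deg, 2),
    density_deg2 = c(pairs$od_density_deg2, pairs$os_density_deg2)))
  utils::write.csv(prof, file.path(outDir, "density_profile.csv"),
                   row.names = FALSE)

  ## ---- summary (deterministic given config + seed)
  configPath <- file.path(outDir, "config.json")
  jsonlite::write_json(config, configPath, auto_unbox = TRUE, digits = NA,
                       na = "null")
  summary <- list(
    seed = seed,
    config_md5 = unname(tools::md5sum(configPath)),
    mosaics = list(
      n_images = nMosaic,
      mean_abs_density_error_pct = mean(
        abs(mosaicTab$density_deg2 - mosaicTab$true_density_deg2) /
          mosaicTab$true_density_deg2, na.rm = TRUE) * 100),
    repeatability = study$repeatability,
    friedman = if (!is.null(study$interobserver)) list(
      chi2 = study$interobserver$friedmanChi2,
      p = study$interobserver$friedmanP,
      significant_pairs = sum(study$interobserver$pairwise$significant)),
    sd_vs_mean = study$sdVsMean[c("slope", "p")],
    bland_altman = list(
      difference = baD[c("bias", "loaLow", "loaHigh", "pearsonR", "pearsonP")],
      ratio = baR[c("bias", "loaLow", "loaHigh", "geoBias", "geoLoaLow",
                    "geoLoaHigh")]),
    profile_peak_deg = as.list(attr(prof, "peakEccentricityDeg")))
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = I(10), na = "null",
                       pretty = TRUE)
  writeLines(c(sprintf("seed: %d", seed),
               sprintf("config_md5: %s", summary$config_md5),
               sprintf("R: %s", R.version.string)),
             file.path(outDir, "pipeline_log.txt"))
  invisible(summary)
}
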