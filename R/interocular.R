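#' Pair fellow-eye measurements
#'
#' Averages density over observers and repeats per (animal, eccentricity, eye)
#' and inner-joins OD with OS on (animal, eccentricity). Unpaired locations
#' are dropped and counted.
#'
#' @param measurements data.frame with columns \code{animal_id,
#'   eccentricity_deg, eye, density_deg2} (extra columns such as observer or
#'   repeat are averaged over).
#' @return data.frame \code{animal_id, eccentricity_deg, od_density_deg2,
#'   os_density_deg2}; \code{attr(, "nDropped")} counts unpaired locations.
#' @export
pairEyes <- function(measurements) {
  need <- c("animal_id", "eccentricity_deg", "eye", "density_deg2")
  stopifnot(all(need %in% names(measurements)))
  stopifnot(all(measurements$eye %in% c("OD", "OS")))
  key <- interaction(measurements$animal_id, measurements$eccentricity_deg,
                     measurements$eye, drop = TRUE)
  agg <- data.frame(
    animal_id = tapply(as.character(measurements$animal_id), key, `[`, 1),
    eccentricity_deg = tapply(measurements$eccentricity_deg, key, `[`, 1),
    eye = tapply(as.character(measurements$eye), key, `[`, 1),
    density_deg2 = tapply(measurements$density_deg2, key, mean))
  od <- agg[agg$eye == "OD", c("animal_id", "eccentricity_deg", "density_deg2")]
  os <- agg[agg$eye == "OS", c("animal_id", "eccentricity_deg", "density_deg2")]
  names(od)[3] <- "od_density_deg2"
  names(os)[3] <- "os_density_deg2"
  pairs <- merge(od, os, by = c("animal_id", "eccentricity_deg"))
  if (!nrow(pairs)) stop("zero fellow-eye pairs after joining OD and OS")
  pairs <- pairs[order(pairs$animal_id, pairs$eccentricity_deg), ]
  rownames(pairs) <- NULL
  attr(pairs, "nDropped") <- (nrow(od) - nrow(pairs)) + (nrow(os) - nrow(pairs))
  pairs
}

baCore <- function(v, mean2, n) {
  bias <- mean(v); s <- stats::sd(v)
  tq <- stats::qt(0.975, n - 1)
  seBias <- s / sqrt(n)
  seLoa <- s * sqrt(3 / n)  # Bland & Altman (1999) approximation
  pr <- if (stats::var(mean2) == 0 || s == 0)
    list(estimate = NA_real_, p.value = NA_real_)
  else stats::cor.test(v, mean2)
  list(bias = bias, sd = s,
       loaLow = bias - 1.96 * s, loaHigh = bias + 1.96 * s,
       ciBias = c(bias - tq * seBias, bias + tq * seBias),
       ciLoaLow = c(bias - 1.96 * s - tq * seLoa, bias - 1.96 * s + tq * seLoa),
       ciLoaHigh = c(bias + 1.96 * s - tq * seLoa, bias + 1.96 * s + tq * seLoa),
       pearsonR = unname(pr$estimate), pearsonP = pr$p.value, nPairs = n)
}

#' Bland-Altman agreement between fellow eyes, difference form
#'
#' Differences d = OD - OS: bias = mean(d), limits of agreement bias +/- 1.96
#' SD(d), t-based CI of the bias, Bland-Altman (1999) approximate CIs of the
#' limits (SE = SD sqrt(3/n)), and the Pearson proportional-bias correlation of
#' d against the pair mean (OD + OS)/2.
#'
#' @param pairs data.frame from \code{\link{pairEyes}} or
#'   \code{\link{simulateEyePairs}}.
#' @return list with \code{mode, bias, sd, loaLow, loaHigh, ciBias, ciLoaLow,
#'   ciLoaHigh, pearsonR, pearsonP, nPairs}.
#' @export
blandAltmanDifference <- function(pairs) {
  n <- nrow(pairs)
  if (n < 3) stop("need at least 3 pairs")
  d <- pairs$od_density_deg2 - pairs$os_density_deg2
  m <- (pairs$od_density_deg2 + pairs$os_density_deg2) / 2
  c(list(mode = "difference"), baCore(d, m, n))
}

#' Bland-Altman agreement between fellow eyes, ratio form
#'
#' Ratios r = OD/OS (equivalent, up to the log transform, to differencing
#' log densities): bias = mean(r), limits of agreement bias +/- 1.96 SD(r),
#' plotted against the pair means. The geometric (log-scale, back-transformed)
#' variant exp(mean(log r) +/- 1.96 SD(log r)) is reported alongside.
#'
#' @param pairs as in \code{\link{blandAltmanDifference}}; all densities must
#'   be positive.
#' @return list as for the difference form plus \code{geoBias, geoLoaLow,
#'   geoLoaHigh}.
#' @export
blandAltmanRatio <- function(pairs) {
  n <- nrow(pairs)
  if (n < 3) stop("need at least 3 pairs")
  if (any(pairs$od_density_deg2 <= 0 | pairs$os_density_deg2 <= 0))
    stop("ratio mode requires positive densities")
  r <- pairs$od_density_deg2 / pairs$os_density_deg2
  m <- (pairs$od_density_deg2 + pairs$os_density_deg2) / 2
  out <- c(list(mode = "ratio"), baCore(r, m, n))
  lr <- log(r)
  out$geoBias <- exp(mean(lr))
  out$geoLoaLow <- exp(mean(lr) - 1.96 * stats::sd(lr))
  out$geoLoaHigh <- exp(mean(lr) + 1.96 * stats::sd(lr))
  out
}
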