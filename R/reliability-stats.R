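## Repeated-measures tables are plain long-format data.frames with columns
## image_id, observer_id, repeat, density_deg2 (see readMeasurementTable).

checkRepeatedMeasures <- function(table) {
  need <- c("image_id", "observer_id", "repeat", "density_deg2")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!is.numeric(table$density_deg2)) stop("density_deg2 must be numeric")
  invisible(table)
}

## Per-image repeat matrix (images x repeats) for one observer.
observerMatrix <- function(table, observerId) {
  checkRepeatedMeasures(table)
  d <- table[table$observer_id == observerId, ]
  if (!nrow(d)) stop("no rows for observer ", observerId)
  counts <- table(d$image_id)
  bad <- names(counts)[counts < 2]
  if (length(bad))
    stop("image(s) with fewer than 2 repeats: ", paste(bad, collapse = ", "))
  if (length(unique(counts)) != 1)
    stop("unequal repeat counts across images for observer ", observerId)
  d <- d[order(d$image_id, d[["repeat"]]), ]
  matrix(d$density_deg2, nrow = length(counts), byrow = TRUE,
         dimnames = list(names(counts), NULL))
}

#' Within-observer (within-subject) standard deviation
#'
#' Sw is the square root of the mean per-image variance over an observer's m
#' repeated measurements — the residual (within) root mean square of the
#' one-way ANOVA on images. The confidence interval uses the large-sample
#' multipliers \eqn{1 \pm 1.96/\sqrt{2n(m-1)}}.
#'
#' @param table long-format repeated measures (image_id, observer_id, repeat,
#'   density_deg2).
#' @param observerId which observer to analyse (NULL pools all rows as one
#'   observer — only sensible if the table holds a single observer).
#' @return list with \code{sw, ciLow, ciHigh, nImages, mRepeats, grandMean}.
#' @export
#' @examples
#' tab <- data.frame(image_id = rep(c("a", "b"), each = 3),
#'                   observer_id = "obs1", "repeat" = rep(1:3, 2),
#'                   density_deg2 = c(100, 102, 104, 200, 201, 202),
#'                   check.names = FALSE)
#' withinSubjectSD(tab, "obs1")$sw  # sqrt((4 + 1)/2) = 1.5811
withinSubjectSD <- function(table, observerId = NULL) {
  if (is.null(observerId)) {
    obs <- unique(table$observer_id)
    if (length(obs) != 1) stop("observerId required for multi-observer tables")
    observerId <- obs
  }
  m <- observerMatrix(table, observerId)
  vars <- apply(m, 1, stats::var)
  sw <- sqrt(mean(vars))
  n <- nrow(m); mm <- ncol(m)
  h <- 1.96 / sqrt(2 * n * (mm - 1))
  list(sw = sw, ciLow = sw * (1 - h), ciHigh = sw * (1 + h),
       nImages = n, mRepeats = mm, grandMean = mean(m))
}

#' Repeatability coefficient and measurement error from Sw
#'
#' The repeatability coefficient RC = 2.77 Sw bounds the absolute difference
#' between two measurements by the same observer for 95\% of paired
#' observations; the measurement error ME = 1.96 Sw bounds the deviation of a
#' single measurement from the true value for 95\% of observations. RC is also
#' reported as a percentage of the grand mean density.
#'
#' @param sw within-subject SD.
#' @param grandMean grand mean density (for the percent-of-mean form).
#' @param n number of images; \code{m} repeats per image (for the CI).
#' @param m repeats per image.
#' @return list with \code{sw, repeatabilityCoefficient, measurementError,
#'   percentOfMean, ciLow, ciHigh}.
#' @export
repeatabilityMetrics <- function(sw, grandMean, n, m) {
  stopifnot(sw >= 0, grandMean > 0, n >= 1, m >= 2)
  rc <- 2.77 * sw
  h <- 1.96 / sqrt(2 * n * (m - 1))
  list(sw = sw, repeatabilityCoefficient = rc, measurementError = 1.96 * sw,
       percentOfMean = rc / grandMean * 100,
       ciLow = rc * (1 - h), ciHigh = rc * (1 + h))
}

#' One-way random-effects intraclass correlation (single measure)
#'
#' Treats an observer's m repeats as interchangeable readings of each image:
#' ICC(1,1) = (BMS - WMS) / (BMS + (m - 1) WMS) from the one-way ANOVA on
#' images, with the F-based 95\% confidence interval.
#'
#' @inheritParams withinSubjectSD
#' @return list with \code{icc, ciLow, ciHigh, model, undefined}.
#' @export
iccOneWay <- function(table, observerId = NULL) {
  if (is.null(observerId)) {
    obs <- unique(table$observer_id)
    if (length(obs) != 1) stop("observerId required for multi-observer tables")
    observerId <- obs
  }
  mat <- observerMatrix(table, observerId)
  n <- nrow(mat); m <- ncol(mat)
  wms <- mean(apply(mat, 1, stats::var))
  bms <- m * stats::var(rowMeans(mat))
  if (bms == 0 && wms == 0)
    return(list(icc = NA_real_, ciLow = NA_real_, ciHigh = NA_real_,
                model = "oneway", undefined = TRUE))
  icc <- (bms - wms) / (bms + (m - 1) * wms)
  if (wms == 0) {
    ciLow <- ciHigh <- 1
  } else {
    fobs <- bms / wms
    fl <- fobs / stats::qf(0.975, n - 1, n * (m - 1))
    fu <- fobs * stats::qf(0.975, n * (m - 1), n - 1)
    ciLow <- (fl - 1) / (fl + m - 1)
    ciHigh <- (fu - 1) / (fu + m - 1)
  }
  list(icc = icc, ciLow = ciLow, ciHigh = ciHigh, model = "oneway",
       undefined = FALSE)
}

#' Per-observer repeatability summary
#'
#' Computes, for each observer in a repeated-measures table: the range of
#' per-image means, Sw, the repeatability coefficient with CI, the measurement
#' error, RC as percent of the observer's grand mean, and the one-way ICC with
#' CI.
#'
#' @param table long-format repeated measures.
#' @return data.frame, one row per observer.
#' @export
observerRepeatability <- function(table) {
  checkRepeatedMeasures(table)
  obs <- sort(unique(table$observer_id))
  rows <- lapply(obs, function(o) {
    sw <- withinSubjectSD(table, o)
    rm_ <- repeatabilityMetrics(sw$sw, sw$grandMean, sw$nImages, sw$mRepeats)
    icc <- iccOneWay(table, o)
    mat <- observerMatrix(table, o)
    means <- rowMeans(mat)
    data.frame(observer_id = o, n_images = sw$nImages, m_repeats = sw$mRepeats,
               mean_low = min(means), mean_high = max(means),
               sw = sw$sw, rc = rm_$repeatabilityCoefficient,
               rc_ci_low = rm_$ciLow, rc_ci_high = rm_$ciHigh,
               me = rm_$measurementError, percent_of_mean = rm_$percentOfMean,
               icc = icc$icc, icc_ci_low = icc$ciLow, icc_ci_high = icc$ciHigh)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## Tie-corrected Friedman chi-square from a blocks x treatments matrix.
friedmanStatistic <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  r <- t(apply(mat, 1, rank))
  Rj <- colSums(r)
  num <- (k - 1) * (sum(Rj^2) - n^2 * k * (k + 1)^2 / 4)
  den <- sum(r^2) - n * k * (k + 1)^2 / 4
  list(chi2 = if (den == 0) 0 else num / den, meanRanks = colMeans(r),
       df = k - 1, n = n, k = k)
}

#' Interobserver comparison: normality gate, Friedman test, Dunn post hoc
#'
#' Each observer's value per image is the mean of their repeats. Per-observer
#' Shapiro-Wilk p-values are reported as the normality gate; observers are
#' compared with the tie-corrected Friedman rank test (chi-square with k - 1
#' df), followed by Dunn's pairwise comparisons
#' \eqn{z = (\bar R_a - \bar R_b)/\sqrt{k(k+1)/(6n)}} with Bonferroni
#' adjustment over all k(k-1)/2 pairs.
#'
#' @param table long-format repeated measures with at least 3 observers and
#'   complete blocks (every image measured by every observer).
#' @param alpha significance level for flagging pairs.
#' @return list with \code{shapiroP} (named per observer),
#'   \code{friedmanChi2, friedmanDf, friedmanP}, \code{meanRanks}, and
#'   \code{pairwise} (data.frame obs_a, obs_b, dunn_z, p, adjusted_p,
#'   significant).
#' @export
compareObservers <- function(table, alpha = 0.05) {
  checkRepeatedMeasures(table)
  obs <- sort(unique(table$observer_id))
  if (length(obs) < 3) stop("need at least 3 observers")
  key <- interaction(table$image_id, table$observer_id, drop = FALSE)
  agg <- tapply(table$density_deg2, list(table$image_id, table$observer_id), mean)
  if (anyNA(agg)) {
    miss <- which(is.na(agg), arr.ind = TRUE)
    stop("incomplete blocks; missing (image, observer) cells: ",
         paste(sprintf("(%s, %s)", rownames(agg)[miss[, 1]],
                       colnames(agg)[miss[, 2]]), collapse = ", "))
  }
  mat <- agg[, obs, drop = FALSE]
  shap <- vapply(obs, function(o) {
    x <- mat[, o]
    if (stats::var(x) == 0) NA_real_ else stats::shapiro.test(x)$p.value
  }, numeric(1))
  fr <- friedmanStatistic(mat)
  p <- stats::pchisq(fr$chi2, fr$df, lower.tail = FALSE)
  pairs <- utils::combn(seq_along(obs), 2)
  se <- sqrt(fr$k * (fr$k + 1) / (6 * fr$n))
  z <- (fr$meanRanks[pairs[1, ]] - fr$meanRanks[pairs[2, ]]) / se
  praw <- 2 * stats::pnorm(-abs(z))
  padj <- pmin(1, praw * ncol(pairs))
  pw <- data.frame(obs_a = obs[pairs[1, ]], obs_b = obs[pairs[2, ]],
                   dunn_z = as.numeric(z), p = praw, adjusted_p = padj,
                   significant = padj < alpha)
  list(shapiroP = shap, friedmanChi2 = fr$chi2, friedmanDf = fr$df,
       friedmanP = p, meanRanks = stats::setNames(fr$meanRanks, obs),
       pairwise = pw, nImages = fr$n, nObservers = fr$k)
}

#' Spearman correlation of image quality with measurement variance
#'
#' @param quality numeric vector of an image-quality metric, one per image.
#' @param variance per-image variance of the density measurements.
#' @return list with \code{rho, p, n} (\code{undefined = TRUE} when either
#'   vector is constant).
#' @export
correlateQualityVariance <- function(quality, variance) {
  stopifnot(length(quality) == length(variance))
  if (length(quality) < 5) stop("need at least 5 images")
  if (stats::var(quality) == 0 || stats::var(variance) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = length(quality),
                undefined = TRUE))
  ct <- suppressWarnings(
    stats::cor.test(quality, variance, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(quality),
       undefined = FALSE)
}

#' Regression of per-image SD on per-image mean density
#'
#' Tests for density-dependent measurement variability: ordinary least squares
#' of each image's SD (over all observations from all observers) on its mean.
#'
#' @param table long-format repeated measures.
#' @return list with \code{slope, intercept, p, nImages}.
#' @export
regressSDOnMean <- function(table) {
  checkRepeatedMeasures(table)
  mns <- tapply(table$density_deg2, table$image_id, mean)
  sds <- tapply(table$density_deg2, table$image_id, stats::sd)
  if (length(mns) < 3) stop("need at least 3 images")
  if (stats::var(sds) == 0)
    return(list(slope = 0, intercept = unname(sds[1]), p = 1,
                nImages = length(mns)))
  fit <- stats::lm(sds ~ mns)
  sm <- suppressWarnings(summary(fit))
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       p = unname(sm$coefficients[2, 4]), nImages = length(mns))
}

#' Group comparisons of density per retinal location
#'
#' Two-way ANOVA of density on a grouping factor (e.g. sex or age class) and
#' retinal location, followed by per-location pairwise group comparisons using
#' the pooled residual error and Sidak family-wise adjustment
#' \eqn{p' = 1 - (1 - p)^m}.
#'
#' @param data data.frame with columns \code{animal_id, eccentricity_deg,
#'   density_deg2, group} (one density per animal per location; the group
#'   label is constant within animal).
#' @param alpha significance level.
#' @return list with \code{anova} (the aov summary table), \code{comparisons}
#'   (data.frame eccentricity_deg, group_a, group_b, difference, t, df, p,
#'   adjusted_p, significant, estimable) and \code{m} (family size).
#' @export
compareGroups <- function(data, alpha = 0.05) {
  need <- c("animal_id", "eccentricity_deg", "density_deg2", "group")
  stopifnot(all(need %in% names(data)))
  data$group <- factor(data$group)
  data$loc <- factor(data$eccentricity_deg)
  fit <- stats::aov(density_deg2 ~ group * loc, data = data)
  tab <- summary(fit)[[1]]
  mse <- tab["Residuals", "Mean Sq"]
  dfres <- tab["Residuals", "Df"]
  locs <- levels(data$loc)
  gl <- levels(data$group)
  pairs <- utils::combn(gl, 2, simplify = FALSE)
  rows <- list()
  for (lv in locs) for (pr in pairs) {
    a <- data$density_deg2[data$loc == lv & data$group == pr[1]]
    b <- data$density_deg2[data$loc == lv & data$group == pr[2]]
    est <- length(a) >= 2 && length(b) >= 2
    if (est) {
      diff <- mean(a) - mean(b)
      tstat <- diff / sqrt(mse * (1 / length(a) + 1 / length(b)))
      p <- 2 * stats::pt(-abs(tstat), dfres)
    } else {
      diff <- tstat <- p <- NA_real_
    }
    rows[[length(rows) + 1L]] <- data.frame(
      eccentricity_deg = as.numeric(lv), group_a = pr[1], group_b = pr[2],
      difference = diff, t = tstat, df = dfres, p = p, estimable = est)
  }
  cmp <- do.call(rbind, rows)
  m <- sum(cmp$estimable)
  cmp$adjusted_p <- ifelse(cmp$estimable, sidakAdjust(cmp$p, max(m, 1)), NA_real_)
  cmp$significant <- !is.na(cmp$adjusted_p) & cmp$adjusted_p < alpha
  list(anova = tab, comparisons = cmp, m = m)
}

#' Full observer-study analysis
#'
#' Convenience wrapper that runs the per-observer repeatability summary, the
#' interobserver comparison, and the SD-versus-mean regression on one
#' repeated-measures table — the deterministic analysis applied to an observer
#' measurement study once its table is loaded.
#'
#' @param table long-format repeated measures.
#' @return list with \code{repeatability} (data.frame),
#'   \code{interobserver} (see \code{\link{compareObservers}}) and
#'   \code{sdVsMean}.
#' @export
analyzeObserverStudy <- function(table) {
  rep_ <- observerRepeatability(table)
  inter <- if (length(unique(table$observer_id)) >= 3)
    compareObservers(table) else NULL
  list(repeatability = rep_, interobserver = inter,
       sdVsMean = regressSDOnMean(table))
}
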