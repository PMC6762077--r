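test_that("within-subject SD matches hand-computed variances", {
  tab <- makeTable(c(100, 102, 104, 200, 201, 202), c("a", "b"), "obs1", 1:3)
  sw <- withinSubjectSD(tab, "obs1")
  expect_equal(sw$sw, sqrt((4 + 1) / 2), tolerance = 1e-9)  # 1.5811
  expect_lte(sw$ciLow, sw$sw); expect_gte(sw$ciHigh, sw$sw)

  # identical repeats -> Sw = 0
  z <- makeTable(rep(c(100, 200), each = 3), c("a", "b"), "obs1", 1:3)
  expect_equal(withinSubjectSD(z, "obs1")$sw, 0)

  # an image with a single repeat is an error naming the image
  bad <- tab[-c(1, 2), ]
  expect_error(withinSubjectSD(bad, "obs1"), "fewer than 2 repeats.*a")
})

test_that("repeatability metrics keep the exact 2.77/1.96 structure", {
  r <- repeatabilityMetrics(sqrt(2.5), 150, 2, 3)
  expect_equal(r$repeatabilityCoefficient, 4.380, tolerance = 1e-3)
  expect_equal(r$measurementError, 3.099, tolerance = 1e-3)
  expect_equal(r$repeatabilityCoefficient / r$measurementError, 2.77 / 1.96)
  expect_equal(repeatabilityMetrics(0, 100, 10, 3)$repeatabilityCoefficient, 0)

  # ratio is exact for every simulated observer too
  tab <- simulateMeasurementTable(MeasurementTableSpec(nImages = 20, seed = 1))
  rep_ <- observerRepeatability(tab)
  expect_equal(rep_$rc / rep_$me, rep(2.77 / 1.96, 5))
})

test_that("RC estimates are unbiased for 2.77 sigma_w over repeated simulation", {
  sigw <- 5
  rcs <- vapply(1:200, function(sd) {
    tab <- simulateMeasurementTable(MeasurementTableSpec(
      nImages = 50, nObservers = 1, withinSD = sigw, seed = 1000 + sd))
    sw <- withinSubjectSD(tab, "obs1")
    repeatabilityMetrics(sw$sw, sw$grandMean, 50, 3)$repeatabilityCoefficient
  }, numeric(1))
  target <- 2.77 * sigw
  # Sw^2 ~ sigma^2 chi2_df/df, df = n(m-1); delta-method SE on 2.77 Sw
  se <- target / sqrt(2 * 50 * 2) / sqrt(200)
  expect_lt(abs(mean(rcs) - target), 3 * se)
})

test_that("one-way ICC recovers known variance components", {
  # identical repeats, varying images -> ICC = 1
  tab <- makeTable(rep(c(100, 200, 300), each = 3), c("a", "b", "c"), "o", 1:3)
  expect_equal(iccOneWay(tab, "o")$icc, 1)

  # between 100, within 1 -> ICC -> 100/101
  big <- simulateMeasurementTable(MeasurementTableSpec(
    nImages = 400, nObservers = 1, imageMeanRange = c(0, sqrt(12 * 100)),
    observerBiasSD = 0, withinSD = 1, seed = 9))
  ic <- iccOneWay(big, "obs1")
  expect_equal(ic$icc, 100 / 101, tolerance = 0.01)
  expect_lte(ic$ciLow, ic$icc); expect_gte(ic$ciHigh, ic$icc)

  # zero total variance is flagged undefined
  flat <- makeTable(rep(5, 9), c("a", "b", "c"), "o", 1:3)
  expect_true(iccOneWay(flat, "o")$undefined)
})

test_that("ICC confidence intervals achieve nominal coverage", {
  for (target in c(0.5, 0.9, 0.99)) {
    # between-variance = target/(1-target) x within-variance (unit within SD)
    sigB <- sqrt(target / (1 - target))
    cover <- vapply(1:200, function(sd) {
      set.seed(30000 + sd)
      n <- 30; m <- 3
      mu <- rnorm(n, 0, sigB)
      vals <- rep(mu, each = m) + rnorm(n * m)
      tab <- data.frame(image_id = sprintf("i%02d", rep(seq_len(n), each = m)),
                        observer_id = "o", rep = rep(seq_len(m), n),
                        density_deg2 = vals, check.names = FALSE)
      names(tab)[3] <- "repeat"
      ic <- iccOneWay(tab, "o")
      ic$ciLow <= target && target <= ic$ciHigh
    }, logical(1))
    # 95% nominal; binomial SE at n=200 is ~1.5%, allow 3 SE
    expect_gt(mean(cover), 0.95 - 3 * sqrt(0.95 * 0.05 / 200))
  }
})

test_that("Friedman statistic matches closed form, stats::friedman.test and a permutation oracle", {
  # strict rank order preserved on every image: chi2 = 8 for k=3, n=4
  t2 <- data.frame(image_id = rep(rep(paste0("i", 1:4), each = 3), 2),
                   observer_id = rep(paste0("obs", 1:3), 8),
                   rep = rep(1:2, each = 12),
                   density_deg2 = rep(c(1, 5, 9), 8) + rep(1:4, each = 3) / 10,
                   check.names = FALSE)
  names(t2)[3] <- "repeat"
  co <- compareObservers(t2)
  expect_equal(co$friedmanChi2, 8)
  expect_equal(co$friedmanP, pchisq(8, 2, lower.tail = FALSE))
  expect_identical(nrow(co$pairwise), 3L)  # k(k-1)/2

  # tie-corrected implementation agrees with stats::friedman.test (with and
  # without ties) on random matrices
  set.seed(4)
  for (i in 1:10) {
    m <- matrix(rnorm(15), 5, 3)
    if (i > 5) m <- round(m)  # force ties
    mine <- coneMosaic:::friedmanStatistic(m)$chi2
    ref <- unname(friedman.test(m)$statistic)
    expect_equal(mine, ref, tolerance = 1e-12)
  }

  # exact permutation oracle: every within-block rank assignment for n <= 5,
  # k = 3 gives the same statistic from the package as from first principles
  perms <- as.matrix(expand.grid(p = 1:6, q = 1:6, r = 1:6, s = 1:6, t = 1:6))
  allOrders <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                     c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  base <- c(10, 20, 30)
  agree <- vapply(seq_len(nrow(perms)), function(i) {
    mat <- t(vapply(perms[i, ], function(o) base[allOrders[o, ]], numeric(3)))
    isTRUE(all.equal(coneMosaic:::friedmanStatistic(mat)$chi2,
                     friedmanOracle(mat), tolerance = 1e-12))
  }, logical(1))
  expect_true(all(agree))
})

test_that("identical observers give a null Friedman result", {
  vals <- rep(rep(c(100, 200, 300, 400), each = 3), 3)
  tab <- data.frame(image_id = rep(paste0("i", 1:4), each = 9),
                    observer_id = rep(rep(paste0("o", 1:3), each = 3), 4),
                    rep = rep(1:3, 12),
                    density_deg2 = rep(c(100, 200, 300, 400), each = 9),
                    check.names = FALSE)
  names(tab)[3] <- "repeat"
  co <- compareObservers(tab)
  expect_equal(co$friedmanChi2, 0)
  expect_false(any(co$pairwise$significant))
})

test_that("observer comparison demands complete blocks and >= 3 observers", {
  tab <- simulateMeasurementTable(MeasurementTableSpec(nImages = 6, seed = 2))
  expect_error(compareObservers(tab[tab$observer_id %in% c("obs1", "obs2"), ]),
               "at least 3")
  holed <- tab[!(tab$image_id == "img001" & tab$observer_id == "obs3"), ]
  expect_error(compareObservers(holed), "incomplete blocks")
})

test_that("observer-bias-free tables yield near-nominal Friedman size", {
  rejections <- vapply(1:200, function(sd) {
    tab <- simulateMeasurementTable(MeasurementTableSpec(
      nImages = 20, nObservers = 3, observerBiasSD = 0, withinSD = 5,
      seed = 5000 + sd))
    compareObservers(tab)$friedmanP < 0.05
  }, logical(1))
  # alpha = 0.05; binomial 3 SE band at n=200 is +-4.6%
  expect_lt(abs(mean(rejections) - 0.05), 0.05)
})

test_that("statistics are invariant under image relabeling", {
  tab <- simulateMeasurementTable(MeasurementTableSpec(nImages = 15, seed = 6))
  relab <- tab
  ids <- unique(tab$image_id)
  relab$image_id <- setNames(sample(LETTERS, length(ids)), ids)[tab$image_id]
  expect_equal(withinSubjectSD(relab, "obs2")$sw,
               withinSubjectSD(tab, "obs2")$sw)
  expect_equal(iccOneWay(relab, "obs4")$icc, iccOneWay(tab, "obs4")$icc)
  expect_equal(compareObservers(relab)$friedmanChi2,
               compareObservers(tab)$friedmanChi2)
})

test_that("Spearman quality association behaves at the extremes", {
  q <- c(5, 4, 3, 2, 1, 0)
  v <- c(1, 2, 3, 4, 5, 6)
  r <- correlateQualityVariance(q, v)
  expect_equal(r$rho, -1)

  perm <- sample(6)
  r2 <- correlateQualityVariance(q[perm], v[perm])
  expect_equal(r2$rho, r$rho)

  expect_true(correlateQualityVariance(rep(1, 6), v)$undefined)

  # independent vectors: |rho| small for most seeds
  nulls <- vapply(1:100, function(sd) {
    set.seed(sd)
    abs(correlateQualityVariance(rnorm(214), rnorm(214))$rho)
  }, numeric(1))
  expect_gt(mean(nulls < 0.2), 0.9)  # null SE ~ 1/sqrt(213) ~ 0.069
})

test_that("SD-on-mean regression detects trends and their absence", {
  tab <- simulateMeasurementTable(MeasurementTableSpec(nImages = 30, seed = 3))
  # constant SD across images: slope 0, p = 1
  flat <- tab
  mns <- tapply(flat$density_deg2, flat$image_id, mean)
  flat$density_deg2 <- mns[flat$image_id] +
    rep(c(-1, 0, 1), length.out = nrow(flat))
  rFlat <- regressSDOnMean(flat)
  expect_equal(rFlat$slope, 0, tolerance = 1e-12)
  expect_equal(rFlat$p, 1)

  # SD exactly proportional to mean: slope recovered, p ~ 0
  prop <- tab
  prop$density_deg2 <- ave(prop$density_deg2, prop$image_id, FUN = function(x) {
    mean(x) + 0.01 * mean(x) * scale(seq_along(x))[, 1]
  })
  rProp <- regressSDOnMean(prop)
  expect_equal(rProp$slope, 0.01, tolerance = 1e-9)
  expect_lt(rProp$p, 1e-9)

  # homoscedastic tables: nominal type-I error for the slope test
  rejections <- vapply(1:200, function(sd) {
    t2 <- simulateMeasurementTable(MeasurementTableSpec(
      nImages = 25, nObservers = 2, withinSD = 5, seed = 7000 + sd))
    regressSDOnMean(t2)$p < 0.05
  }, logical(1))
  expect_lt(abs(mean(rejections) - 0.05), 0.05)
})

test_that("group comparisons flag only built-in differences, with Sidak", {
  expect_equal(sidakAdjust(0.03, 1), 0.03)  # m = 1 identity
  expect_equal(sidakAdjust(0.02, 5), 1 - (1 - 0.02)^5)

  locs <- seq(-9, 19, by = 2)
  makeGroups <- function(bump, seed) {
    set.seed(seed)
    rows <- expand.grid(animal = 1:8, loc = locs)
    rows$group <- ifelse(rows$animal <= 4, "A", "B")
    mu <- densityProfileDefault(rows$loc)
    mu[rows$group == "B" & rows$loc %in% c(9, 11, 13)] <-
      mu[rows$group == "B" & rows$loc %in% c(9, 11, 13)] * (1 + bump)
    data.frame(animal_id = paste0("a", rows$animal),
               eccentricity_deg = rows$loc, group = rows$group,
               density_deg2 = mu + rnorm(nrow(rows), 0, 15))
  }
  # identical group means: no significant comparisons
  null <- compareGroups(makeGroups(0, 1))
  expect_false(any(null$comparisons$significant))

  # +15% at three streak locations, n = 4/group: detected in most replicates
  hits <- vapply(1:50, function(sd) {
    cmp <- compareGroups(makeGroups(0.15, sd))$comparisons
    sum(cmp$significant & cmp$eccentricity_deg %in% c(9, 11, 13))
  }, numeric(1))
  expect_gt(mean(hits >= 2), 0.5)

  # a group with < 2 animals at a location is flagged not estimable
  d <- makeGroups(0, 2)
  d <- d[!(d$group == "B" & d$eccentricity_deg == 11 & d$animal_id != "a5"), ]
  cmp <- compareGroups(d)$comparisons
  expect_false(cmp$estimable[cmp$eccentricity_deg == 11])
})
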