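# Loss detection: reference median vs sort-based oracle, the quality-pixel
# rule, anomaly arithmetic, threshold semantics, epoch dating and the
# partition/monotonicity invariants.

test_that("reference median matches a sort-based oracle", {
  s <- sceneSeries(generateScene(quietSceneConfig(cloudFraction = 0.4)))
  ref <- buildReference(s, c("1998-01", "2001-12"), minQuality = 10)
  nd <- ndviSeries(s, c("1998-01", "2001-12"))
  withr::with_seed(9, cells <- sample(length(ref@medianNdvi), 50))
  for (cell in cells) {
    r <- (cell - 1) %% nrow(ref@medianNdvi) + 1
    c <- (cell - 1) %/% nrow(ref@medianNdvi) + 1
    obs <- nd[r, c, ]
    want <- if (sum(!is.na(obs)) < 10) NA_real_ else oracleMedian(obs)
    expect_equal(ref@medianNdvi[r, c], want, tolerance = 1e-12)
  }
  expect_true(all(is.na(ref@medianNdvi[ref@qualityCount < 10])))
})

test_that("pixels below the quality-observation rule are excluded", {
  s <- flipSeries(nDates = 16L)  # cloud-free: all 16 obs valid
  expect_true(all(!is.na(buildReference(s, c("2001-01", "2001-12"),
                                        minQuality = 10)@medianNdvi)))
  # only 9 acquisitions in the window -> below a minQuality of 10 everywhere
  ref9 <- buildReference(s, c("2001-01", "2001-09"), minQuality = 10)
  expect_true(all(is.na(ref9@medianNdvi)))
  expect_true(all(ref9@qualityCount == 9L))
  expect_error(buildReference(s, c("1980-01", "1980-12")), "no acquisition dates")
})

test_that("cumulative anomaly reproduces direct arithmetic", {
  # one pixel flips mangrove (NDVI 0.75) -> wet soil (0.15) at obs 9 of 16:
  # mean change = 8 * (-0.6) / 16 = -0.3, cumulative = -4.8
  s <- flipSeries(nDates = 16L, flipAt = 9L)
  ref <- buildReference(s, c("2001-01", "2001-12"), minQuality = 10)
  an <- cumulativeAnomaly(s, ref, c("2001-01", "2002-04"))
  expect_equal(meanChange(an)[10, 10], -0.3, tolerance = 1e-9)
  expect_equal(an@cumulative[10, 10], -4.8, tolerance = 1e-9)
  expect_equal(obsCount(an)[10, 10], 16L)
  # an unconverted pixel sees zero anomaly
  expect_equal(meanChange(an)[5, 5], 0, tolerance = 1e-12)
  # identity: mean change * count = cumulative everywhere
  resid <- meanChange(an) * obsCount(an) - an@cumulative
  expect_lt(max(abs(resid), na.rm = TRUE), 1e-9)
  expect_error(cumulativeAnomaly(s, ref, c("2030-01", "2030-12")), "disjoint")
})

test_that("cloud-masked observations are skipped from sum and count", {
  s <- sceneSeries(generateScene(quietSceneConfig(cloudFraction = 0.4)))
  ref <- buildReference(s, c("1998-01", "2001-12"))
  an <- cumulativeAnomaly(s, ref, c("2002-01", "2003-04"))  # 16 dates
  nd <- ndviSeries(s, c("2002-01", "2003-04"))
  valid <- apply(!is.na(nd), c(1, 2), sum)
  ok <- !is.na(ref@medianNdvi)
  expect_equal(obsCount(an)[ok], valid[ok])
  expect_true(all(obsCount(an) <= 16L))
})

test_that("loss thresholding is inclusive, mask-restricted and monotone", {
  mc <- matrix(c(-0.25, -0.19, -0.2, 0.1), 2, 2)
  an <- new("AnomalyStack", cumulative = mc * 4,
            obsCount = matrix(4L, 2, 2), meanChange = mc,
            window = as.Date(c("2001-01-01", "2016-12-31")))
  mask <- matrix(TRUE, 2, 2)
  loss <- lossRaster(detectLoss(an, mask, -0.2))
  expect_identical(loss, matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2))
  # outside the mangrove mask: never loss
  mask2 <- matrix(FALSE, 2, 2)
  expect_false(any(lossRaster(detectLoss(an, mask2, -0.2))))
  # monotone in threshold
  l1 <- lossRaster(detectLoss(an, mask, -0.25))
  l2 <- lossRaster(detectLoss(an, mask, -0.19))
  expect_true(all(!l1 | l2))
  expect_error(detectLoss(an, mask, 0.2), "negative")
})

test_that("epoch dating picks the conversion epoch and partitions the loss", {
  cfg <- smallSceneConfig(cloudFraction = 0, noiseSigma = 0, events = list(
    eventSpec("CM", areaHa = 10.8, date = "2003-06-15", anchor = c(24, 25), width = 8),
    eventSpec("EWE", areaHa = 10.8, date = "2012-06-15", anchor = c(56, 19), width = 8)))
  scene <- generateScene(cfg)
  s <- sceneSeries(scene)
  ref <- buildReference(s)
  an <- cumulativeAnomaly(s, ref)
  # a mid-2012 conversion only reaches a full-window mean change of ~-0.17,
  # so use a -0.1 threshold here to keep both events in the total loss extent
  total <- detectLoss(an, mangroveMask(scene), threshold = -0.1)
  lm <- assignEpochs(s, ref, total)
  truth <- truthMap(scene)
  expect_true(all(epochRaster(lm)[truth@driver == "CM"] == "loss2005"))
  expect_true(all(epochRaster(lm)[truth@driver == "EWE"] == "loss2016"))
  expect_true(all(epochRaster(lm)[!lossRaster(lm)] == "none"))
  # epoch labels partition the loss mask exactly
  expect_identical(epochRaster(lm) != "none", lossRaster(lm))
  expect_error(assignEpochs(s, ref, total, epochs = list(
    a = c("2000-01", "2004-12"), b = c("2006-01", "2016-12"))), "tile")
})

test_that("noise-free detection recovers the truth loss area exactly", {
  scene <- generateScene(smallSceneConfig(cloudFraction = 0, noiseSigma = 0))
  s <- sceneSeries(scene)
  an <- cumulativeAnomaly(s, buildReference(s))
  loss <- lossRaster(detectLoss(an, mangroveMask(scene)))
  truth <- truthMap(scene)@driver != "none"
  expect_identical(loss, truth)
})
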