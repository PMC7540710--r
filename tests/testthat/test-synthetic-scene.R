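# Synthetic scene generator: area bookkeeping, determinism, spectra,
# detectability margins, cloud statistics, and error paths.

test_that("event areas are pixel-exact and totals match the event specs", {
  nr <- 120L
  cfg <- sceneConfig(nr, nr,
    layout = list(ocean = c(1, nr, 1, 10), mangrove = c(1, nr, 11, 80),
                  roads = list(), settlement = list(), agriculture = list(),
                  regions = list(all = c(1, nr, 1, nr))),
    events = list(eventSpec("CM", areaHa = 90, date = "2003-06-15",
                            anchor = c(11, 41), width = 20)),
    cloudFraction = 0, noiseSigma = 0, seed = 3L)
  scene <- generateScene(cfg)
  ta <- trueAreas(scene)
  expect_equal(ta$pixels[ta$driver == "CM"], 1000L)  # 90 ha / 0.09 ha per px
  expect_equal(ta$area_ha[ta$driver == "CM"], 90)
  expect_equal(sum(truthMap(scene)@driver != "none"), 1000L)
})

test_that("an empty event list yields a stationary scene with no truth loss", {
  scene <- generateScene(quietSceneConfig())
  expect_true(all(truthMap(scene)@driver == "none"))
  expect_true(all(truthMap(scene)@epoch == "none"))
  expect_equal(nrow(trueAreas(scene)), 0L)
  s <- sceneSeries(scene)
  first <- bandStack(s, 1)
  last <- bandStack(s, length(sceneDates(s)))
  # stationary up to noise: per-band means agree within a few noise SEs
  for (b in 1:6) {
    se <- s@noiseSigma / sqrt(sum(!is.na(first[, , b])))
    expect_lt(abs(mean(first[, , b], na.rm = TRUE) -
                  mean(last[, , b], na.rm = TRUE)), 6 * se)
  }
})

test_that("generation and lazy materialisation are deterministic given the seed", {
  cfg <- smallSceneConfig(seed = 11L)
  s1 <- generateScene(cfg)
  s2 <- generateScene(smallSceneConfig(seed = 11L))
  expect_identical(s1, s2)
  expect_identical(bandStack(sceneSeries(s1), 37), bandStack(sceneSeries(s2), 37))
  # single-band draw reproduces the same values as the full stack
  full <- bandStack(sceneSeries(s1), 37)
  expect_identical(bandStack(sceneSeries(s1), 37, bands = 4L)[, , 1],
                   full[, , 4])
  s3 <- generateScene(smallSceneConfig(seed = 12L))
  expect_false(identical(bandStack(sceneSeries(s1), 37),
                         bandStack(sceneSeries(s3), 37)))
})

test_that("simulated spectra follow the endmember table", {
  cfg <- smallSceneConfig(noiseSigma = 0)
  expect_equal(unname(simulateReflectance("water", Sys.Date(), cfg)),
               unname(defaultEndmembers()["water", ]))
  expect_error(simulateReflectance("lava", Sys.Date(), cfg), "unknown class")
  em <- defaultEndmembers()
  ndviM <- (em["mangrove", "nir"] - em["mangrove", "red"]) /
           (em["mangrove", "nir"] + em["mangrove", "red"])
  expect_gte(ndviM, 0.6); expect_lte(ndviM, 0.9)
  expect_lt(em["water", "nir"], 0.08)
  # noisy draws stay near the mean and inside [0, 1]
  cfgN <- smallSceneConfig(noiseSigma = 0.02)
  withr::with_seed(1, {
    draws <- replicate(200, simulateReflectance("mangrove", Sys.Date(), cfgN))
  })
  expect_true(all(draws >= 0 & draws <= 1))
  expect_lt(max(abs(rowMeans(draws) - em["mangrove", ])), 0.01)
})

test_that("every conversion drops mean NDVI by at least 0.3", {
  em <- defaultEndmembers()
  ndvi <- (em[, "nir"] - em[, "red"]) / (em[, "nir"] + em[, "red"])
  for (cl in c("wet_soil", "dry_soil", "water")) {
    expect_lte(ndvi[cl] - ndvi["mangrove"], -0.3)
  }
})

test_that("masked-observation fraction converges to cloudFraction", {
  cf <- 0.3
  s <- sceneSeries(generateScene(smallSceneConfig(cloudFraction = cf)))
  n <- 0; masked <- 0
  for (t in seq(1, length(s@dates), by = 12)) {
    bs <- bandStack(s, t, bands = 1L)
    masked <- masked + sum(is.na(bs)); n <- n + length(bs)
  }
  se <- sqrt(cf * (1 - cf) / n)
  expect_lt(abs(masked / n - cf), 3 * se)
})

test_that("impossible events are rejected with explicit errors", {
  # exceeds the mangrove band
  cfgBig <- smallSceneConfig(events = list(
    eventSpec("CM", areaHa = 5000, date = "2003-06-15", anchor = c(1, 9), width = 40)))
  expect_error(generateScene(cfgBig), "does not fit|exceeds")
  # overlapping events
  cfgOver <- smallSceneConfig(events = list(
    eventSpec("CM", areaHa = 10.8, date = "2002-09-15", anchor = c(24, 25), width = 8),
    eventSpec("NPC", areaHa = 10.8, date = "2006-09-15", anchor = c(24, 25), width = 8)))
  expect_error(generateScene(cfgOver), "overlaps")
  # outside the mangrove extent
  cfgOut <- smallSceneConfig(events = list(
    eventSpec("ST", areaHa = 10.8, date = "2006-03-15", anchor = c(1, 60), width = 8)))
  expect_error(generateScene(cfgOut), "outside the mangrove")
  # conversion date outside the epoch span
  expect_error(generateScene(smallSceneConfig(events = list(
    eventSpec("CM", areaHa = 10.8, date = "1999-06-15", anchor = c(24, 25), width = 8)))),
    "outside the 2000-2016 epochs")
})

test_that("scene config invariants are enforced", {
  expect_error(sceneConfig(16, 16, layout = list(), events = list()),
               ">= 32")
  expect_error(smallSceneConfig(cloudFraction = 1), "cloudFraction")
  lay <- smallSceneConfig()@layout
  lay$ocean <- c(30, 50, 30, 50)  # ocean not touching an edge
  expect_error(generateScene(smallSceneConfig(layout = lay, events = list())),
               "edge")
})

test_that("training points land on interior pixels of their class", {
  scene <- generateScene(smallSceneConfig())
  pts <- makeTrainingPoints(scene, nPerClass = 20, seed = 2)
  expect_true(all(table(pts$label) <= 20))
  expect_setequal(unique(pts$label), landcoverClasses())
  px <- pixelSize(scene)
  truth <- truthMap(scene)@driver
  for (i in seq_len(nrow(pts))) {
    r <- ceiling(pts$y[i] / px); cl <- ceiling(pts$x[i] / px)
    expect_true(truth[r, cl] != "none")
  }
})
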