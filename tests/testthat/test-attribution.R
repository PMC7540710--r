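# Driver attribution: connectivity, proximity geometry, the per-land-cover
# rule cascade, infrastructure sensitivity and epoch conservation.

test_that("ocean connectivity separates coastal water from enclosed ponds", {
  nr <- 12; nc <- 12
  ocean <- matrix(FALSE, nr, nc); ocean[, 1] <- TRUE
  water <- matrix(FALSE, nr, nc)
  water[5, 2:6] <- TRUE           # strip touching the ocean edge
  water[9:10, 8:10] <- TRUE       # enclosed pond
  conn <- oceanConnected(water, ocean, 8)
  expect_true(all(conn[5, 2:6]))
  expect_false(any(conn[9:10, 8:10]))
})

test_that("diagonal contact connects under 8- but not 4-connectivity", {
  ocean <- matrix(FALSE, 3, 3); ocean[1, 1] <- TRUE
  water <- matrix(FALSE, 3, 3); water[2, 2] <- TRUE; water[3, 3] <- TRUE
  for (conn in c(4, 8)) {
    got <- oceanConnected(water, ocean, conn)
    expect_identical(got, oracleFloodFill(water, ocean, conn))
  }
  expect_true(oceanConnected(water, ocean, 8)[2, 2])
  expect_false(oceanConnected(water, ocean, 4)[2, 2])
  # larger random case against the flood-fill oracle
  withr::with_seed(13, {
    w <- matrix(runif(400) < 0.45, 20, 20)
    oc <- matrix(FALSE, 20, 20); oc[, 1] <- TRUE
    for (conn in c(4, 8)) {
      expect_identical(oceanConnected(w, oc, conn), oracleFloodFill(w, oc, conn))
    }
  })
})

test_that("proximity buffers use exact centre-to-centre distances", {
  m <- matrix(FALSE, 9, 9); m[5, 5] <- TRUE
  expect_identical(proximity(m, 0, 30), m)
  p30 <- proximity(m, 30, 30)
  expect_true(all(p30[cbind(c(4, 6, 5, 5, 5), c(5, 5, 4, 6, 5))]))
  expect_equal(sum(p30), 5L)  # diagonals at 42.4 m are out
  expect_false(any(proximity(matrix(FALSE, 9, 9), 100, 30)))
  # brute-force oracle on a random mask
  withr::with_seed(31, msk <- matrix(runif(225) < 0.1, 15, 15))
  d <- 75; px <- 30
  got <- proximity(msk, d, px)
  truth <- which(msk, arr.ind = TRUE)
  for (r in 1:15) for (cl in 1:15) {
    dmin <- min(sqrt((truth[, 1] - r)^2 + (truth[, 2] - cl)^2)) * px
    expect_identical(got[r, cl], dmin <= d)
  }
})

test_that("the rule cascade recovers every driver on a clean scene", {
  scene <- generateScene(smallSceneConfig(cloudFraction = 0, noiseSigma = 0))
  truth <- truthMap(scene)@driver
  lossM <- truth != "none"
  post <- c(ER = "water", CM = "water", ST = "dry_soil",
            NPC = "wet_soil", EWE = "wet_soil")
  lc <- new("LandCoverMap",
            classRaster = ifelse(lossM, post[truth], NA_character_),
            compositeWindow = as.Date(c("2014-01-01", "2016-12-31")))
  dm <- attributeDrivers(lc, ancillaryLayers(scene))
  expect_identical(driverRaster(dm)[lossM], truth[lossM])
  expect_true(all(is.na(driverRaster(dm)[!lossM])))
})

test_that("infrastructure presence flips dieback from EWE to NPC", {
  cfgIsolated <- smallSceneConfig(cloudFraction = 0, noiseSigma = 0, events = list(
    eventSpec("EWE", areaHa = 10.8, date = "2010-06-15", anchor = c(56, 19), width = 8)))
  sceneI <- generateScene(cfgIsolated)
  lossM <- truthMap(sceneI)@driver != "none"
  lc <- new("LandCoverMap",
            classRaster = ifelse(lossM, "wet_soil", NA_character_),
            compositeWindow = as.Date(c("2014-01-01", "2016-12-31")))
  expect_true(all(driverRaster(attributeDrivers(lc, ancillaryLayers(sceneI)))[lossM]
                  == "EWE"))
  # the same dieback patch with a road through its neighbourhood becomes NPC
  layRoad <- cfgIsolated@layout
  layRoad$roads <- c(layRoad$roads, list(c(50, 80, 30, 30)))
  sceneR <- generateScene(smallSceneConfig(cloudFraction = 0, noiseSigma = 0,
    layout = layRoad, events = cfgIsolated@events))
  expect_true(all(driverRaster(attributeDrivers(lc, ancillaryLayers(sceneR)))[lossM]
                  == "NPC"))
})

test_that("unclassified pixels become unattributed and are reported", {
  lossM <- matrix(FALSE, 40, 40); lossM[10, 10:12] <- TRUE
  cr <- matrix(NA_character_, 40, 40)
  cr[10, 10] <- "unclassified"; cr[10, 11:12] <- "wet_soil"
  lc <- new("LandCoverMap", classRaster = cr,
            compositeWindow = as.Date(c("2014-01-01", "2016-12-31")))
  ocean <- matrix(FALSE, 40, 40); ocean[, 1] <- TRUE
  anc <- new("AncillaryLayers", oceanMask = ocean,
             roads = matrix(FALSE, 40, 40), settlement = matrix(FALSE, 40, 40),
             agriculture = matrix(FALSE, 40, 40), regions = list())
  expect_message(dm <- attributeDrivers(lc, anc), "unattributed")
  expect_equal(driverRaster(dm)[10, 10], "unattributed")
  da <- driverAreas(dm)
  expect_equal(da$pixels[da$driver == "unattributed"], 1L)
})

test_that("epoch cuts restrict the full map and conserve counts", {
  scene <- generateScene(smallSceneConfig(cloudFraction = 0, noiseSigma = 0))
  s <- sceneSeries(scene)
  ref <- buildReference(s)
  total <- detectLoss(cumulativeAnomaly(s, ref), mangroveMask(scene))
  lm <- assignEpochs(s, ref, total)
  truth <- truthMap(scene)@driver
  lossM <- truth != "none"
  post <- c(ER = "water", CM = "water", ST = "dry_soil",
            NPC = "wet_soil", EWE = "wet_soil")
  lc <- new("LandCoverMap",
            classRaster = ifelse(lossM, post[truth], NA_character_),
            compositeWindow = as.Date(c("2014-01-01", "2016-12-31")))
  dm <- cutByEpoch(attributeDrivers(lc, ancillaryLayers(scene)), lm)
  cuts <- lapply(lossEpochs(), function(e) epochCut(dm, e))
  # union of the epoch cuts is the full driver map
  merged <- matrix(NA_character_, 80, 80)
  for (cut in cuts) merged[!is.na(cut)] <- cut[!is.na(cut)]
  expect_identical(merged, driverRaster(dm))
  # per-epoch driver counts sum to the full-map counts
  perEpoch <- driverAreas(dm, byEpoch = TRUE)
  full <- driverAreas(dm)
  agg <- tapply(perEpoch$pixels, perEpoch$driver, sum)
  expect_equal(as.vector(agg[full$driver]), full$pixels)
  # an epoch with no pixels yields an empty cut
  dmNone <- cutByEpoch(dm, matrix("none", 80, 80))
  expect_true(all(is.na(epochCut(dmNone, "loss2005"))))
})
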