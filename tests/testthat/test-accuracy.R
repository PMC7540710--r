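# Stratified accuracy assessment: allocation arithmetic, error-matrix
# construction, the good-practice estimators against hand arithmetic, and
# the area-estimator identities.

test_that("proportional allocation uses largest remainders and a floor of one", {
  expect_equal(allocateSamples(c(a = 50, b = 50), 10), c(a = 5L, b = 5L))
  x <- allocateSamples(c(a = 1, b = 1, c = 1), 10)
  expect_equal(sum(x), 10L)
  expect_lte(max(x) - min(x), 1L)
  y <- allocateSamples(c(big = 1e6, tiny = 1), 20)
  expect_equal(sum(y), 20L)
  expect_gte(y["tiny"][[1]], 1L)
  expect_error(allocateSamples(c(a = 0, b = 1), 10), "positive")
  expect_error(allocateSamples(c(a = 1, b = 1), 1), "per class")
})

test_that("error matrices cross-tabulate with correct margins", {
  areas <- c(x = 60, y = 30, z = 10)
  map <- rep(c("x", "y", "z"), c(5, 3, 2))
  expect_identical(matrixCounts(buildErrorMatrix(map, map, areas)),
                   diag(c(5L, 3L, 2L)) |> (\(m) {
                     dimnames(m) <- list(names(areas), names(areas)); m })())
  withr::with_seed(2, {
    ref <- sample(names(areas), 10, replace = TRUE)
  })
  em <- buildErrorMatrix(map, ref, areas)
  expect_equal(sum(matrixCounts(em)), 10)
  perm <- sample(10)
  expect_identical(matrixCounts(buildErrorMatrix(map[perm], ref[perm], areas)),
                   matrixCounts(em))
  expect_error(buildErrorMatrix(c(map, "w"), c(ref, "x"), areas), "outside")
})

test_that("a perfect matrix gives unit accuracies with zero variance", {
  areas <- c(a = 70, b = 30)
  em <- buildErrorMatrix(rep(c("a", "b"), c(7, 3)),
                         rep(c("a", "b"), c(7, 3)), areas)
  rep <- accuracyReport(em)
  expect_equal(rep$overall$oa, 1)
  expect_equal(rep$overall$se, 0)
  expect_equal(rep$perClass$ua, c(1, 1))
  expect_equal(rep$perClass$pa, c(1, 1))
  ca <- correctedAreas(em)
  expect_equal(ca$area_est, unname(areas))
  expect_equal(ca$ci_halfwidth, c(0, 0))
})

test_that("the two-class hand computation is reproduced", {
  # W = (0.8, 0.2), counts [[45,5],[10,40]]:
  # OA = 0.8*45/50 + 0.2*40/50 = 0.88; corrected area of class 1 with
  # A_total = 100 is 100*(0.8*45/50 + 0.2*10/50) = 76
  counts <- matrix(c(45L, 10L, 5L, 40L), 2, 2,
                   dimnames = list(c("p", "q"), c("p", "q")))
  em <- new("ErrorMatrix", countsTable = counts, areas = c(p = 80, q = 20))
  rep <- accuracyReport(em)
  expect_equal(rep$overall$oa, 0.88, tolerance = 1e-12)
  expect_equal(correctedAreas(em)$area_est[1], 76, tolerance = 1e-12)
})

test_that("estimators match the brute-force oracle on random matrices", {
  withr::with_seed(77, {
    for (rep in 1:25) {
      k <- sample(3:5, 1)
      rm <- randomErrorMatrix(k)
      em <- new("ErrorMatrix", countsTable = rm$counts, areas = rm$areas)
      want <- oracleEstimators(rm$counts, rm$areas)
      got <- accuracyReport(em)
      ca <- correctedAreas(em)
      expect_equal(got$overall$oa, want$oa, tolerance = 1e-12)
      expect_equal(got$overall$se, sqrt(want$voa), tolerance = 1e-12)
      expect_equal(got$perClass$ua, want$ua, tolerance = 1e-12)
      expect_equal(got$perClass$pa, want$pa, tolerance = 1e-12)
      expect_equal(got$perClass$ua_se, sqrt(want$vua), tolerance = 1e-12)
      expect_equal(got$perClass$pa_se, sqrt(want$vpa), tolerance = 1e-12)
      expect_equal(ca$area_est, want$areaEst, tolerance = 1e-12)
      expect_equal(ca$se, want$areaSe, tolerance = 1e-12)
      # corrected areas conserve the total mapped area
      expect_equal(sum(ca$area_est), sum(rm$areas), tolerance = 1e-9)
    }
  })
})

test_that("degenerate rows raise informative errors", {
  counts <- matrix(c(5L, 0L, 3L, 0L), 2, 2,
                   dimnames = list(c("a", "b"), c("a", "b")))
  em <- new("ErrorMatrix", countsTable = counts, areas = c(a = 50, b = 50))
  expect_error(accuracyReport(em), "b")
  counts2 <- matrix(c(5L, 1L, 3L, 0L), 2, 2,
                    dimnames = list(c("a", "b"), c("a", "b")))
  em2 <- new("ErrorMatrix", countsTable = counts2, areas = c(a = 50, b = 50))
  expect_error(correctedAreas(em2), "fewer than 2")
})

test_that("simulated reference labels follow the confusion rows", {
  conf <- matrix(c(0.9, 0.2, 0.1, 0.8), 2, 2,
                 dimnames = list(c("a", "b"), c("a", "b")))
  map <- rep(c("a", "b"), each = 2000)
  ref <- simulateReferenceLabels(map, conf, seed = 5)
  expect_identical(ref, simulateReferenceLabels(map, conf, seed = 5))
  pAA <- mean(ref[map == "a"] == "a")
  expect_lt(abs(pAA - 0.9), 3 * sqrt(0.9 * 0.1 / 2000))
  expect_error(simulateReferenceLabels(c("a", "c"), conf, 1), "outside")
})

test_that("validation sampling is stratified and drops no-reference pixels", {
  scene <- generateScene(smallSceneConfig(cloudFraction = 0, noiseSigma = 0))
  truth <- truthMap(scene)@driver
  dm <- new("DriverMap",
            driver = ifelse(truth != "none", truth, NA_character_),
            epochLabel = truthMap(scene)@epoch)
  val <- sampleValidation(dm, truthMap(scene), 200, seed = 8)
  expect_equal(nrow(val) + attr(val, "droppedNoReference"), 200L)
  expect_true(all(val$map == val$reference))  # map equals truth here
  tab <- table(val$map)
  expect_equal(sort(names(tab)), sort(lossDrivers()))
})
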