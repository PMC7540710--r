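# One-call pipeline: scene -> loss detection -> epoch dating -> land-cover
# classification -> driver attribution -> validation -> regional reporting,
# with YAML-serialisable configuration, per-stage logging and a provenance
# record. Every stochastic step carries an explicit seed.

#' Build a pipeline configuration
#'
#' @param scene A [SceneConfig-class] (generated at run time) or a path to a
#'   scene directory written by [writeScene()].
#' @param refWindow,obsWindow Reference / observation windows.
#' @param minQuality Reference quality-pixel rule (default 10).
#' @param threshold Loss threshold (default -0.2).
#' @param compositeWindow Classification composite window.
#' @param trainingPerClass Training points per land-cover class.
#' @param nTrees,classifierSeed Random-forest settings.
#' @param rules A [ruleConfig()].
#' @param validationN,validationSeed Validation sample size and seed.
#' @param trainingSeed Seed for training-point sampling.
#' @return List of class `pipelineConfig` (YAML round-trippable via
#'   [writePipelineConfig()] / [readPipelineConfig()]).
#' @export
pipelineConfig <- function(scene = defaultSceneConfig(),
                           refWindow = c("1998-01", "2001-12"),
                           obsWindow = c("2001-01", "2016-12"),
                           minQuality = 10L, threshold = -0.2,
                           compositeWindow = c("2014-01", "2018-12"),
                           trainingPerClass = 60L, nTrees = 200L,
                           classifierSeed = 421L, rules = ruleConfig(),
                           validationN = 400L, validationSeed = 1243L,
                           trainingSeed = 77L) {
  structure(list(
    scene = scene, refWindow = refWindow, obsWindow = obsWindow,
    minQuality = as.integer(minQuality), threshold = threshold,
    compositeWindow = compositeWindow,
    trainingPerClass = as.integer(trainingPerClass),
    nTrees = as.integer(nTrees), classifierSeed = as.integer(classifierSeed),
    rules = rules, validationN = as.integer(validationN),
    validationSeed = as.integer(validationSeed),
    trainingSeed = as.integer(trainingSeed)
  ), class = "pipelineConfig")
}

#' Serialise / load a pipeline configuration (YAML)
#' @param config A `pipelineConfig`.
#' @param path YAML file path.
#' @return `readPipelineConfig` returns the `pipelineConfig`; a
#'   load-save-load round trip is identical.
#' @export
writePipelineConfig <- function(config, path) {
  x <- unclass(config)
  x$rules <- unclass(x$rules)
  x$scene <- if (is(x$scene, "SceneConfig")) sceneConfigToList(x$scene) else x$scene
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  x <- yaml::read_yaml(path)
  scene <- if (is.character(x$scene)) x$scene else sceneConfigFromList(x$scene)
  pipelineConfig(
    scene = scene,
    refWindow = unlist(x$refWindow), obsWindow = unlist(x$obsWindow),
    minQuality = x$minQuality, threshold = x$threshold,
    compositeWindow = unlist(x$compositeWindow),
    trainingPerClass = x$trainingPerClass, nTrees = x$nTrees,
    classifierSeed = x$classifierSeed,
    rules = do.call(ruleConfig, x$rules),
    validationN = x$validationN, validationSeed = x$validationSeed,
    trainingSeed = x$trainingSeed
  )
}

stageRun <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full pipeline
#'
#' Executes all stages in order and writes nine artifacts under `outDir`:
#' loss mask, epoch labels, land-cover map, driver map (TSV rasters), error
#' matrix, accuracy report, area estimates, regional summary (CSV) and a
#' provenance log (JSON: config hash, seeds, versions, per-stage pixel
#' audits). Deterministic given the config seeds: running twice gives
#' identical summary tables.
#'
#' @param config A `pipelineConfig`.
#' @param outDir Output directory (created).
#' @param quiet Suppress per-stage messages.
#' @return Invisibly, a list with the in-memory objects (`scene`,
#'   `reference`, `anomaly`, `lossMask`, `landcover`, `driverMap`,
#'   `errorMatrix`, `accuracy`, `areas`, `regional`) and `outDir`.
#' @export
runPipeline <- function(config, outDir, quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  scene <- stageRun("scene", {
    if (is.character(config$scene)) readScene(config$scene)
    else generateScene(config$scene)
  })
  px <- pixelSize(scene)
  pxHa <- px^2 / 1e4
  series <- sceneSeries(scene)
  say("scene: ", series@nrowGrid, "x", series@ncolGrid, " px, ",
      length(sceneDates(scene)), " dates")

  reference <- stageRun("reference",
    buildReference(series, config$refWindow, config$minQuality))
  anomaly <- stageRun("anomaly",
    cumulativeAnomaly(series, reference, config$obsWindow))
  totalLoss <- stageRun("detect",
    detectLoss(anomaly, mangroveMask(scene), config$threshold))
  lossMask <- stageRun("epochs",
    assignEpochs(series, reference, totalLoss, obsWindow = config$obsWindow))
  nLoss <- sum(lossRaster(lossMask))
  say("detect: ", nLoss, " loss px (", nLoss * pxHa, " ha)")

  composite <- stageRun("composite",
    buildComposite(series, config$compositeWindow))
  stack <- stageRun("predictors", predictorStack(composite))
  landcover <- stageRun("classify", {
    pts <- makeTrainingPoints(scene, config$trainingPerClass,
                              seed = config$trainingSeed)
    samples <- rasterizeTraining(pts, dim(mangroveMask(scene)), px)
    feats <- extractFeatures(stack, samples)
    model <- trainLandcoverModel(feats, config$nTrees, config$classifierSeed)
    say("classify: OOB accuracy ", round(attr(model, "oobAccuracy"), 4))
    classifyLossPixels(model, stack, lossMask, config$compositeWindow)
  })

  driverMap <- stageRun("attribute", {
    dm <- attributeDrivers(landcover, ancillaryLayers(scene), config$rules, px)
    cutByEpoch(dm, lossMask)
  })
  dAreas <- driverAreas(driverMap, pxHa)
  nAttr <- sum(dAreas$pixels[dAreas$driver != "unattributed"])
  nUnattr <- sum(dAreas$pixels[dAreas$driver == "unattributed"])
  say("attribute: ", nAttr, " attributed + ", nUnattr,
      " unattributed = ", nLoss, " loss px")

  val <- stageRun("validate",
    sampleValidation(driverMap, truthMap(scene), config$validationN,
                     config$validationSeed))
  mapAreasHa <- setNames(dAreas$area_ha, dAreas$driver)
  mapAreasHa <- mapAreasHa[names(mapAreasHa) %in% lossDrivers() & mapAreasHa > 0]
  em <- stageRun("error-matrix",
    buildErrorMatrix(val$map, val$reference, mapAreasHa))
  accuracy <- stageRun("accuracy", accuracyReport(em))
  areas <- stageRun("areas", correctedAreas(em))
  regional <- stageRun("report",
    regionalSummary(driverMap, ancillaryLayers(scene)@regions, px))

  # artifacts
  writeMatrixTSV(lossRaster(lossMask), file.path(outDir, "loss_mask.tsv"))
  writeMatrixTSV(epochRaster(lossMask), file.path(outDir, "epoch_label.tsv"))
  writeMatrixTSV(classRaster(landcover), file.path(outDir, "landcover.tsv"))
  writeMatrixTSV(driverRaster(driverMap), file.path(outDir, "driver_map.tsv"))
  write.csv(as.data.frame.matrix(matrixCounts(em)),
            file.path(outDir, "error_matrix.csv"))
  write.csv(accuracy$perClass, file.path(outDir, "accuracy_report.csv"),
            row.names = FALSE)
  write.csv(areas, file.path(outDir, "area_estimates.csv"), row.names = FALSE)
  write.csv(regional, file.path(outDir, "regional_summary.csv"),
            row.names = FALSE)
  provenance <- list(
    configHash = rlang::hash(config),
    seeds = list(scene = if (is(config$scene, "SceneConfig"))
                   config$scene@seed else NA,
                 classifier = config$classifierSeed,
                 training = config$trainingSeed,
                 validation = config$validationSeed),
    package = as.character(utils::packageVersion("mangroveDrivers")),
    rVersion = R.version.string,
    audit = list(lossPixels = nLoss, attributed = nAttr,
                 unattributed = nUnattr,
                 validationDropped = attr(val, "droppedNoReference"))
  )
  jsonlite::write_json(provenance, file.path(outDir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(scene = scene, reference = reference, anomaly = anomaly,
                 lossMask = lossMask, landcover = landcover,
                 driverMap = driverMap, errorMatrix = em,
                 accuracy = accuracy, areas = areas, regional = regional,
                 outDir = outDir))
}
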