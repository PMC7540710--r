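# S4 classes for the pipeline's central objects. Rasters are plain matrices in
# row/col (north-up, row 1 at the top) order; all objects on one scene share
# the grid. Georeferencing is a desk-scale convention: pixel centres at
# x = (col - 0.5) * pixelSize, y = (row - 0.5) * pixelSize, pixel area =
# pixelSize^2 everywhere (no geodesic correction).

#' @title Scene configuration for the synthetic coastal generator
#' @description Fully specifies a synthetic scene: grid, date axis, noise and
#'   cloud model, per-class endmember spectra, ancillary-layer layout,
#'   conversion events, aggregation regions and the master seed. Built with
#'   [sceneConfig()].
#' @slot gridRows,gridCols integer, pixel counts (each >= 32).
#' @slot pixelSize numeric, metres (default 30).
#' @slot dates `Date` vector, strictly increasing acquisition dates.
#' @slot cloudFraction numeric in `[0, 1)`, per pixel-date masking probability.
#' @slot noiseSigma numeric, reflectance noise standard deviation.
#' @slot endmembers numeric matrix, class x 6 bands mean reflectance.
#' @slot layout list of named rectangles/column spans for ocean, mangrove,
#'   roads, settlement, agriculture and regions.
#' @slot events list of [eventSpec()] entries.
#' @slot seed integer master seed.
#' @export
setClass("SceneConfig", representation(
  gridRows = "integer", gridCols = "integer", pixelSize = "numeric",
  dates = "Date", cloudFraction = "numeric", noiseSigma = "numeric",
  endmembers = "matrix", layout = "list", events = "list", seed = "integer"
), validity = function(object) {
  msg <- character()
  if (object@gridRows < 32L || object@gridCols < 32L)
    msg <- c(msg, "grid dimensions must be >= 32")
  if (object@cloudFraction < 0 || object@cloudFraction >= 1)
    msg <- c(msg, "cloudFraction must be in [0, 1)")
  if (length(object@dates) < 2L || any(diff(as.numeric(object@dates)) <= 0))
    msg <- c(msg, "date axis must be strictly increasing")
  if (!all(bandNames() %in% colnames(object@endmembers)))
    msg <- c(msg, "endmembers must have the six reflective bands as columns")
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @title Lazy synthetic reflectance time series
#' @description Procedural representation of a per-date six-band reflectance
#'   stack: per-pixel class before/after conversion plus the conversion date
#'   index, endmember table, noise and cloud model, and a seed. Per-date
#'   rasters are materialised on demand by [bandStack()] / [ndviSeries()];
#'   the draw for a given date is deterministic and independent of query
#'   order (the per-date RNG stream is derived from the master seed).
#' @slot nrowGrid,ncolGrid integer grid size.
#' @slot pixelSize numeric, metres.
#' @slot dates `Date` acquisition axis.
#' @slot classBefore,classAfter integer matrices indexing endmember rows.
#' @slot convIdx integer matrix: first date index at/after the conversion
#'   date (`NA` = never converts).
#' @slot endmembers class x band matrix.
#' @slot noiseSigma,cloudFraction numeric noise/cloud parameters.
#' @slot seed integer.
#' @export
setClass("ReflectanceSeries", representation(
  nrowGrid = "integer", ncolGrid = "integer", pixelSize = "numeric",
  dates = "Date", classBefore = "matrix", classAfter = "matrix",
  convIdx = "matrix", endmembers = "matrix", noiseSigma = "numeric",
  cloudFraction = "numeric", seed = "integer"
))

#' @title Ancillary infrastructure and aggregation layers
#' @description Boolean rasters for ocean, roads, settlement and
#'   agriculture/aquaculture extent, plus labelled region polygons used for
#'   aggregation. These are the desk-scale stand-ins for the open-source
#'   global layers a production attribution would consume.
#' @slot oceanMask,roads,settlement,agriculture logical matrices on the grid.
#' @slot regions named list of closed polygons (two-column x/y matrices in
#'   scene metre coordinates).
#' @export
setClass("AncillaryLayers", representation(
  oceanMask = "matrix", roads = "matrix", settlement = "matrix",
  agriculture = "matrix", regions = "list"
), validity = function(object) {
  dims <- vapply(list(object@oceanMask, object@roads, object@settlement,
                      object@agriculture), function(m) paste(dim(m), collapse = "x"),
                 character(1))
  if (length(unique(dims)) != 1L) return("ancillary masks must share the grid")
  om <- object@oceanMask
  edge <- any(om[1, ]) || any(om[nrow(om), ]) || any(om[, 1]) || any(om[, ncol(om)])
  if (!edge) return("oceanMask must touch at least one raster edge")
  TRUE
})

#' @title Ground-truth driver and epoch map of a synthetic scene
#' @slot driver character matrix in `{"none", ER, CM, ST, NPC, EWE}`.
#' @slot epoch character matrix in `{"none", loss2005, loss2010, loss2016}`.
#' @slot trueAreas data.frame with columns `driver`, `pixels`, `area_ha`.
#' @export
setClass("GroundTruthMap", representation(
  driver = "matrix", epoch = "matrix", trueAreas = "data.frame"
), validity = function(object) {
  if (!identical(dim(object@driver), dim(object@epoch)))
    return("driver and epoch rasters must share the grid")
  if (!all((object@driver == "none") == (object@epoch == "none")))
    return("driver != none must coincide exactly with epoch != none")
  TRUE
})

#' @title Synthetic scene bundle
#' @description Everything downstream stages consume: the (lazy) reflectance
#'   series, the baseline mangrove extent mask, ancillary layers, the
#'   ground-truth driver map, and the generating config.
#' @slot series [ReflectanceSeries-class].
#' @slot mangroveMask logical matrix, baseline mangrove extent.
#' @slot ancillary [AncillaryLayers-class].
#' @slot truth [GroundTruthMap-class].
#' @slot config [SceneConfig-class].
#' @export
setClass("SceneBundle", representation(
  series = "ReflectanceSeries", mangroveMask = "matrix",
  ancillary = "AncillaryLayers", truth = "GroundTruthMap",
  config = "SceneConfig"
))

#' @title Reference-period median NDVI raster
#' @slot medianNdvi numeric matrix (NA below the quality threshold).
#' @slot qualityCount integer matrix of valid observations used.
#' @slot minQuality integer threshold (default 10).
#' @slot window length-2 `Date`, the reference window.
#' @export
setClass("ReferenceRaster", representation(
  medianNdvi = "matrix", qualityCount = "matrix", minQuality = "integer",
  window = "Date"
), validity = function(object) {
  bad <- object@qualityCount < object@minQuality & !is.na(object@medianNdvi)
  if (any(bad)) return("medianNdvi must be NA where qualityCount < minQuality")
  if (any(abs(object@medianNdvi) > 1, na.rm = TRUE))
    return("medianNdvi must lie in [-1, 1]")
  TRUE
})

#' @title Cumulative NDVI anomaly stack
#' @description Per-pixel sum of (NDVI_t - reference median) over the
#'   observation window, the count of valid observations, and their ratio,
#'   the mean NDVI change — the loss decision variable.
#' @slot cumulative,meanChange numeric matrices.
#' @slot obsCount integer matrix.
#' @slot window length-2 `Date` observation window.
#' @export
setClass("AnomalyStack", representation(
  cumulative = "matrix", obsCount = "matrix", meanChange = "matrix",
  window = "Date"
), validity = function(object) {
  mc <- object@meanChange
  if (any(abs(mc) > 2, na.rm = TRUE)) return("meanChange must lie in [-2, 2]")
  resid <- object@meanChange * object@obsCount - object@cumulative
  if (any(abs(resid) > 1e-9, na.rm = TRUE))
    return("meanChange * obsCount must equal cumulative")
  TRUE
})

#' @title Loss mask with epoch labels
#' @slot loss logical matrix.
#' @slot epochLabel character matrix in `{"none", loss2005, loss2010,
#'   loss2016}` ("none" everywhere until [assignEpochs()]).
#' @slot threshold numeric change threshold (default -0.2, inclusive).
#' @slot epochs named list of epoch windows.
#' @export
setClass("LossMask", representation(
  loss = "matrix", epochLabel = "matrix", threshold = "numeric",
  epochs = "list"
), validity = function(object) {
  if (!identical(dim(object@loss), dim(object@epochLabel)))
    return("loss and epochLabel must share the grid")
  if (any(object@epochLabel != "none" & !object@loss))
    return("epoch labels are only allowed on loss pixels")
  TRUE
})

#' @title Post-loss land-cover map
#' @slot classRaster character matrix: NA outside the loss mask, otherwise
#'   one of wet_soil / dry_soil / water, or "unclassified" where predictors
#'   were null.
#' @slot compositeWindow length-2 `Date` of the classification composite.
#' @export
setClass("LandCoverMap", representation(
  classRaster = "matrix", compositeWindow = "Date"
))

#' @title Proximate-driver map
#' @slot driver character matrix: NA outside the loss mask, otherwise one of
#'   ER / CM / ST / NPC / EWE, or "unattributed" for unclassified land cover.
#' @slot epochLabel character matrix of epoch labels used by [epochCut()]
#'   (all "none" until [cutByEpoch()]).
#' @export
setClass("DriverMap", representation(
  driver = "matrix", epochLabel = "matrix"
))

#' @title Validation error matrix with mapped class areas
#' @slot countsTable integer matrix, map class i (rows) x reference class j
#'   (columns).
#' @slot areas named numeric, mapped area per class (same order as rows).
#' @export
setClass("ErrorMatrix", representation(
  countsTable = "matrix", areas = "numeric"
), validity = function(object) {
  ct <- object@countsTable
  if (nrow(ct) != ncol(ct)) return("error matrix must be square")
  if (!identical(rownames(ct), colnames(ct)))
    return("row and column class labels must match")
  if (!identical(rownames(ct), names(object@areas)))
    return("areas must be named by the map classes, in row order")
  if (any(ct < 0) || any(ct != round(ct))) return("counts must be non-negative integers")
  if (any(object@areas <= 0)) return("mapped class areas must be positive")
  TRUE
})
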