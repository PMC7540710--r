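# Generics and accessors. Slots are never touched directly by user code.

#' @rdname accessors
#' @export
setGeneric("meanChange", function(x) standardGeneric("meanChange"))
#' @rdname accessors
#' @export
setGeneric("obsCount", function(x) standardGeneric("obsCount"))
#' @rdname accessors
#' @export
setGeneric("lossRaster", function(x) standardGeneric("lossRaster"))
#' @rdname accessors
#' @export
setGeneric("epochRaster", function(x) standardGeneric("epochRaster"))
#' @rdname accessors
#' @export
setGeneric("classRaster", function(x) standardGeneric("classRaster"))
#' @rdname accessors
#' @export
setGeneric("driverRaster", function(x) standardGeneric("driverRaster"))
#' @rdname accessors
#' @export
setGeneric("mangroveMask", function(x) standardGeneric("mangroveMask"))
#' @rdname accessors
#' @export
setGeneric("ancillaryLayers", function(x) standardGeneric("ancillaryLayers"))
#' @rdname accessors
#' @export
setGeneric("truthMap", function(x) standardGeneric("truthMap"))
#' @rdname accessors
#' @export
setGeneric("sceneSeries", function(x) standardGeneric("sceneSeries"))
#' @rdname accessors
#' @export
setGeneric("sceneDates", function(x) standardGeneric("sceneDates"))
#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("trueAreas", function(x) standardGeneric("trueAreas"))
#' @rdname accessors
#' @export
setGeneric("matrixCounts", function(x) standardGeneric("matrixCounts"))
#' @rdname accessors
#' @export
setGeneric("classAreas", function(x) standardGeneric("classAreas"))

#' Accessors for pipeline objects
#'
#' Small read-only accessors: `meanChange()`/`obsCount()` on an
#' [AnomalyStack-class]; `lossRaster()`/`epochRaster()` on a
#' [LossMask-class]; `classRaster()` on a [LandCoverMap-class];
#' `driverRaster()`/`epochRaster()` on a [DriverMap-class];
#' `mangroveMask()`, `ancillaryLayers()`, `truthMap()`, `sceneSeries()` on a
#' [SceneBundle-class]; `sceneDates()`/`pixelSize()` on a
#' [ReflectanceSeries-class] or [SceneBundle-class]; `trueAreas()` on a
#' [GroundTruthMap-class]; `matrixCounts()`/`classAreas()` on an
#' [ErrorMatrix-class].
#'
#' @param x The object.
#' @return The corresponding raster matrix, table or scalar.
#' @name accessors
NULL

#' @rdname accessors
setMethod("meanChange", "AnomalyStack", function(x) x@meanChange)
#' @rdname accessors
setMethod("obsCount", "AnomalyStack", function(x) x@obsCount)
#' @rdname accessors
setMethod("lossRaster", "LossMask", function(x) x@loss)
#' @rdname accessors
setMethod("epochRaster", "LossMask", function(x) x@epochLabel)
#' @rdname accessors
setMethod("classRaster", "LandCoverMap", function(x) x@classRaster)
#' @rdname accessors
setMethod("driverRaster", "DriverMap", function(x) x@driver)
#' @rdname accessors
setMethod("epochRaster", "DriverMap", function(x) x@epochLabel)
#' @rdname accessors
setMethod("mangroveMask", "SceneBundle", function(x) x@mangroveMask)
#' @rdname accessors
setMethod("ancillaryLayers", "SceneBundle", function(x) x@ancillary)
#' @rdname accessors
setMethod("truthMap", "SceneBundle", function(x) x@truth)
#' @rdname accessors
setMethod("sceneSeries", "SceneBundle", function(x) x@series)
#' @rdname accessors
setMethod("sceneDates", "ReflectanceSeries", function(x) x@dates)
#' @rdname accessors
setMethod("sceneDates", "SceneBundle", function(x) x@series@dates)
#' @rdname accessors
setMethod("pixelSize", "ReflectanceSeries", function(x) x@pixelSize)
#' @rdname accessors
setMethod("pixelSize", "SceneBundle", function(x) x@series@pixelSize)
#' @rdname accessors
setMethod("trueAreas", "GroundTruthMap", function(x) x@trueAreas)
#' @rdname accessors
setMethod("trueAreas", "SceneBundle", function(x) x@truth@trueAreas)
#' @rdname accessors
setMethod("matrixCounts", "ErrorMatrix", function(x) x@countsTable)
#' @rdname accessors
setMethod("classAreas", "ErrorMatrix", function(x) x@areas)

setMethod("show", "SceneBundle", function(object) {
  s <- object@series
  cat("SceneBundle:", s@nrowGrid, "x", s@ncolGrid, "pixels at",
      s@pixelSize, "m,", length(s@dates), "dates",
      format(min(s@dates), "%Y-%m"), "..", format(max(s@dates), "%Y-%m"), "\n")
  cat("  mangrove extent:", sum(object@mangroveMask), "px (",
      format(sum(object@mangroveMask) * s@pixelSize^2 / 1e4, digits = 5), "ha )\n")
  ta <- object@truth@trueAreas
  if (nrow(ta)) {
    cat("  truth loss:", sum(ta$pixels), "px across drivers:",
        paste(sprintf("%s=%.1fha", ta$driver, ta$area_ha), collapse = ", "), "\n")
  } else cat("  truth loss: none\n")
})

setMethod("show", "AnomalyStack", function(object) {
  cat("AnomalyStack over", format(object@window[1]), "..",
      format(object@window[2]), "\n")
  cat("  mean change: range",
      paste(format(range(object@meanChange, na.rm = TRUE), digits = 3),
            collapse = " .. "),
      "(", sum(!is.na(object@meanChange)), "valid px )\n")
})

setMethod("show", "LossMask", function(object) {
  cat("LossMask: threshold <=", object@threshold, ";",
      sum(object@loss), "loss px\n")
  tab <- table(object@epochLabel[object@loss])
  if (length(tab)) cat("  epochs:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "LandCoverMap", function(object) {
  tab <- table(object@classRaster[!is.na(object@classRaster)])
  cat("LandCoverMap (composite",
      paste(format(object@compositeWindow, "%Y-%m"), collapse = ".."), "):",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "DriverMap", function(object) {
  tab <- table(object@driver[!is.na(object@driver)])
  cat("DriverMap:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "ErrorMatrix", function(object) {
  cat("ErrorMatrix (map rows x reference columns), n =",
      sum(object@countsTable), "\n")
  print(object@countsTable)
})
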