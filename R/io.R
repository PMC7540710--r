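# Plain-text raster/vector/config serialisation. Rasters travel as TSV
# matrices (readable, diffable, adequate at desk scale) with an explicit
# "NA" nodata token, or optionally as (non-geocoded) TIFF; regions as
# GeoJSON; configs as YAML. A scene directory stores the scene config plus
# derived layers; the reflectance series itself is procedural and is
# regenerated bit-identically from the config on read.

#' Write / read a matrix as TSV
#' @param m Matrix (numeric, logical or character).
#' @param path File path.
#' @return `readMatrixTSV` returns the matrix (numeric unless `mode` says
#'   otherwise).
#' @export
writeMatrixTSV <- function(m, path) {
  utils::write.table(m, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname writeMatrixTSV
#' @param mode "numeric", "logical" or "character".
#' @export
readMatrixTSV <- function(path, mode = "numeric") {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE,
                                   na.strings = "NA",
                                   colClasses = if (mode == "character") "character" else NA,
                                   stringsAsFactors = FALSE))
  dimnames(m) <- NULL
  switch(mode,
         numeric = matrix(as.numeric(m), nrow(m), ncol(m)),
         logical = matrix(as.logical(m), nrow(m), ncol(m)),
         character = m)
}

#' Write region polygons as GeoJSON
#' @param regions Named list of closed two-column polygon matrices (metres).
#' @param path Output file.
#' @export
writeRegionsGeoJSON <- function(regions, path) {
  features <- lapply(names(regions), function(nm) {
    coords <- regions[[nm]]
    list(type = "Feature",
         properties = list(name = nm),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(coords)),
                           function(i) as.numeric(coords[i, ])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeRegionsGeoJSON
#' @export
readRegionsGeoJSON <- function(path) {
  gj <- jsonlite::read_json(path)
  out <- lapply(gj$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    do.call(rbind, lapply(ring, function(p) c(x = p[[1]], y = p[[2]])))
  })
  names(out) <- vapply(gj$features, function(f) f$properties$name, "")
  out
}

sceneConfigToList <- function(cfg) {
  list(
    gridRows = cfg@gridRows, gridCols = cfg@gridCols,
    pixelSize = cfg@pixelSize,
    dates = format(cfg@dates),
    cloudFraction = cfg@cloudFraction, noiseSigma = cfg@noiseSigma,
    endmembers = apply(cfg@endmembers, 1, as.list, simplify = FALSE) |>
      lapply(function(r) setNames(r, colnames(cfg@endmembers))),
    layout = cfg@layout,
    events = lapply(cfg@events, function(e) {
      e$date <- format(e$date); e
    }),
    seed = cfg@seed
  )
}

sceneConfigFromList <- function(x) {
  em <- do.call(rbind, lapply(x$endmembers, function(r) unlist(r[bandNames()])))
  rownames(em) <- names(x$endmembers)
  lay <- x$layout
  for (nm in c("ocean", "mangrove")) lay[[nm]] <- unlist(lay[[nm]])
  for (nm in c("roads", "settlement", "agriculture"))
    lay[[nm]] <- lapply(lay[[nm]], unlist)
  lay$regions <- lapply(lay$regions, unlist)
  events <- lapply(x$events, function(e) {
    eventSpec(e$driver, e$areaHa, e$date, unlist(e$anchor), e$width,
              postClass = e$postClass)
  })
  sceneConfig(x$gridRows, x$gridCols, pixelSize = x$pixelSize,
              dates = as.Date(unlist(x$dates)),
              cloudFraction = x$cloudFraction, noiseSigma = x$noiseSigma,
              endmembers = em, layout = lay, events = events, seed = x$seed)
}

#' Write a scene to a directory
#'
#' Writes `scene_config.yaml`, the mangrove mask, ancillary masks, truth
#' rasters (TSV), the true-area table (CSV) and region polygons (GeoJSON).
#' With `reflectance = TRUE` also writes one (non-geocoded) multi-band
#' float TIFF per acquisition date (requires the `tiff` package). The
#' config alone reconstructs the full series deterministically, so
#' [readScene()] does not need the TIFFs.
#'
#' @param scene A [SceneBundle-class].
#' @param dir Output directory (created).
#' @param reflectance Also write per-date reflectance TIFFs.
#' @return `dir`, invisibly.
#' @export
writeScene <- function(scene, dir, reflectance = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(sceneConfigToList(scene@config),
                   file.path(dir, "scene_config.yaml"))
  writeMatrixTSV(scene@mangroveMask, file.path(dir, "mangrove_mask.tsv"))
  anc <- scene@ancillary
  writeMatrixTSV(anc@oceanMask, file.path(dir, "ocean_mask.tsv"))
  writeMatrixTSV(anc@roads, file.path(dir, "roads.tsv"))
  writeMatrixTSV(anc@settlement, file.path(dir, "settlement.tsv"))
  writeMatrixTSV(anc@agriculture, file.path(dir, "agriculture.tsv"))
  writeMatrixTSV(scene@truth@driver, file.path(dir, "truth_driver.tsv"))
  writeMatrixTSV(scene@truth@epoch, file.path(dir, "truth_epoch.tsv"))
  write.csv(scene@truth@trueAreas, file.path(dir, "true_areas.csv"),
            row.names = FALSE)
  writeRegionsGeoJSON(anc@regions, file.path(dir, "regions.geojson"))
  if (reflectance) {
    assertThat(requireNamespace("tiff", quietly = TRUE),
               "the tiff package is required for reflectance output")
    rdir <- file.path(dir, "reflectance")
    dir.create(rdir, showWarnings = FALSE)
    s <- scene@series
    for (t in seq_along(s@dates)) {
      arr <- bandStack(s, t)
      arr[is.na(arr)] <- 0  # TIFF has no NA; validity implied by the QA model
      tiff::writeTIFF(arr, file.path(rdir, paste0(format(s@dates[t]), ".tif")),
                      bits.per.sample = 32L)
    }
  }
  invisible(dir)
}

#' Read a scene directory back
#'
#' Reconstructs the [SceneBundle-class] by regenerating it from the stored
#' config (deterministic given the stored seed).
#'
#' @param dir Directory written by [writeScene()].
#' @return A [SceneBundle-class].
#' @export
readScene <- function(dir) {
  path <- file.path(dir, "scene_config.yaml")
  assertThat(file.exists(path), paste("no scene at", dir))
  generateScene(sceneConfigFromList(yaml::read_yaml(path)))
}
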