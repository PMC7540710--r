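# Synthetic coastal scene generator: a seeded, fully specified stand-in for a
# Landsat-like archive over a mangrove coastline. Classes are spectrally
# separable endmembers plus Gaussian noise; conversion events switch a pixel
# from mangrove to its post-conversion class at a stated date; clouds are
# i.i.d. per pixel-date. The generator is the test bed for every downstream
# stage: the truth driver/epoch map it records is what parameter-recovery
# experiments compare against.

#' Default per-class endmember spectra
#'
#' Mean surface reflectance per class for the six reflective bands (blue,
#' green, red, NIR, SWIR1, SWIR2). Chosen for class separability, not
#' radiative-transfer realism: mangrove NDVI = 0.75, wet soil 0.15, dry soil
#' 0.10, water -0.30, so every conversion drops mean NDVI by at least 0.6 —
#' a comfortable margin over the -0.2 loss threshold. The table is data, not
#' logic: pass an edited copy to [sceneConfig()] to change the spectra.
#'
#' @return 4 x 6 numeric matrix, rows mangrove/wet_soil/dry_soil/water,
#'   columns [bandNames()].
#' @export
#' @examples
#' em <- defaultEndmembers()
#' (em["mangrove", "nir"] - em["mangrove", "red"]) /
#'   (em["mangrove", "nir"] + em["mangrove", "red"])  # 0.75
defaultEndmembers <- function() {
  em <- rbind(
    mangrove = c(0.030, 0.050, 0.060, 0.420, 0.150, 0.070),
    wet_soil = c(0.080, 0.120, 0.170, 0.230, 0.200, 0.150),
    dry_soil = c(0.180, 0.220, 0.270, 0.330, 0.380, 0.300),
    water    = c(0.060, 0.055, 0.065, 0.035, 0.015, 0.008)
  )
  colnames(em) <- bandNames()
  em
}

# post-conversion land cover implied by each driver
postClassOf <- function(driver) {
  c(ER = "water", CM = "water", ST = "dry_soil",
    NPC = "wet_soil", EWE = "wet_soil")[driver]
}

#' Specify one conversion event
#'
#' An event converts a block of mangrove pixels to the driver's
#' post-conversion class at `date`. `CM`/`ST`/`NPC`/`EWE` events are
#' rectangles anchored at `anchor = c(row, col)` (top-left), `width` columns
#' wide, filled row by row until the target area is reached (so the pixel
#' count is exactly `round(areaHa / pixelAreaHa)`). `ER` events are erosion
#' fronts carved inward from the seaward mangrove edge: `anchor` is the first
#' row and `width` the number of rows of coastline affected; columns fill
#' from the ocean side so the resulting water is connected to the ocean.
#'
#' @param driver One of [lossDrivers()].
#' @param areaHa Target area in hectares.
#' @param date Conversion date (`Date` or string); must fall inside the epoch
#'   span 2000--2016.
#' @param anchor For rectangles `c(row, col)`; for `ER` the first coast row.
#' @param width Columns (rectangles) or rows (`ER`) spanned.
#' @param postClass Optional override of the post-conversion class.
#' @return A validated event list, for `events` of [sceneConfig()].
#' @export
#' @examples
#' eventSpec("CM", areaHa = 90, date = "2002-09-15", anchor = c(60, 71), width = 20)
eventSpec <- function(driver, areaHa, date, anchor, width,
                      postClass = postClassOf(driver)) {
  driver <- match.arg(driver, lossDrivers())
  date <- as.Date(date)
  assertThat(areaHa > 0, "event area must be positive")
  assertThat(!is.na(date), "event date must be a valid date")
  assertThat(postClass %in% setdiff(landcoverClasses(), NULL),
             "postClass must be a land-cover class")
  list(driver = driver, areaHa = areaHa, date = date,
       anchor = as.integer(anchor), width = as.integer(width),
       postClass = unname(postClass))
}

rectMask <- function(nr, nc, rect) {
  m <- matrix(FALSE, nr, nc)
  m[rect[1]:rect[2], rect[3]:rect[4]] <- TRUE
  m
}

rectPolygon <- function(rect, pixelSize) {
  # pixel-edge polygon of a row/col rectangle, in scene metre coordinates
  x0 <- (rect[3] - 1) * pixelSize; x1 <- rect[4] * pixelSize
  y0 <- (rect[1] - 1) * pixelSize; y1 <- rect[2] * pixelSize
  cbind(x = c(x0, x1, x1, x0, x0), y = c(y0, y0, y1, y1, y1)[c(1, 2, 3, 4, 1)])
}

#' Build a scene configuration
#'
#' @param gridRows,gridCols Grid size in pixels (each >= 32).
#' @param pixelSize Pixel edge length in metres (default 30).
#' @param dates Acquisition date axis; default monthly 1998-01..2016-12
#'   (228 dates), dense enough to satisfy the >= 10 quality-observation rule
#'   in the 1998--2001 reference window even under heavy cloud cover.
#' @param cloudFraction Probability an observation is cloud-masked,
#'   independently per pixel and date (default 0.3).
#' @param noiseSigma Reflectance noise standard deviation (default 0.02).
#' @param endmembers Class x band mean-reflectance table
#'   (default [defaultEndmembers()]).
#' @param layout Named list of grid rectangles `c(row1, row2, col1, col2)`:
#'   `ocean`, `mangrove`, and lists `roads`, `settlement`, `agriculture`,
#'   plus a named list `regions` of aggregation rectangles.
#' @param events List of [eventSpec()] entries.
#' @param seed Integer master seed; every stochastic component (noise,
#'   clouds) derives its stream from it.
#' @return A validated [SceneConfig-class].
#' @seealso [defaultSceneConfig()] for the ready-made five-event study scene.
#' @export
sceneConfig <- function(gridRows, gridCols, pixelSize = 30,
                        dates = monthlyDates(), cloudFraction = 0.3,
                        noiseSigma = 0.02, endmembers = defaultEndmembers(),
                        layout, events = list(), seed = 1L) {
  new("SceneConfig", gridRows = as.integer(gridRows),
      gridCols = as.integer(gridCols), pixelSize = pixelSize,
      dates = as.Date(dates), cloudFraction = cloudFraction,
      noiseSigma = noiseSigma, endmembers = endmembers,
      layout = layout, events = events, seed = as.integer(seed))
}

#' The default five-event study scene (200 x 200 px, 30 m)
#'
#' A 6 km x 6 km coastline: ocean along the west edge, a 3 km mangrove band,
#' land with a road, a settlement footprint and an agriculture block to the
#' east. One conversion event per driver, ~432 ha of loss in total, spread
#' over the three epochs: an erosion front (ER, 2002), an enclosed
#' aquaculture pond (CM, 2002), settlement expansion next to the urban
#' footprint (ST, 2006), road-adjacent dieback (NPC, 2006) and isolated
#' storm dieback (EWE, 2010).
#'
#' @param seed Master seed.
#' @param cloudFraction,noiseSigma Observation-model parameters, see
#'   [sceneConfig()].
#' @return A [SceneConfig-class].
#' @export
#' @examples
#' cfg <- defaultSceneConfig(seed = 7)
#' sum(vapply(cfg@events, `[[`, numeric(1), "areaHa"))
defaultSceneConfig <- function(seed = 1L, cloudFraction = 0.3,
                               noiseSigma = 0.02) {
  nr <- 200L; nc <- 200L
  layout <- list(
    ocean = c(1, nr, 1, 20),
    mangrove = c(1, nr, 21, 120),
    roads = list(c(1, nr, 140, 140)),
    settlement = list(c(1, 50, 121, 135)),
    agriculture = list(c(150, 180, 150, 170)),
    regions = list(west = c(1, nr, 1, 100), east = c(1, nr, 101, nc))
  )
  events <- list(
    eventSpec("ER", areaHa = 90, date = "2002-03-15", anchor = 1, width = nr),
    eventSpec("CM", areaHa = 90, date = "2002-09-15", anchor = c(60, 71), width = 20),
    eventSpec("ST", areaHa = 72, date = "2006-03-15", anchor = c(1, 105), width = 16),
    eventSpec("NPC", areaHa = 90, date = "2006-09-15", anchor = c(60, 111), width = 10),
    eventSpec("EWE", areaHa = 90, date = "2010-06-15", anchor = c(140, 41), width = 20)
  )
  sceneConfig(nr, nc, layout = layout, events = events, seed = seed,
              cloudFraction = cloudFraction, noiseSigma = noiseSigma)
}

epochOfDate <- function(date, epochs = defaultEpochs()) {
  for (e in names(epochs)) {
    if (date >= epochs[[e]][1] && date <= epochs[[e]][2]) return(e)
  }
  NA_character_
}

# carve one event into the claim matrix; returns linear pixel indices
carveEvent <- function(ev, config, mangrove, claimed) {
  nr <- config@gridRows; nc <- config@gridCols
  pxHa <- config@pixelSize^2 / 1e4
  nPx <- round(ev$areaHa / pxHa)
  assertThat(nPx >= 1, "event area smaller than one pixel")
  cells <- integer(0)
  if (ev$driver == "ER") {
    rows <- ev$anchor[1]:(ev$anchor[1] + ev$width - 1L)
    assertThat(all(rows >= 1 & rows <= nr), "ER rows outside grid")
    mangCols <- which(apply(mangrove, 2, any))
    for (cc in mangCols) {
      take <- rows[mangrove[rows, cc] & !claimed[rows, cc]]
      take <- head(take, nPx - length(cells))
      cells <- c(cells, (cc - 1L) * nr + take)
      if (length(cells) >= nPx) break
    }
  } else {
    r0 <- ev$anchor[1]; c0 <- ev$anchor[2]
    cols <- c0:(c0 + ev$width - 1L)
    assertThat(all(cols >= 1 & cols <= nc), "event columns outside grid")
    r <- r0
    while (length(cells) < nPx) {
      assertThat(r <= nr, sprintf("%s event of %g ha does not fit below row %d",
                                  ev$driver, ev$areaHa, r0))
      take <- cols[seq_len(min(ev$width, nPx - length(cells)))]
      cells <- c(cells, (take - 1L) * nr + r)
      r <- r + 1L
    }
  }
  assertThat(length(cells) == nPx,
             sprintf("%s event of %g ha exceeds the available mangrove area",
                     ev$driver, ev$areaHa))
  assertThat(all(mangrove[cells]),
             sprintf("%s event extends outside the mangrove extent", ev$driver))
  assertThat(!any(claimed[cells]),
             sprintf("%s event overlaps a previously placed event", ev$driver))
  cells
}

#' Generate a synthetic scene
#'
#' Deterministic given the config seed: two calls with the same config return
#' identical bundles, and every per-date raster drawn later from the bundle's
#' series is likewise reproducible.
#'
#' @param config A [SceneConfig-class].
#' @return A [SceneBundle-class] holding the lazy reflectance series, the
#'   baseline mangrove mask, ancillary layers, and the ground-truth
#'   driver/epoch map with exact per-driver areas.
#' @export
#' @examples
#' cfg <- defaultSceneConfig()
#' scene <- generateScene(cfg)
#' trueAreas(scene)
generateScene <- function(config) {
  validObject(config)
  nr <- config@gridRows; nc <- config@gridCols
  lay <- config@layout
  pxHa <- config@pixelSize^2 / 1e4

  ocean <- rectMask(nr, nc, lay$ocean)
  mangrove <- rectMask(nr, nc, lay$mangrove) & !ocean
  maskFrom <- function(rects) {
    m <- matrix(FALSE, nr, nc)
    for (r in rects) m <- m | rectMask(nr, nc, r)
    m
  }
  roads <- maskFrom(lay$roads %||% list())
  settlement <- maskFrom(lay$settlement %||% list())
  agriculture <- maskFrom(lay$agriculture %||% list())

  classIdx <- function(lbl) match(lbl, rownames(config@endmembers))
  before <- matrix(classIdx("dry_soil"), nr, nc)
  before[ocean] <- classIdx("water")
  before[mangrove] <- classIdx("mangrove")

  after <- before
  convIdx <- matrix(NA_integer_, nr, nc)
  driver <- matrix("none", nr, nc)
  epoch <- matrix("none", nr, nc)
  claimed <- matrix(FALSE, nr, nc)

  for (ev in config@events) {
    cells <- carveEvent(ev, config, mangrove, claimed)
    claimed[cells] <- TRUE
    after[cells] <- classIdx(ev$postClass)
    ti <- which(config@dates >= ev$date)
    assertThat(length(ti) > 0,
               sprintf("%s conversion date %s is after the series end",
                       ev$driver, format(ev$date)))
    convIdx[cells] <- ti[1]
    driver[cells] <- ev$driver
    ep <- epochOfDate(ev$date)
    assertThat(!is.na(ep),
               sprintf("%s conversion date %s falls outside the 2000-2016 epochs",
                       ev$driver, format(ev$date)))
    epoch[cells] <- ep
  }

  counts <- table(factor(driver[driver != "none"], levels = lossDrivers()))
  present <- counts[counts > 0]
  trueAreasTbl <- data.frame(
    driver = names(present), pixels = as.integer(present),
    area_ha = as.integer(present) * pxHa, row.names = NULL,
    stringsAsFactors = FALSE
  )

  regions <- lapply(lay$regions %||% list(), rectPolygon,
                    pixelSize = config@pixelSize)

  series <- new("ReflectanceSeries", nrowGrid = nr, ncolGrid = nc,
                pixelSize = config@pixelSize, dates = config@dates,
                classBefore = before, classAfter = after, convIdx = convIdx,
                endmembers = config@endmembers,
                noiseSigma = config@noiseSigma,
                cloudFraction = config@cloudFraction, seed = config@seed)
  ancillary <- new("AncillaryLayers", oceanMask = ocean, roads = roads,
                   settlement = settlement, agriculture = agriculture,
                   regions = regions)
  truth <- new("GroundTruthMap", driver = driver, epoch = epoch,
               trueAreas = trueAreasTbl)
  new("SceneBundle", series = series, mangroveMask = mangrove,
      ancillary = ancillary, truth = truth, config = config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic per-(date, component) seed; component 0 = cloud mask,
# 1..6 = band noise; stays below 2^31
streamSeed <- function(seed, t, k) {
  as.integer((as.double(seed) + 1000003 * t + 97 * k) %% 2147483629)
}

#' Simulate one six-band reflectance observation
#'
#' Endmember mean plus Gaussian noise (sd `noiseSigma`), truncated to
#' `[0, 1]`. Uses the current RNG stream (seed it yourself for
#' reproducibility); the lazy series accessors use their own per-date
#' streams instead.
#'
#' @param classLabel Row name of the endmember table.
#' @param date Ignored by the default model (spectra are stationary); kept so
#'   signatures match time-varying models.
#' @param config A [SceneConfig-class].
#' @return Named numeric vector over [bandNames()].
#' @export
simulateReflectance <- function(classLabel, date, config) {
  em <- config@endmembers
  assertThat(classLabel %in% rownames(em),
             paste("unknown class:", classLabel))
  v <- em[classLabel, bandNames()] + rnorm(6, 0, config@noiseSigma)
  pmin(pmax(v, 0), 1)
}

#' Materialise the six-band raster for one date
#'
#' @param series A [ReflectanceSeries-class].
#' @param t Date index (1-based) into `sceneDates(series)`.
#' @param bands Integer subset of bands to draw (default all six). The noise
#'   stream is per-band, so a subset reproduces exactly the same values as
#'   the full stack.
#' @return Array `[rows, cols, length(bands)]` with `NA` at cloud-masked
#'   pixels (the per-date validity mask is `!is.na()` of any band).
#' @export
bandStack <- function(series, t, bands = 1:6) {
  nr <- series@nrowGrid; nc <- series@ncolGrid; n <- nr * nc
  t <- as.integer(t)
  assertThat(t >= 1 && t <= length(series@dates), "date index out of range")
  cls <- ifelse(!is.na(series@convIdx) & t >= series@convIdx,
                series@classAfter, series@classBefore)
  cloudy <- withr::with_seed(streamSeed(series@seed, t, 0L),
                             runif(n) < series@cloudFraction)
  out <- array(NA_real_, c(nr, nc, length(bands)),
               dimnames = list(NULL, NULL, bandNames()[bands]))
  for (i in seq_along(bands)) {
    b <- bands[i]
    mu <- series@endmembers[, b][cls]
    noise <- if (series@noiseSigma > 0) {
      withr::with_seed(streamSeed(series@seed, t, b), rnorm(n, 0, series@noiseSigma))
    } else 0
    v <- pmin(pmax(mu + noise, 0), 1)
    v[cloudy] <- NA_real_
    out[, , i] <- v
  }
  out
}

#' NDVI observation stack over a date window
#'
#' NDVI is recomputed from the red and NIR bands at materialisation time (so
#' the validity mask is applied once, at the band level).
#'
#' @param series A [ReflectanceSeries-class].
#' @param window Optional `c(start, end)` window ("YYYY-MM" strings or
#'   Dates); default all dates.
#' @return Array `[rows, cols, nDates]`, with the matched dates as
#'   `dimnames[[3]]`; `NA` where cloud-masked.
#' @export
ndviSeries <- function(series, window = NULL) {
  idx <- if (is.null(window)) seq_along(series@dates)
         else windowIndices(series@dates, window)
  assertThat(length(idx) > 0, "window contains no acquisition dates")
  nr <- series@nrowGrid; nc <- series@ncolGrid
  out <- array(NA_real_, c(nr, nc, length(idx)),
               dimnames = list(NULL, NULL, format(series@dates[idx])))
  for (i in seq_along(idx)) {
    bs <- bandStack(series, idx[i], bands = c(3L, 4L))
    red <- bs[, , 1]; nir <- bs[, , 2]
    den <- nir + red
    v <- (nir - red) / den
    v[!is.na(den) & den == 0] <- NA_real_
    out[, , i] <- v
  }
  out
}

# binary erosion of a logical matrix by a (2e+1) square, edge-padded FALSE
shrinkMask <- function(m, e) {
  out <- m
  nr <- nrow(m); nc <- ncol(m)
  for (dr in -e:e) for (dc in -e:e) {
    if (dr == 0 && dc == 0) next
    sh <- matrix(FALSE, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    sh[rs, cs] <- m[rs - dr, cs - dc]
    out <- out & sh
  }
  out
}

#' Sample labelled training points from a scene's ground truth
#'
#' Emulates the photo-interpreted training points of a real campaign: points
#' are placed at pixel centres of converted (loss) pixels, labelled with
#' their post-conversion land-cover class. Sampling is restricted to block
#' interiors (`erode`-pixel margin) so the 1-ha training buffers drawn around
#' each point stay inside a single class.
#'
#' @param scene A [SceneBundle-class].
#' @param nPerClass Points per land-cover class (classes with fewer eligible
#'   pixels contribute what they have).
#' @param seed RNG seed.
#' @param erode Interior margin in pixels (default 2).
#' @return data.frame with `x`, `y` (metres, pixel centres) and `label`.
#' @export
makeTrainingPoints <- function(scene, nPerClass = 60, seed = 1L, erode = 2L) {
  truth <- scene@truth
  px <- pixelSize(scene)
  post <- matrix(NA_character_, nrow(truth@driver), ncol(truth@driver))
  lossIdx <- truth@driver != "none"
  post[lossIdx] <- unname(postClassOf(truth@driver[lossIdx]))
  pts <- withr::with_seed(as.integer(seed), {
    do.call(rbind, lapply(landcoverClasses(), function(cl) {
      m <- !is.na(post) & post == cl
      core <- shrinkMask(m, erode)
      cells <- which(core)
      if (!length(cells)) return(NULL)
      take <- sample(cells, min(nPerClass, length(cells)))
      rows <- (take - 1L) %% nrow(m) + 1L
      cols <- (take - 1L) %/% nrow(m) + 1L
      data.frame(x = (cols - 0.5) * px, y = (rows - 0.5) * px, label = cl,
                 stringsAsFactors = FALSE)
    }))
  })
  assertThat(!is.null(pts) && nrow(pts) > 0, "no eligible training pixels")
  pts
}
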