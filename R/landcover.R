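# Post-loss land-cover classification: a late-period per-band median
# composite supplies the seven predictors; labelled points are buffered to
# 1-ha discs of training pixels; a random forest assigns every loss pixel to
# wet soil, dry soil, or water.

#' Per-band median composite over a date window
#'
#' Cloud-masked observations are skipped; pixels with no valid observation
#' in any band are null in that band. The default window (2014--2018) is
#' clipped to the available acquisition dates.
#'
#' @param series A [ReflectanceSeries-class].
#' @param window `c(start, end)` (default `c("2014-01", "2018-12")`).
#' @return Array `[rows, cols, 6]` in [bandNames()] order.
#' @export
buildComposite <- function(series, window = c("2014-01", "2018-12")) {
  idx <- windowIndices(series@dates, window)
  assertThat(length(idx) > 0, "composite window contains no acquisition dates")
  nr <- series@nrowGrid; nc <- series@ncolGrid
  out <- array(NA_real_, c(nr, nc, 6L), dimnames = list(NULL, NULL, bandNames()))
  obs <- array(NA_real_, c(nr, nc, length(idx)))
  for (b in 1:6) {
    for (i in seq_along(idx)) obs[, , i] <- bandStack(series, idx[i], bands = b)[, , 1]
    out[, , b] <- stackMedian(obs)$median
  }
  out
}

#' Rasterise labelled training points through 1-ha circular buffers
#'
#' Around each point a disc of area `bufferAreaHa` hectares (radius
#' `sqrt(1e4 * bufferAreaHa / pi)`, about 56.4 m for 1 ha) is drawn, and
#' every pixel whose centre falls inside the disc becomes a training sample
#' with the point's label. Pixels claimed by points of conflicting labels
#' are dropped; duplicates under one label are de-duplicated.
#'
#' @param points data.frame with `x`, `y` (metres) and `label` columns;
#'   labels must come from [landcoverClasses()].
#' @param gridDim `c(rows, cols)` of the scene grid.
#' @param pixelSize Pixel edge length in metres.
#' @param bufferAreaHa Disc area in hectares (default 1).
#' @return data.frame with `row`, `col`, `label` (one row per pixel).
#' @export
rasterizeTraining <- function(points, gridDim, pixelSize = 30,
                              bufferAreaHa = 1.0) {
  assertThat(all(c("x", "y", "label") %in% names(points)),
             "points need x, y and label columns")
  assertThat(all(points$label %in% landcoverClasses()),
             "labels must be wet_soil, dry_soil or water")
  nr <- gridDim[1]; nc <- gridDim[2]
  inGrid <- points$x >= 0 & points$x <= nc * pixelSize &
            points$y >= 0 & points$y <= nr * pixelSize
  assertThat(all(inGrid), "training point outside the grid")
  radius <- sqrt(1e4 * bufferAreaHa / pi)
  rpx <- ceiling(radius / pixelSize)
  samples <- do.call(rbind, lapply(seq_len(nrow(points)), function(i) {
    pcol <- points$x[i] / pixelSize + 0.5  # fractional col of the point
    prow <- points$y[i] / pixelSize + 0.5
    cols <- max(1, floor(pcol - rpx)):min(nc, ceiling(pcol + rpx))
    rows <- max(1, floor(prow - rpx)):min(nr, ceiling(prow + rpx))
    grid <- expand.grid(row = rows, col = cols)
    dx <- (grid$col - 0.5) * pixelSize - points$x[i]
    dy <- (grid$row - 0.5) * pixelSize - points$y[i]
    keep <- sqrt(dx^2 + dy^2) <= radius
    if (!any(keep)) return(NULL)
    data.frame(grid[keep, , drop = FALSE], label = points$label[i],
               stringsAsFactors = FALSE)
  }))
  assertThat(!is.null(samples) && nrow(samples) > 0,
             "no pixels fell inside any training buffer")
  key <- paste(samples$row, samples$col)
  nLabels <- tapply(samples$label, key, function(x) length(unique(x)))
  conflicted <- names(nLabels)[nLabels > 1]
  samples <- samples[!(key %in% conflicted), , drop = FALSE]
  samples <- samples[!duplicated(paste(samples$row, samples$col, samples$label)), ]
  assertThat(nrow(samples) > 0,
             "all training pixels were dropped by label conflicts")
  rownames(samples) <- NULL
  samples
}

#' Extract predictor features at sample pixels
#'
#' @param stack A `[rows, cols, 7]` [predictorStack()] array.
#' @param samples data.frame with `row`, `col` (and optionally `label`).
#' @return The samples with one column per predictor appended; rows with any
#'   null feature are dropped (null features exclude a pixel from training
#'   and prediction).
#' @export
extractFeatures <- function(stack, samples) {
  nr <- dim(stack)[1]
  feat <- vapply(seq_len(7L), function(k) {
    stack[, , k][(samples$col - 1L) * nr + samples$row]
  }, numeric(nrow(samples)))
  feat <- matrix(feat, nrow = nrow(samples),
                 dimnames = list(NULL, predictorNames()))
  out <- cbind(samples, as.data.frame(feat))
  out[stats::complete.cases(feat), , drop = FALSE]
}

#' Train the random-forest land-cover model
#'
#' An ensemble of decision trees (randomForest) on the seven predictors.
#' Deterministic given the seed; out-of-bag accuracy is attached as
#' `attr(model, "oobAccuracy")`.
#'
#' @param samples data.frame from [extractFeatures()] with a `label` column
#'   and the seven predictor columns.
#' @param nTrees Number of trees (default 200).
#' @param seed RNG seed (mandatory: determinism over tuning).
#' @return A `randomForest` model.
#' @export
trainLandcoverModel <- function(samples, nTrees = 200L, seed) {
  assertThat(!missing(seed), "a seed is required")
  assertThat(all(predictorNames() %in% names(samples)),
             "samples lack predictor columns (run extractFeatures first)")
  labs <- factor(samples$label, levels = landcoverClasses())
  labs <- droplevels(labs)
  assertThat(nlevels(labs) >= 2,
             "training samples contain a single class; at least two are required")
  x <- samples[, predictorNames()]
  assertThat(all(is.finite(as.matrix(x))), "features must be finite")
  model <- withr::with_seed(as.integer(seed),
    randomForest::randomForest(x = x, y = labs, ntree = nTrees))
  attr(model, "oobAccuracy") <- 1 - tail(model$err.rate[, "OOB"], 1)
  model
}

#' Classify every loss pixel into wet soil, dry soil or water
#'
#' Prediction is restricted to the loss mask; pixels outside it are `NA`,
#' and loss pixels whose predictors are null are `"unclassified"`.
#'
#' @param model Model from [trainLandcoverModel()].
#' @param stack A `[rows, cols, 7]` [predictorStack()] array.
#' @param lossMask A [LossMask-class] (or logical matrix).
#' @param compositeWindow Date window recorded on the map (metadata).
#' @return A [LandCoverMap-class].
#' @export
classifyLossPixels <- function(model, stack, lossMask,
                               compositeWindow = c("2014-01", "2018-12")) {
  loss <- if (is(lossMask, "LossMask")) lossRaster(lossMask) else lossMask
  assertThat(identical(dim(loss), dim(stack)[1:2]),
             "stack and loss mask grids differ")
  nr <- nrow(loss)
  cells <- which(loss)
  out <- matrix(NA_character_, nr, ncol(loss))
  if (length(cells)) {
    feat <- vapply(seq_len(7L), function(k) stack[, , k][cells],
                   numeric(length(cells)))
    feat <- matrix(feat, nrow = length(cells),
                   dimnames = list(NULL, predictorNames()))
    ok <- stats::complete.cases(feat)
    out[cells] <- "unclassified"
    if (any(ok)) {
      pred <- predict(model, as.data.frame(feat[ok, , drop = FALSE]))
      out[cells[ok]] <- as.character(pred)
    }
  }
  new("LandCoverMap", classRaster = out,
      compositeWindow = parseWindow(compositeWindow))
}
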