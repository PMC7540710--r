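# NDVI cumulative-anomaly loss detection: reference median (1998-2001),
# per-observation differencing over 2001-2016, normalisation by valid
# observation count, thresholding within the baseline mangrove extent, and
# epoch dating by re-running the anomaly on each epoch's window.

#' Build the reference-period median NDVI raster
#'
#' Per-pixel median of the valid NDVI observations inside the reference
#' window (default January 1998 .. December 2001). Pixel stacks with fewer
#' than `minQuality` valid observations are excluded (set to `NA`); the
#' quality rule applies to the reference window only.
#'
#' @param series A [ReflectanceSeries-class].
#' @param refWindow `c(start, end)` (default `c("1998-01", "2001-12")`).
#' @param minQuality Minimum valid observations (default 10).
#' @return A [ReferenceRaster-class].
#' @export
buildReference <- function(series, refWindow = c("1998-01", "2001-12"),
                           minQuality = 10L) {
  idx <- windowIndices(series@dates, refWindow)
  assertThat(length(idx) > 0, "reference window contains no acquisition dates")
  nd <- ndviSeries(series, refWindow)
  st <- stackMedian(nd)
  med <- st$median
  med[st$count < minQuality] <- NA_real_
  new("ReferenceRaster", medianNdvi = med, qualityCount = st$count,
      minQuality = as.integer(minQuality), window = parseWindow(refWindow))
}

#' Cumulative NDVI anomaly over an observation window
#'
#' Each observation's NDVI is differenced against the reference median;
#' summing the differences gives the cumulative anomaly, and dividing by the
#' number of non-null observations gives the mean NDVI change relative to the
#' reference. Cloud-masked observations are skipped from both the sum and the
#' count; pixels with a null reference or no valid observation are null.
#'
#' @param series A [ReflectanceSeries-class].
#' @param reference A [ReferenceRaster-class].
#' @param obsWindow `c(start, end)` (default `c("2001-01", "2016-12")`).
#' @return An [AnomalyStack-class].
#' @export
cumulativeAnomaly <- function(series, reference,
                              obsWindow = c("2001-01", "2016-12")) {
  idx <- windowIndices(series@dates, obsWindow)
  assertThat(length(idx) > 0, "observation window is disjoint from the series dates")
  nd <- ndviSeries(series, obsWindow)
  d <- dim(nd)
  m <- matrix(nd, d[1] * d[2], d[3])
  diffm <- m - as.vector(reference@medianNdvi)
  cnt <- rowSums(!is.na(diffm))
  cum <- rowSums(diffm, na.rm = TRUE)
  refNull <- is.na(as.vector(reference@medianNdvi))
  cum[refNull | cnt == 0L] <- NA_real_
  mc <- cum / cnt
  mc[refNull | cnt == 0L] <- NA_real_
  cnt[refNull] <- 0L
  new("AnomalyStack",
      cumulative = matrix(cum, d[1], d[2]),
      obsCount = matrix(as.integer(cnt), d[1], d[2]),
      meanChange = matrix(mc, d[1], d[2]),
      window = parseWindow(obsWindow))
}

#' Threshold the mean NDVI change into a loss mask
#'
#' A pixel is permanent loss iff its mean change is at or below the
#' threshold (inclusive), it lies inside the baseline mangrove extent, and
#' its anomaly is non-null. Lowering the threshold magnitude can only add
#' loss pixels (monotonicity).
#'
#' @param anomaly An [AnomalyStack-class].
#' @param mangroveMask Logical matrix, baseline mangrove extent.
#' @param threshold Negative change threshold (default -0.2).
#' @return A [LossMask-class] with all epoch labels `"none"`.
#' @export
#' @examples
#' # mean change of -0.25 inside the mask is loss; -0.19 is not
detectLoss <- function(anomaly, mangroveMask, threshold = -0.2) {
  assertThat(threshold < 0, "threshold must be negative")
  assertThat(identical(dim(anomaly@meanChange), dim(mangroveMask)),
             "anomaly and mask grids differ")
  mc <- anomaly@meanChange
  loss <- !is.na(mc) & mc <= threshold & mangroveMask
  new("LossMask", loss = loss,
      epochLabel = matrix("none", nrow(loss), ncol(loss)),
      threshold = threshold, epochs = list())
}

checkEpochTiling <- function(epochs) {
  assertThat(length(epochs) >= 1, "no epochs given")
  starts <- as.Date(vapply(epochs, function(w) format(parseWindow(w)[1]), ""))
  ends <- as.Date(vapply(epochs, function(w) format(parseWindow(w)[2]), ""))
  ord <- order(starts)
  starts <- starts[ord]; ends <- ends[ord]
  gaps <- starts[-1] - ends[-length(ends)]
  assertThat(all(gaps == 1),
             "epoch windows must tile the full period without gaps or overlap")
  ord
}

#' Date loss pixels to epochs
#'
#' For each epoch the anomaly analysis is re-run on that epoch's observation
#' window (clipped to the overall observation period). A total-loss pixel is
#' assigned the earliest epoch whose mean change crosses the threshold;
#' total-loss pixels that cross in no single epoch get the epoch with the
#' most negative mean change (so the epoch masks always partition the total
#' loss mask). Loss is only dated within the total 2000--2016 loss extent:
#' non-loss pixels keep label `"none"`.
#'
#' @param series A [ReflectanceSeries-class].
#' @param reference A [ReferenceRaster-class].
#' @param totalLoss The [LossMask-class] from [detectLoss()] on the full
#'   window.
#' @param epochs Named list of epoch windows (default [defaultEpochs()]);
#'   must tile the full period.
#' @param obsWindow Overall observation window the epochs are clipped to.
#' @return A [LossMask-class] with epoch labels set.
#' @export
assignEpochs <- function(series, reference, totalLoss,
                         epochs = defaultEpochs(),
                         obsWindow = c("2001-01", "2016-12")) {
  checkEpochTiling(epochs)
  obs <- parseWindow(obsWindow)
  loss <- totalLoss@loss
  thr <- totalLoss@threshold
  mcPerEpoch <- lapply(epochs, function(w) {
    w <- parseWindow(w)
    clipped <- c(max(w[1], obs[1]), min(w[2], obs[2]))
    assertThat(clipped[1] <= clipped[2], "epoch window outside the observation period")
    meanChange(cumulativeAnomaly(series, reference, clipped))
  })
  label <- matrix("none", nrow(loss), ncol(loss))
  assigned <- matrix(FALSE, nrow(loss), ncol(loss))
  for (e in names(epochs)) {
    hit <- loss & !assigned & !is.na(mcPerEpoch[[e]]) & mcPerEpoch[[e]] <= thr
    label[hit] <- e
    assigned <- assigned | hit
  }
  rest <- which(loss & !assigned)
  if (length(rest)) {
    mcMat <- vapply(mcPerEpoch, function(m) m[rest], numeric(length(rest)))
    mcMat <- matrix(mcMat, nrow = length(rest))
    mcMat[is.na(mcMat)] <- Inf
    label[rest] <- names(epochs)[max.col(-mcMat, ties.method = "first")]
  }
  new("LossMask", loss = loss, epochLabel = label, threshold = thr,
      epochs = lapply(epochs, parseWindow))
}
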