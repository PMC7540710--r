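# The seven spectral predictors used by the land-cover classifier. Formulas
# are the standard literature definitions; "ratio54"/"ratio35" follow
# Landsat-5/7 band numbering (band5 = SWIR1, band4 = NIR, band3 = red), and
# the bare "surface reflectance" predictor is the NIR band value (the band
# with the strongest vegetation/water contrast).

#' Names of the seven predictor variables
#' @return Character vector: ndvi, ndmi, mndwi, gcvi, surface_reflectance,
#'   ratio54, ratio35.
#' @export
predictorNames <- function() {
  c("ndvi", "ndmi", "mndwi", "gcvi", "surface_reflectance",
    "ratio54", "ratio35")
}

normDiff <- function(a, b) {
  den <- a + b
  v <- (a - b) / den
  v[!is.na(den) & den == 0] <- NA_real_
  v
}

bandRatio <- function(num, den) {
  v <- num / den
  v[!is.na(den) & den == 0] <- NA_real_
  v[is.infinite(v)] <- NA_real_
  v
}

#' Compute one spectral index from a six-band raster
#'
#' * `ndvi  = (NIR - red) / (NIR + red)`
#' * `ndmi  = (NIR - SWIR1) / (NIR + SWIR1)`
#' * `mndwi = (green - SWIR1) / (green + SWIR1)`
#' * `gcvi  = NIR / green - 1`
#' * `surface_reflectance = NIR` (passthrough)
#' * `ratio54 = SWIR1 / NIR`
#' * `ratio35 = red / SWIR1`
#'
#' Zero denominators yield `NA` at that pixel (not an error), mirroring
#' QA-style masking; `NA` bands propagate.
#'
#' @param bands Array `[rows, cols, 6]` in [bandNames()] order (a
#'   [bandStack()] or [buildComposite()] result), or a named 6-vector.
#' @param indexName One of [predictorNames()].
#' @return Numeric matrix (or scalar for vector input).
#' @export
#' @examples
#' v <- setNames(c(.05, .10, .10, .40, .20, .10), bandNames())
#' computeIndex(v, "ndvi")   # (0.4 - 0.1) / (0.4 + 0.1) = 0.6
#' computeIndex(v, "ratio54") # 0.2 / 0.4 = 0.5
computeIndex <- function(bands, indexName) {
  indexName <- match.arg(indexName, predictorNames())
  if (is.null(dim(bands))) {
    b <- function(nm) unname(bands[nm])
  } else {
    assertThat(length(dim(bands)) == 3 && dim(bands)[3] == 6L,
               "bands must be a [rows, cols, 6] array")
    b <- function(nm) bands[, , match(nm, bandNames())]
  }
  switch(indexName,
    ndvi = normDiff(b("nir"), b("red")),
    ndmi = normDiff(b("nir"), b("swir1")),
    mndwi = normDiff(b("green"), b("swir1")),
    gcvi = bandRatio(b("nir"), b("green")) - 1,
    surface_reflectance = b("nir"),
    ratio54 = bandRatio(b("swir1"), b("nir")),
    ratio35 = bandRatio(b("red"), b("swir1"))
  )
}

#' Stack of all seven predictors
#'
#' Nulls propagate jointly: if any input band is `NA` at a pixel (or any
#' index is undefined there), all seven features are `NA` at that pixel, so
#' a pixel is either fully featured or excluded from training/prediction.
#'
#' @param composite Array `[rows, cols, 6]` in [bandNames()] order.
#' @return Array `[rows, cols, 7]` with [predictorNames()] as the third
#'   dimnames.
#' @export
predictorStack <- function(composite) {
  assertThat(length(dim(composite)) == 3 && dim(composite)[3] == 6L,
             "composite must be a [rows, cols, 6] array")
  d <- dim(composite)
  out <- array(NA_real_, c(d[1], d[2], 7L),
               dimnames = list(NULL, NULL, predictorNames()))
  for (nm in predictorNames()) out[, , nm] <- computeIndex(composite, nm)
  anyNA <- apply(is.na(out), c(1, 2), any)
  for (k in seq_len(7L)) {
    sl <- out[, , k]
    sl[anyNA] <- NA_real_
    out[, , k] <- sl
  }
  out
}
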