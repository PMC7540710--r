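# Driver attribution: fixed per-land-cover decision rules (recursive
# partition) over ancillary layers. Spectral classes are ambiguous between
# land uses (aquaculture vs coastal water, agriculture vs mudflat,
# impervious vs sand), so connectivity and proximity evidence disambiguates:
#   water    -> ocean-connected ? ER : CM
#   wet soil -> near agriculture ? CM
#               : near shoreline ? ER
#               : near any infrastructure ? NPC : EWE
#   dry soil -> near settlement/roads ? ST
#               : near any infrastructure ? NPC : EWE
# Rule order is fixed and first match wins; all distances live in the
# RuleConfig, never in code.

#' Attribution rule parameters
#'
#' @param connectivity Pixel connectivity for the ocean-connected test, 4 or
#'   8 (default 8).
#' @param dSettlement Buffer around settlement and roads for the settlement
#'   call, metres (default 500).
#' @param dAgriculture Buffer around the agriculture/aquaculture extent for
#'   the commodities call on wet soil, metres (default 500).
#' @param dInfrastructure Human-influence radius separating non-productive
#'   conversion from extreme-weather dieback, metres (default 1000).
#' @param shorelineBand Distance from the ocean within which wet-soil loss is
#'   called erosion (tidal mudflat), metres (default 300).
#' @return A validated list of class `ruleConfig`.
#' @export
ruleConfig <- function(connectivity = 8, dSettlement = 500,
                       dAgriculture = 500, dInfrastructure = 1000,
                       shorelineBand = 300) {
  assertThat(connectivity %in% c(4, 8), "connectivity must be 4 or 8")
  dists <- c(dSettlement, dAgriculture, dInfrastructure, shorelineBand)
  assertThat(all(dists >= 0), "all rule distances must be >= 0")
  structure(list(connectivity = as.integer(connectivity),
                 dSettlement = dSettlement, dAgriculture = dAgriculture,
                 dInfrastructure = dInfrastructure,
                 shorelineBand = shorelineBand),
            class = "ruleConfig")
}

#' Water pixels connected to the open ocean
#'
#' Flood fill from the ocean seed region through the water mask. A water
#' pixel is ocean-connected iff its connected component (4- or
#' 8-connectivity) contains an ocean pixel. Distinguishes eroded coastline
#' (connected) from enclosed aquaculture basins (not connected).
#'
#' @param waterMask Logical matrix of water pixels.
#' @param oceanMask Logical matrix of the open-ocean seed region.
#' @param connectivity 4 or 8 (default 8).
#' @return Logical matrix, `TRUE` where water is ocean-connected.
#' @export
oceanConnected <- function(waterMask, oceanMask, connectivity = 8) {
  assertThat(identical(dim(waterMask), dim(oceanMask)), "grids differ")
  assertThat(connectivity %in% c(4, 8), "connectivity must be 4 or 8")
  nr <- nrow(waterMask); nc <- ncol(waterMask)
  medium <- waterMask | oceanMask
  reach <- oceanMask & medium
  offsets <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 8) {
    offsets <- c(offsets, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
  }
  repeat {
    grown <- reach
    for (o in offsets) {
      rs <- max(1, 1 + o[1]):min(nr, nr + o[1])
      cs <- max(1, 1 + o[2]):min(nc, nc + o[2])
      sh <- matrix(FALSE, nr, nc)
      sh[rs, cs] <- reach[rs - o[1], cs - o[2]]
      grown <- grown | (sh & medium)
    }
    if (identical(grown, reach)) break
    reach <- grown
  }
  reach & waterMask
}

#' Euclidean proximity buffer around a mask
#'
#' `TRUE` wherever the pixel centre lies within `distance` metres of the
#' centre of any `TRUE` pixel of `mask` (centre-to-centre Euclidean
#' distance, via an exact distance transform). `distance = 0` returns the
#' mask itself.
#'
#' @param mask Logical matrix.
#' @param distance Buffer distance in metres (>= 0).
#' @param pixelSize Pixel edge length in metres.
#' @return Logical matrix.
#' @export
proximity <- function(mask, distance, pixelSize = 30) {
  assertThat(distance >= 0, "distance must be >= 0")
  if (!any(mask)) return(mask & FALSE)
  d <- EBImage::distmap(1 - mask, metric = "euclidean")
  matrix(as.numeric(d) * pixelSize <= distance, nrow(mask), ncol(mask))
}

#' Attribute every classified loss pixel to a proximate driver
#'
#' Applies the per-land-cover decision rules (see the module header above;
#' first match wins, visit-order independent). Unclassified land-cover
#' pixels become `"unattributed"` and are excluded from area accounting.
#'
#' @param landcover A [LandCoverMap-class].
#' @param ancillary An [AncillaryLayers-class].
#' @param rules A [ruleConfig()] (default rules).
#' @param pixelSize Pixel edge length in metres.
#' @return A [DriverMap-class] (epoch labels unset; see [cutByEpoch()]).
#' @export
attributeDrivers <- function(landcover, ancillary, rules = ruleConfig(),
                             pixelSize = 30) {
  lc <- classRaster(landcover)
  nr <- nrow(lc); nc <- ncol(lc)
  ocean <- ancillary@oceanMask
  infra <- ancillary@roads | ancillary@settlement | ancillary@agriculture
  nearSettle <- proximity(ancillary@settlement | ancillary@roads,
                          rules$dSettlement, pixelSize)
  nearAgri <- proximity(ancillary@agriculture, rules$dAgriculture, pixelSize)
  nearInfra <- proximity(infra, rules$dInfrastructure, pixelSize)
  nearShore <- proximity(ocean, rules$shorelineBand, pixelSize)

  driver <- matrix(NA_character_, nr, nc)
  isWater <- !is.na(lc) & lc == "water"
  conn <- oceanConnected(isWater, ocean, rules$connectivity)
  driver[isWater] <- ifelse(conn[isWater], "ER", "CM")

  isWet <- !is.na(lc) & lc == "wet_soil"
  driver[isWet] <- ifelse(nearAgri[isWet], "CM",
                    ifelse(nearShore[isWet], "ER",
                      ifelse(nearInfra[isWet], "NPC", "EWE")))

  isDry <- !is.na(lc) & lc == "dry_soil"
  driver[isDry] <- ifelse(nearSettle[isDry], "ST",
                     ifelse(nearInfra[isDry], "NPC", "EWE"))

  unc <- !is.na(lc) & lc == "unclassified"
  driver[unc] <- "unattributed"
  if (any(unc))
    message(sum(unc), " loss pixel(s) unattributed (null predictors)")

  new("DriverMap", driver = driver,
      epochLabel = matrix("none", nr, nc))
}

#' Cut the driver map by epoch
#'
#' Records the per-pixel epoch labels so each epoch's driver map is the
#' restriction of the full map to that epoch's loss extent (driver maps are
#' never regenerated per epoch).
#'
#' @param driverMap A [DriverMap-class].
#' @param lossMask A [LossMask-class] with epoch labels assigned (or a
#'   character matrix of epoch labels).
#' @return The [DriverMap-class] with epoch labels set.
#' @export
cutByEpoch <- function(driverMap, lossMask) {
  lab <- if (is(lossMask, "LossMask")) epochRaster(lossMask) else lossMask
  assertThat(identical(dim(lab), dim(driverMap@driver)), "grids differ")
  new("DriverMap", driver = driverMap@driver, epochLabel = lab)
}

#' Restriction of a driver map to one epoch
#'
#' @param driverMap A [DriverMap-class] after [cutByEpoch()].
#' @param epoch One of [lossEpochs()].
#' @return Character matrix: driver codes on that epoch's pixels, `NA`
#'   elsewhere.
#' @export
epochCut <- function(driverMap, epoch) {
  epoch <- match.arg(epoch, lossEpochs())
  out <- driverMap@driver
  out[driverMap@epochLabel != epoch] <- NA_character_
  out
}

#' Pixel counts (and areas) per driver, optionally per epoch
#'
#' @param driverMap A [DriverMap-class].
#' @param pixelAreaHa Pixel area in hectares (default 0.09 for 30 m).
#' @param byEpoch Split counts by epoch label (requires [cutByEpoch()]).
#' @return data.frame with `driver`, optional `epoch`, `pixels`, `area_ha`;
#'   "unattributed" pixels are reported separately and excluded from driver
#'   areas.
#' @export
driverAreas <- function(driverMap, pixelAreaHa = 0.09, byEpoch = FALSE) {
  drv <- driverMap@driver
  keep <- !is.na(drv)
  if (!byEpoch) {
    tab <- table(factor(drv[keep], levels = c(lossDrivers(), "unattributed")))
    data.frame(driver = names(tab), pixels = as.integer(tab),
               area_ha = as.integer(tab) * pixelAreaHa,
               stringsAsFactors = FALSE)
  } else {
    ep <- driverMap@epochLabel
    tab <- table(
      driver = factor(drv[keep], levels = c(lossDrivers(), "unattributed")),
      epoch = factor(ep[keep], levels = c(lossEpochs(), "none"))
    )
    df <- as.data.frame(tab, stringsAsFactors = FALSE)
    names(df)[3] <- "pixels"
    df$area_ha <- df$pixels * pixelAreaHa
    df
  }
}
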