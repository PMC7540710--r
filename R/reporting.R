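# Regional / epoch / driver aggregation arithmetic: area tables, integer
# percentage shares, the anthropogenic vs natural split, annualised epoch
# rates, percent declines and primary-driver labels. All outputs are pure
# functions of the area table. Integer shares use round-half-away-from-zero;
# declines are returned at full precision together with rounded and
# truncated integer forms (published figures mix the two conventions).

#' Per-region, per-epoch, per-driver area summary
#'
#' Counts attributed loss pixels per (region, epoch, driver) and converts to
#' km2. Region membership is by pixel centre (point-in-polygon); pixels
#' outside every polygon go to region `"unassigned"`. Overlapping polygons
#' are an error.
#'
#' @param driverMap A [DriverMap-class] after [cutByEpoch()].
#' @param regions Named list of closed polygons (two-column x/y matrices in
#'   scene metre coordinates), e.g. `ancillaryLayers(scene)@regions`.
#' @param pixelSize Pixel edge length in metres.
#' @return data.frame (region, epoch, driver, pixels, area_km2, share_pct,
#'   rate_km2_yr, anthropogenic); shares are of the region-epoch total.
#' @export
regionalSummary <- function(driverMap, regions, pixelSize = 30) {
  drv <- driverMap@driver
  ep <- driverMap@epochLabel
  keep <- which(!is.na(drv) & drv != "unattributed")
  assertThat(length(keep) > 0, "driver map has no attributed pixels")
  nr <- nrow(drv)
  x <- ((keep - 1L) %/% nr + 1L - 0.5) * pixelSize
  y <- ((keep - 1L) %% nr + 1L - 0.5) * pixelSize
  pts <- cbind(x, y)
  region <- rep("unassigned", length(keep))
  for (nm in names(regions)) {
    inside <- mgcv::in.out(regions[[nm]], pts)
    assertThat(!any(inside & region != "unassigned"),
               paste("overlapping region polygons at", nm))
    region[inside] <- nm
  }
  tab <- table(region = region,
               epoch = factor(ep[keep], levels = c(lossEpochs(), "none")),
               driver = factor(drv[keep], levels = lossDrivers()))
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(df)[4] <- "pixels"
  df <- df[df$pixels > 0, , drop = FALSE]
  df$area_km2 <- df$pixels * (pixelSize / 1000)^2
  totals <- tapply(df$area_km2, paste(df$region, df$epoch), sum)
  df$share_pct <- as.integer(roundHalfAway(
    100 * df$area_km2 / totals[paste(df$region, df$epoch)]))
  yrs <- epochYears()
  df$rate_km2_yr <- ifelse(df$epoch %in% names(yrs),
                           df$area_km2 / yrs[df$epoch], NA_real_)
  df$anthropogenic <- df$driver %in% anthropogenicDrivers()
  rownames(df) <- NULL
  df
}

#' Nominal epoch lengths in years
#' @return `c(loss2005 = 5, loss2010 = 5, loss2016 = 6)`.
#' @export
epochYears <- function() c(loss2005 = 5, loss2010 = 5, loss2016 = 6)

#' Integer percentage shares per driver
#'
#' `share_d = round(100 * area_d / total)`, rounding half away from zero.
#'
#' @param areas Named numeric vector of per-driver areas (any unit).
#' @return Named integer vector of percentages.
#' @export
#' @examples
#' driverShares(c(CM = 1596, ER = 912, NPC = 398, ST = 96, EWE = 361))
driverShares <- function(areas) {
  assertThat(sum(areas) > 0, "total area must be positive")
  setNames(as.integer(roundHalfAway(100 * areas / sum(areas))), names(areas))
}

#' Anthropogenic vs natural split
#'
#' Anthropogenic = CM + ST + NPC; natural = ER + EWE.
#'
#' @param areas Named per-driver areas with names in [lossDrivers()].
#' @return List with `anthropogenic`/`natural` totals (area units) and
#'   integer `shares` (percent).
#' @export
#' @examples
#' anthroNaturalSplit(c(CM = 1596, ER = 912, NPC = 398, ST = 96, EWE = 361))
anthroNaturalSplit <- function(areas) {
  a <- sum(areas[names(areas) %in% anthropogenicDrivers()])
  n <- sum(areas[!(names(areas) %in% anthropogenicDrivers())])
  list(anthropogenic = a, natural = n,
       shares = driverShares(c(anthropogenic = a, natural = n)))
}

#' Annualised loss rates per epoch
#'
#' Rate = area / nominal epoch length.
#'
#' @param areasPerEpoch Named numeric, areas keyed by epoch label.
#' @param years Named epoch lengths (default [epochYears()]).
#' @return Named numeric rates (area units per year).
#' @export
epochRates <- function(areasPerEpoch, years = epochYears()) {
  unknown <- setdiff(names(areasPerEpoch), names(years))
  assertThat(length(unknown) == 0,
             paste("unknown epoch:", paste(unknown, collapse = ", ")))
  assertThat(all(years[names(areasPerEpoch)] > 0), "epoch years must be > 0")
  areasPerEpoch / years[names(areasPerEpoch)]
}

#' Percent decline between a first and last epoch area
#'
#' @param firstArea,lastArea Areas (first must be > 0).
#' @return List: `percent` (full precision `100 * (first - last) / first`),
#'   `rounded` (half away from zero) and `truncated` (fractional part
#'   dropped) integer forms.
#' @export
#' @examples
#' percentChange(443, 178)   # 59.8 -> rounded 60
#' percentChange(1186, 314)  # 73.5 -> truncated 73
percentChange <- function(firstArea, lastArea) {
  assertThat(firstArea > 0, "first-epoch area must be positive")
  p <- 100 * (firstArea - lastArea) / firstArea
  list(percent = p, rounded = as.integer(roundHalfAway(p)),
       truncated = as.integer(trunc(p)))
}

#' Primary driver of an area table
#'
#' Argmax area; ties broken by the fixed precedence ER < CM < ST < NPC < EWE
#' (the order of [lossDrivers()]).
#'
#' @param areas Named per-driver areas, at least one positive.
#' @return Single driver code.
#' @export
primaryDriver <- function(areas) {
  assertThat(any(areas > 0), "all areas are zero")
  ord <- intersect(lossDrivers(), names(areas))
  areas <- areas[ord]
  ord[which.max(areas)]
}
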