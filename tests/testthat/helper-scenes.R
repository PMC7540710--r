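# Shared fixtures: a compact 80 x 80 coastal scene with one event per driver,
# scaled from the default study layout so end-to-end runs stay fast.

smallSceneConfig <- function(seed = 1L, cloudFraction = 0.3, noiseSigma = 0.02,
                             events = NULL, layout = NULL) {
  nr <- 80L; nc <- 80L
  if (is.null(layout)) layout <- list(
    ocean = c(1, nr, 1, 8),
    mangrove = c(1, nr, 9, 48),
    roads = list(c(1, 36, 56, 56)),
    settlement = list(c(1, 16, 49, 54)),
    agriculture = list(c(60, 72, 64, 76)),
    regions = list(west = c(1, nr, 1, 40), east = c(1, nr, 41, nc))
  )
  if (is.null(events)) events <- list(
    eventSpec("ER", areaHa = 14.4, date = "2002-03-15", anchor = 1, width = nr),
    eventSpec("CM", areaHa = 10.8, date = "2002-09-15", anchor = c(24, 25), width = 8),
    eventSpec("ST", areaHa = 10.8, date = "2006-03-15", anchor = c(1, 41), width = 8),
    eventSpec("NPC", areaHa = 10.8, date = "2006-09-15", anchor = c(20, 43), width = 6),
    eventSpec("EWE", areaHa = 10.8, date = "2010-06-15", anchor = c(56, 19), width = 8)
  )
  sceneConfig(nr, nc, layout = layout, events = events, seed = seed,
              cloudFraction = cloudFraction, noiseSigma = noiseSigma)
}

# a scene with no conversion events (stationary mangrove coast)
quietSceneConfig <- function(seed = 5L, cloudFraction = 0.2, noiseSigma = 0.02) {
  smallSceneConfig(seed = seed, cloudFraction = cloudFraction,
                   noiseSigma = noiseSigma, events = list())
}

# hand-built noise/cloud-free series: one pixel class flips at a known date
# index; endmember NDVI values are mangrove 0.75 and wet soil 0.15
flipSeries <- function(nDates = 16L, flipAt = 9L, nr = 32L, nc = 32L,
                       from = "mangrove", to = "wet_soil") {
  em <- defaultEndmembers()
  cfg <- sceneConfig(nr, nc,
    dates = seq(as.Date("2001-01-01"), by = "1 month", length.out = nDates),
    cloudFraction = 0, noiseSigma = 0, endmembers = em,
    layout = list(ocean = c(1, nr, 1, 2), mangrove = c(1, nr, 3, nc),
                  roads = list(), settlement = list(), agriculture = list(),
                  regions = list(all = c(1, nr, 1, nc))),
    events = list(), seed = 1L)
  scene <- generateScene(cfg)
  s <- scene@series
  s@classAfter[10, 10] <- match(to, rownames(em))
  s@convIdx[10, 10] <- flipAt
  s
}
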