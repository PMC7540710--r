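# Stratified ("good-practice") accuracy assessment and area estimation from
# an error matrix of validation samples, with the map classes as strata.
# Estimated cell proportions are area-weighted: p_ij = W_i * n_ij / n_i.
# where W_i is the mapped area proportion of class i. Overall, user's and
# producer's accuracies with variances and 95% CIs, and reference-corrected
# class areas with standard errors, follow the standard stratified
# estimators. Count-based (unweighted) accuracies are exposed alongside for
# comparison with conventionally printed per-class numbers.

#' Proportional sample allocation with largest-remainder rounding
#'
#' Allocates `nTotal` validation samples to classes proportionally to their
#' mapped areas. Integerisation uses largest-remainder rounding (ties broken
#' by class order), then every class is guaranteed at least one sample by
#' taking from the largest allocations.
#'
#' @param classAreas Named positive numeric vector of mapped areas.
#' @param nTotal Total samples (>= number of classes).
#' @return Named integer vector summing to `nTotal`, all entries >= 1.
#' @export
#' @examples
#' allocateSamples(c(a = 50, b = 50), 10)          # 5, 5
#' allocateSamples(c(a = 1, b = 1, c = 1), 10)     # sums to 10, max-min <= 1
allocateSamples <- function(classAreas, nTotal) {
  assertThat(all(classAreas > 0) && length(classAreas) >= 1,
             "class areas must be positive")
  k <- length(classAreas)
  assertThat(nTotal >= k, "need at least one sample per class")
  quota <- nTotal * classAreas / sum(classAreas)
  counts <- floor(quota)
  rem <- nTotal - sum(counts)
  if (rem > 0) {
    ord <- order(-(quota - counts), seq_len(k))
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1
  }
  while (any(counts == 0)) {
    counts[which.max(counts)] <- max(counts) - 1
    counts[which(counts == 0)[1]] <- 1
  }
  setNames(as.integer(counts), names(classAreas))
}

#' Cross-tabulate map and reference labels into an error matrix
#'
#' @param mapLabels,referenceLabels Paired label vectors (same length).
#' @param mapAreas Named positive numeric vector of mapped class areas; the
#'   names define the class set and row/column order.
#' @return An [ErrorMatrix-class].
#' @export
buildErrorMatrix <- function(mapLabels, referenceLabels, mapAreas) {
  classes <- names(mapAreas)
  assertThat(!is.null(classes), "mapAreas must be named by class")
  assertThat(length(mapLabels) == length(referenceLabels),
             "label vectors differ in length")
  bad <- setdiff(unique(c(mapLabels, referenceLabels)), classes)
  assertThat(length(bad) == 0,
             paste("labels outside the class set:", paste(bad, collapse = ", ")))
  ct <- table(factor(mapLabels, levels = classes),
              factor(referenceLabels, levels = classes))
  ct <- matrix(as.integer(ct), length(classes), length(classes),
               dimnames = list(classes, classes))
  new("ErrorMatrix", countsTable = ct, areas = mapAreas[classes])
}

emProportions <- function(em) {
  ct <- matrixCounts(em)
  ni <- rowSums(ct)
  W <- classAreas(em) / sum(classAreas(em))
  list(ct = ct, ni = ni, W = W, phat = W * ct / ni)
}

#' Accuracies with variances and 95% confidence intervals
#'
#' Area-weighted estimates: `OA = sum_j p_jj`, `UA_i = p_ii / W_i`,
#' `PA_j = p_jj / p_.j` with the standard stratified variance estimators;
#' 95% CIs are `estimate +/- 1.96 * SE`, clipped to `[0, 1]`. Raw
#' count-based accuracies (`*_count` columns) are reported alongside.
#'
#' @param em An [ErrorMatrix-class]; every map class needs at least one
#'   sample (two for a finite variance).
#' @return List of class `accuracyReport`: `$overall` (one-row data.frame
#'   with `oa`, `se`, `lo`, `hi`, `oa_count`) and `$perClass` (per-class
#'   `ua`, `ua_se`, `ua_lo`, `ua_hi`, `pa`, `pa_se`, `pa_lo`, `pa_hi`,
#'   `ua_count`, `pa_count`).
#' @export
accuracyReport <- function(em) {
  p <- emProportions(em)
  empty <- names(which(p$ni == 0))
  assertThat(length(empty) == 0,
             paste("map class with no samples:", paste(empty, collapse = ", ")))
  ct <- p$ct; ni <- p$ni; W <- p$W; phat <- p$phat
  k <- nrow(ct)
  diagp <- diag(phat)
  oa <- sum(diagp)
  ua <- diagp / rowSums(phat)
  pa <- diagp / colSums(phat)
  vUA <- ua * (1 - ua) / (ni - 1)
  vOA <- sum(W^2 * vUA)
  A <- classAreas(em)
  estRefArea <- as.vector(t(ct / ni) %*% A)  # A_total * p_.j per class
  vPA <- numeric(k)
  for (j in seq_len(k)) {
    t1 <- A[j]^2 * (1 - pa[j])^2 * ua[j] * (1 - ua[j]) / (ni[j] - 1)
    t2 <- 0
    for (i in seq_len(k)) {
      if (i == j) next
      pij <- ct[i, j] / ni[i]
      t2 <- t2 + A[i]^2 * pij * (1 - pij) / (ni[i] - 1)
    }
    vPA[j] <- (t1 + pa[j]^2 * t2) / estRefArea[j]^2
  }
  clip <- function(x) pmin(pmax(x, 0), 1)
  ci <- function(est, v) {
    se <- sqrt(v)
    list(se = se, lo = clip(est - 1.96 * se), hi = clip(est + 1.96 * se))
  }
  cOA <- ci(oa, vOA); cUA <- ci(ua, vUA); cPA <- ci(pa, vPA)
  perClass <- data.frame(
    class = rownames(ct),
    ua = unname(ua), ua_se = unname(cUA$se),
    ua_lo = unname(cUA$lo), ua_hi = unname(cUA$hi),
    pa = unname(pa), pa_se = unname(cPA$se),
    pa_lo = unname(cPA$lo), pa_hi = unname(cPA$hi),
    ua_count = unname(diag(ct) / ni),
    pa_count = unname(diag(ct) / colSums(ct)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  overall <- data.frame(oa = oa, se = cOA$se, lo = cOA$lo, hi = cOA$hi,
                        oa_count = sum(diag(ct)) / sum(ct))
  structure(list(overall = overall, perClass = perClass),
            class = "accuracyReport")
}

#' @export
print.accuracyReport <- function(x, ...) {
  cat(sprintf("Overall accuracy %.1f%% (95%% CI %.1f-%.1f%%)\n",
              100 * x$overall$oa, 100 * x$overall$lo, 100 * x$overall$hi))
  print(x$perClass, digits = 3)
  invisible(x)
}

#' Reference-corrected class areas with standard errors and 95% CIs
#'
#' The stratified area estimator: `A_hat_j = A_total * sum_i W_i n_ij/n_i.`
#' with `SE(p_.j) = sqrt(sum_i W_i^2 (n_ij/n_i.)(1 - n_ij/n_i.)/(n_i. - 1))`
#' and CI half-width `1.96 * A_total * SE`. Corrected areas conserve the
#' total mapped area.
#'
#' @param em An [ErrorMatrix-class]; every map class needs at least two
#'   samples (the variance is undefined at one).
#' @return data.frame with `class`, `area_mapped`, `area_est`, `se`,
#'   `ci_halfwidth`, `lo`, `hi` (area units of `classAreas(em)`).
#' @export
correctedAreas <- function(em) {
  p <- emProportions(em)
  assertThat(all(p$ni >= 2),
             paste("map class with fewer than 2 samples:",
                   paste(names(which(p$ni < 2)), collapse = ", ")))
  Atot <- sum(classAreas(em))
  pdotj <- colSums(p$phat)
  sePj <- sqrt(colSums(p$W^2 * (p$ct / p$ni) * (1 - p$ct / p$ni) / (p$ni - 1)))
  est <- Atot * pdotj
  half <- 1.96 * Atot * sePj
  data.frame(class = colnames(p$ct), area_mapped = unname(classAreas(em)),
             area_est = unname(est), se = unname(Atot * sePj),
             ci_halfwidth = unname(half),
             lo = unname(pmax(est - half, 0)), hi = unname(est + half),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Simulate reference labels with a known confusion structure
#'
#' For each sample, draws a reference label from the row of `confusion`
#' matching its map label — the generative model behind coverage experiments
#' for the area CIs.
#'
#' @param mapLabels Character vector of map labels.
#' @param confusion Row-stochastic matrix, `confusion[i, j] = P(ref = j |
#'   map = i)`, dimnames = classes.
#' @param seed RNG seed.
#' @return Character vector of reference labels.
#' @export
simulateReferenceLabels <- function(mapLabels, confusion, seed) {
  classes <- rownames(confusion)
  assertThat(identical(classes, colnames(confusion)),
             "confusion needs identical row/column class names")
  assertThat(all(abs(rowSums(confusion) - 1) < 1e-9),
             "confusion rows must sum to 1")
  assertThat(all(mapLabels %in% classes), "map label outside confusion classes")
  withr::with_seed(as.integer(seed), {
    vapply(mapLabels, function(l) {
      sample(classes, 1L, prob = confusion[l, ])
    }, character(1), USE.NAMES = FALSE)
  })
}

#' Stratified validation sample of a driver map against scene truth
#'
#' Allocates `n` points to mapped driver classes proportionally to mapped
#' area ([allocateSamples()]), samples pixels within each mapped class, and
#' reads the reference label from the ground-truth driver map — the
#' desk-scale stand-in for photo-interpreted validation. Sampling is within
#' the mapped loss extent only, so loss omission is not assessed. Sampled
#' pixels whose truth is `"none"` (commission against truth) are dropped
#' and counted in `attr(, "droppedNoReference")`.
#'
#' @param driverMap A [DriverMap-class].
#' @param truth A [GroundTruthMap-class].
#' @param n Total validation points.
#' @param seed RNG seed.
#' @return data.frame with `row`, `col`, `map`, `reference`.
#' @export
sampleValidation <- function(driverMap, truth, n, seed) {
  drv <- driverMap@driver
  counts <- table(factor(drv[!is.na(drv) & drv != "unattributed"],
                         levels = lossDrivers()))
  counts <- counts[counts > 0]
  assertThat(length(counts) >= 1, "driver map has no attributed pixels")
  alloc <- allocateSamples(setNames(as.numeric(counts), names(counts)), n)
  out <- withr::with_seed(as.integer(seed), {
    do.call(rbind, lapply(names(alloc), function(cl) {
      cells <- which(!is.na(drv) & drv == cl)
      take <- sample(cells, min(alloc[[cl]], length(cells)),
                     replace = length(cells) < alloc[[cl]])
      data.frame(row = (take - 1L) %% nrow(drv) + 1L,
                 col = (take - 1L) %/% nrow(drv) + 1L,
                 map = cl, reference = truth@driver[take],
                 stringsAsFactors = FALSE)
    }))
  })
  dropped <- sum(out$reference == "none")
  out <- out[out$reference != "none", , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "droppedNoReference") <- dropped
  out
}
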