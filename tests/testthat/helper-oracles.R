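# Independent brute-force oracles, kept deliberately naive (explicit loops,
# no shared code with the implementation).

# stratified accuracy/area estimators from first principles
oracleEstimators <- function(counts, areas) {
  k <- nrow(counts)
  areas <- unname(areas)
  W <- areas / sum(areas)
  ni <- numeric(k)
  for (i in 1:k) for (j in 1:k) ni[i] <- ni[i] + counts[i, j]
  phat <- matrix(0, k, k)
  for (i in 1:k) for (j in 1:k) phat[i, j] <- W[i] * counts[i, j] / ni[i]
  oa <- 0
  for (j in 1:k) oa <- oa + phat[j, j]
  ua <- pa <- numeric(k)
  for (i in 1:k) {
    rowsum <- 0
    for (j in 1:k) rowsum <- rowsum + phat[i, j]
    ua[i] <- phat[i, i] / rowsum
  }
  pdotj <- numeric(k)
  for (j in 1:k) for (i in 1:k) pdotj[j] <- pdotj[j] + phat[i, j]
  for (j in 1:k) pa[j] <- phat[j, j] / pdotj[j]
  vua <- numeric(k)
  for (i in 1:k) vua[i] <- ua[i] * (1 - ua[i]) / (ni[i] - 1)
  voa <- 0
  for (i in 1:k) voa <- voa + W[i]^2 * vua[i]
  Atot <- sum(areas)
  ahat <- Atot * pdotj
  sePdotj <- numeric(k)
  for (j in 1:k) {
    s <- 0
    for (i in 1:k) {
      pij <- counts[i, j] / ni[i]
      s <- s + W[i]^2 * pij * (1 - pij) / (ni[i] - 1)
    }
    sePdotj[j] <- sqrt(s)
  }
  vpa <- numeric(k)
  for (j in 1:k) {
    Nhatj <- 0
    for (i in 1:k) Nhatj <- Nhatj + areas[i] * counts[i, j] / ni[i]
    t1 <- areas[j]^2 * (1 - pa[j])^2 * ua[j] * (1 - ua[j]) / (ni[j] - 1)
    t2 <- 0
    for (i in 1:k) {
      if (i == j) next
      pij <- counts[i, j] / ni[i]
      t2 <- t2 + areas[i]^2 * pij * (1 - pij) / (ni[i] - 1)
    }
    vpa[j] <- (t1 + pa[j]^2 * t2) / Nhatj^2
  }
  list(oa = oa, ua = ua, pa = pa, voa = voa, vua = vua, vpa = vpa,
       areaEst = ahat, areaSe = Atot * sePdotj)
}

# flood fill by explicit queue
oracleFloodFill <- function(water, ocean, connectivity) {
  nr <- nrow(water); nc <- ncol(water)
  medium <- water | ocean
  seen <- matrix(FALSE, nr, nc)
  queue <- which(ocean & medium)
  seen[queue] <- TRUE
  offs <- if (connectivity == 4) list(c(-1,0), c(1,0), c(0,-1), c(0,1))
          else list(c(-1,0), c(1,0), c(0,-1), c(0,1),
                    c(-1,-1), c(-1,1), c(1,-1), c(1,1))
  while (length(queue)) {
    cell <- queue[1]; queue <- queue[-1]
    r <- (cell - 1) %% nr + 1; cl <- (cell - 1) %/% nr + 1
    for (o in offs) {
      rr <- r + o[1]; cc <- cl + o[2]
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
      idx <- (cc - 1) * nr + rr
      if (medium[idx] && !seen[idx]) { seen[idx] <- TRUE; queue <- c(queue, idx) }
    }
  }
  seen & water
}

# pixel centres within a metre radius of a point
oracleDiscCount <- function(px, py, radius, nr, nc, pixelSize) {
  n <- 0
  for (r in 1:nr) for (cl in 1:nc) {
    cx <- (cl - 0.5) * pixelSize; cy <- (r - 0.5) * pixelSize
    if (sqrt((cx - px)^2 + (cy - py)^2) <= radius) n <- n + 1
  }
  n
}

# sort-based median, ignoring NA
oracleMedian <- function(x) {
  x <- sort(unname(x[!is.na(x)]))
  n <- length(x)
  if (n == 0) return(NA_real_)
  if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
}

randomErrorMatrix <- function(k, seedOffset = 0) {
  counts <- matrix(0L, k, k)
  for (i in 1:k) for (j in 1:k) {
    counts[i, j] <- if (i == j) sample(5:20, 1) else sample(0:5, 1)
  }
  classes <- paste0("c", 1:k)
  dimnames(counts) <- list(classes, classes)
  areas <- setNames(runif(k, 50, 500), classes)
  list(counts = counts, areas = areas)
}
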