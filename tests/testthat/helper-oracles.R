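# Independent oracles and tiny scene builders. Everything here is written
# naively (explicit double loops, closed forms) on purpose: these paths must
# stay independent of the vectorised implementations they check.

# Brute-force KDE: explicit loop over (cell, poi) evaluating the
# finite-support kernel sum at each cell centre.
bruteKde <- function(cells, pois, h, kernel = "printed") {
  out <- numeric(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    acc <- 0
    for (j in seq_len(nrow(pois))) {
      d <- sqrt((cells[i, 1] - pois[j, 1])^2 + (cells[i, 2] - pois[j, 2])^2)
      if (d <= h) {
        acc <- acc + if (kernel == "printed") {
          (1 / (pi * h^2)) * (1 - d^2 / h^2)
        } else {
          (3 / (pi * h^2)) * (1 - d^2 / h^2)^2
        }
      }
    }
    out[i] <- acc
  }
  out
}

# Brute-force Gaussian 2SFCA: double loops over parks and units.
brute2sfca <- function(S, parkXY, D, unitXY, d0) {
  g <- function(d) (exp(-0.5 * (d / d0)^2) - exp(-0.5)) / (1 - exp(-0.5))
  nP <- length(S); nU <- length(D)
  R <- rep(NA_real_, nP)
  for (j in seq_len(nP)) {
    dem <- 0
    for (k in seq_len(nU)) {
      d <- sqrt(sum((parkXY[j, ] - unitXY[k, ])^2))
      if (d <= d0) dem <- dem + g(d) * D[k]
    }
    if (dem > 0) R[j] <- S[j] / dem
  }
  A <- numeric(nU)
  for (i in seq_len(nU)) {
    for (j in seq_len(nP)) {
      if (is.na(R[j])) next
      d <- sqrt(sum((unitXY[i, ] - parkXY[j, ])^2))
      if (d <= d0) A[i] <- A[i] + g(d) * R[j]
    }
  }
  list(R = R, A = A)
}

# Fine-grid counting oracle for circle scenes: a cell counts as covered by
# circle i when its centre lies within radius[i] + buffer[i] of the centre
# (analytic point-in-disk, no polygon code involved).
circleCoverCounts <- function(grid, centers, radii) {
  cc <- greenserv::cellCenters(grid)
  counts <- integer(nrow(cc))
  for (i in seq_len(nrow(centers))) {
    d <- sqrt((cc[, 1] - centers[i, 1])^2 + (cc[, 2] - centers[i, 2])^2)
    counts <- counts + as.integer(d <= radii[i])
  }
  counts
}

# Closed-form intersection area of two equal circles of radius R whose
# centres are d apart.
lensArea <- function(R, d) {
  if (d >= 2 * R) return(0)
  2 * R^2 * acos(d / (2 * R)) - (d / 2) * sqrt(4 * R^2 - d^2)
}

# Exhaustive Fisher-Jenks: enumerate all ways to cut sorted x into k
# contiguous classes, return the minimal within-class sum of squares.
bruteJenksSSE <- function(x, k) {
  x <- sort(x)
  n <- length(x)
  sse <- function(v) sum((v - mean(v))^2)
  best <- Inf
  cuts <- utils::combn(n - 1L, k - 1L)
  for (c in seq_len(ncol(cuts))) {
    bounds <- c(0L, cuts[, c], n)
    tot <- 0
    for (m in seq_len(k)) {
      tot <- tot + sse(x[(bounds[m] + 1L):bounds[m + 1L]])
    }
    best <- min(best, tot)
  }
  best
}

jenksSSEof <- function(x, breaks) {
  cls <- findInterval(x, breaks, left.open = TRUE)
  sum(vapply(split(x, cls), function(v) sum((v - mean(v))^2), numeric(1)))
}

# Scene builders ------------------------------------------------------------

# Square park of a given area centred at (cx, cy).
squarePoly <- function(cx, cy, area) {
  s <- sqrt(area) / 2
  rectPolygon(cx - s, cy - s, cx + s, cy + s)
}

# GreenSpaceSet of square parks at given centres/areas.
mkParks <- function(centers, areas, category = "park") {
  geoms <- lapply(seq_len(nrow(centers)), function(i) {
    squarePoly(centers[i, 1], centers[i, 2], areas[i])
  })
  greenSpaceSet(geoms, category = category)
}

# DemandUnitSet with unit squares around the given centroids.
mkUnits <- function(centroids, pop) {
  geoms <- lapply(seq_len(nrow(centroids)), function(i) {
    rectPolygon(centroids[i, 1] - 50, centroids[i, 2] - 50,
                centroids[i, 1] + 50, centroids[i, 2] + 50)
  })
  new("DemandUnitSet", geoms = geoms,
      centroids = cbind(x = centroids[, 1], y = centroids[, 2]),
      info = data.frame(id = paste0("u", seq_len(nrow(centroids))),
                        population = pop, stringsAsFactors = FALSE))
}

# HeatSurface wrapper around a bare value matrix.
mkSurface <- function(values, cellSize = 50, bandwidth = 1250) {
  g <- spatialGrid(0, 0, cellSize, nrow(values), ncol(values))
  new("HeatSurface", grid = g, values = values, bandwidth = bandwidth,
      kernel = "printed")
}

# HeatZoneMap with the given per-zone cell counts (coldest first).
mkZoneMap <- function(cellCounts, cellSize = 50) {
  n <- sum(cellCounts)
  lab <- rep(seq_along(cellCounts), cellCounts)
  nr <- max(1L, floor(sqrt(n)))
  while (n %% nr != 0L) nr <- nr - 1L
  g <- spatialGrid(0, 0, cellSize, nr, n / nr)
  new("HeatZoneMap", grid = g, labels = matrix(lab, nr, n / nr),
      breaks = seq_len(length(cellCounts) - 1L) + 0.5,
      levels = if (length(cellCounts) == 5L)
        c("Cold", "Sub-Cold", "Not-Significant", "Sub-Hot", "Hot")
      else paste0("class", seq_along(cellCounts)))
}

# Small random 2SFCA instance (parks as squares, units on a jittered grid).
random2sfcaInstance <- function(nParks, nUnits, extent = 4000, d0 = 1250) {
  centers <- cbind(runif(nParks, 200, extent - 200),
                   runif(nParks, 200, extent - 200))
  areas <- runif(nParks, 2e3, 5e4)
  ctr <- cbind(runif(nUnits, 0, extent), runif(nUnits, 0, extent))
  pop <- runif(nUnits, 10, 500)
  list(greens = mkParks(centers, areas), units = mkUnits(ctr, pop),
       S = areas, parkXY = centers, D = pop, unitXY = ctr, d0 = d0)
}
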