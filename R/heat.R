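## Residents' life-heat: kernel density of points of interest, classified
## into five ordered density zones (Cold < Sub-Cold < Not-Significant <
## Sub-Hot < Hot), with an area/percentage report.

HEAT_LEVELS <- c("Cold", "Sub-Cold", "Not-Significant", "Sub-Hot", "Hot")

#' Life-heat kernel density surface
#'
#' Evaluates, at every grid cell centre s, the finite-support kernel sum
#' f(s) = sum over POIs c_i with ||s - c_i|| <= h of
#' (1 / (pi h^2)) * (1 - ||s - c_i||^2 / h^2).
#'
#' The default kernel is this exact form, whose mass over its support disk is
#' 1/2 (see [kernelMass()]); `kernel = "quartic"` substitutes the standard
#' quartic (biweight) density kernel
#' (3 / (pi h^2)) * (1 - (d/h)^2)^2, which integrates to 1. Zone
#' classification is invariant to this choice up to the positive scale
#' factor.
#'
#' @param pois a [PoiSet-class] or two-column coordinate matrix.
#' @param h bandwidth (search radius) in meters; default 1250, the walking
#'   life-circle threshold used throughout the analysis.
#' @param grid a [SpatialGrid-class] covering the study area.
#' @param kernel "printed" (default) or "quartic".
#' @return a [HeatSurface-class].
#' @examples
#' g <- spatialGrid(0, 0, 50, 20, 20)
#' hs <- kdeSurface(cbind(500, 500), h = 300, grid = g)
#' max(hs@values) * pi * 300^2  # ~1 at the POI cell
#' @export
kdeSurface <- function(pois, h = 1250, grid, kernel = c("printed", "quartic")) {
  kernel <- match.arg(kernel)
  stopifnotScalarPositive(h, "h")
  if (missing(grid) || is.null(grid)) stop("grid must be supplied")
  g <- gridGeometry(grid)
  xy <- if (is(pois, "PoiSet")) poiCoords(pois) else
    matrix(as.numeric(pois), ncol = 2)
  vals <- matrix(0, g@nrow, g@ncol)
  if (nrow(xy) > 0L) {
    cs <- g@cellSize
    cx <- g@x0 + (seq_len(g@ncol) - 0.5) * cs
    cy <- g@y0 + (seq_len(g@nrow) - 0.5) * cs
    for (i in seq_len(nrow(xy))) {
      jc <- which(abs(cx - xy[i, 1]) <= h)
      jr <- which(abs(cy - xy[i, 2]) <= h)
      if (!length(jc) || !length(jr)) next
      d2 <- outer((cy[jr] - xy[i, 2])^2, (cx[jc] - xy[i, 1])^2, "+")
      u2 <- d2 / h^2
      k <- if (kernel == "printed") {
        (1 / (pi * h^2)) * (1 - u2)
      } else {
        (3 / (pi * h^2)) * (1 - u2)^2
      }
      k[u2 > 1] <- 0
      vals[jr, jc] <- vals[jr, jc] + k
    }
  }
  new("HeatSurface", grid = g, values = vals, bandwidth = h, kernel = kernel)
}

#' Mass of the heat kernel over its support disk
#'
#' Numerically integrates the kernel over the disk of radius h. The default
#' finite-support form integrates to 1/2 for every h (it is an unnormalised
#' density); the quartic option integrates to 1. The constant documents why
#' absolute f(s) values from the default kernel are half those of a proper
#' density estimate — zone classification, which only ranks values, is
#' unaffected.
#'
#' @param h bandwidth in meters.
#' @param kernel "printed" (default) or "quartic".
#' @return the integral (dimensionless).
#' @examples
#' kernelMass(1250)            # 0.5
#' kernelMass(1250, "quartic") # 1
#' @export
kernelMass <- function(h, kernel = c("printed", "quartic")) {
  kernel <- match.arg(kernel)
  stopifnotScalarPositive(h, "h")
  f <- if (kernel == "printed") {
    function(r) (1 / (pi * h^2)) * (1 - r^2 / h^2) * 2 * pi * r
  } else {
    function(r) (3 / (pi * h^2)) * (1 - r^2 / h^2)^2 * 2 * pi * r
  }
  stats::integrate(f, 0, h, rel.tol = 1e-10)$value
}

## Exact Fisher-Jenks natural breaks by dynamic programming on sorted values.
## Returns the k - 1 inner break values (upper bound of each class but the
## last). Values are deterministically thinned to at most maxN before the
## O(k n^2) DP.
jenksBreaks <- function(x, k, maxN = 3000L) {
  x <- sort(x)
  if (length(x) > maxN) {
    x <- x[unique(round(seq(1L, length(x), length.out = maxN)))]
  }
  n <- length(x)
  W1 <- cumsum(x); W2 <- cumsum(x^2)
  ssq <- function(i, j) {         # within-class sum of squares for x[i..j]
    s1 <- W1[j] - ifelse(i > 1L, W1[i - 1L], 0)
    s2 <- W2[j] - ifelse(i > 1L, W2[i - 1L], 0)
    pmax(0, s2 - s1^2 / (j - i + 1L))
  }
  D <- ssq(rep(1L, n), seq_len(n))          # one class
  idx <- matrix(0L, k, n)
  for (m in 2:k) {
    Dm <- rep(Inf, n); im <- rep(0L, n)
    for (j in m:n) {
      i <- m:j                               # first index of class m
      tot <- D[i - 1L] + ssq(i, rep(j, length(i)))
      w <- which.min(tot)
      Dm[j] <- tot[w]; im[j] <- i[w]
    }
    D <- Dm; idx[m, ] <- im
  }
  cuts <- integer(k - 1L)
  j <- n
  for (m in k:2) {
    cuts[m - 1L] <- idx[m, j] - 1L           # last index of class m - 1
    j <- cuts[m - 1L]
  }
  x[cuts]
}

#' Classify a heat surface into ordered density zones
#'
#' Higher density never receives a colder label. Break selection:
#' `"jenks"` (default) uses exact Fisher-Jenks natural breaks — the
#' conventional choice for GIS density zoning; `"quantile"` uses equal-count
#' breaks; `"equal_interval"` splits the value range evenly.
#'
#' @param surface a [HeatSurface-class].
#' @param method break selection method.
#' @param k number of classes (default 5).
#' @param area optional [StudyArea-class]; cells outside it are left NA and
#'   excluded from break estimation.
#' @param levels class names, coldest first (default the five heat zones).
#' @return a [HeatZoneMap-class].
#' @export
classifyHeat <- function(surface,
                         method = c("jenks", "quantile", "equal_interval"),
                         k = 5L, area = NULL,
                         levels = if (k == 5L) HEAT_LEVELS else
                           paste0("class", seq_len(k))) {
  method <- match.arg(method)
  k <- as.integer(k)
  if (length(levels) != k) stop("levels must have length k")
  g <- surface@grid
  vals <- surface@values
  mask <- if (is.null(area)) matrix(TRUE, g@nrow, g@ncol)
          else studyAreaMask(g, area)
  v <- vals[mask]
  if (length(v) == 0L) stop("empty surface")
  if (length(unique(v)) < k) {
    stop("surface has fewer distinct values than classes")
  }
  breaks <- switch(method,
    jenks = jenksBreaks(v, k),
    quantile = stats::quantile(v, probs = seq_len(k - 1L) / k, names = FALSE,
                               type = 7),
    equal_interval = min(v) + diff(range(v)) * seq_len(k - 1L) / k)
  breaks <- unique(breaks)
  if (length(breaks) != k - 1L) {
    stop("degenerate breaks: values do not support ", k, " classes")
  }
  lab <- matrix(NA_integer_, g@nrow, g@ncol)
  lab[mask] <- findInterval(v, breaks, left.open = TRUE) + 1L
  new("HeatZoneMap", grid = g, labels = lab, breaks = as.numeric(breaks),
      levels = levels)
}

#' Zone area and percentage table
#'
#' Per-zone area in km2 and its percentage of the all-zone total (half-up,
#' two decimals), plus a total row.
#'
#' @param zones a [HeatZoneMap-class].
#' @return data.frame(zone, area_km2, percent) with a final "Total" row.
#' @examples
#' ratioPercent(35.60, 48.34)  # the arithmetic behind each percent column
#' @export
zoneAreaTable <- function(zones) {
  cellKm2 <- cellAreaM2(zones) / 1e6
  k <- length(zones@levels)
  n <- tabulate(zones@labels[!is.na(zones@labels)], nbins = k)
  areas <- n * cellKm2
  tot <- sum(areas)
  pct <- if (tot > 0) ratioPercent(areas, tot) else rep(0, k)
  rbind(
    data.frame(zone = zones@levels, area_km2 = areas, percent = pct,
               stringsAsFactors = FALSE),
    data.frame(zone = "Total", area_km2 = tot,
               percent = if (tot > 0) sum(pct) else 0))
}
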