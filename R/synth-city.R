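## Seeded synthetic city: a compact rectangular built-up frame, green patches
## spanning the disaster-shelter size classes, points of interest clustered
## around an old-town centre, a population raster concentrated where POIs
## are, and a tessellation of demand units. Every stage draws from its own
## seed stream derived from the config seed, so outputs are reproducible per
## stage and identical configs give identical cities.

## Disaster-shelter park size classes (m2): 0.5-1 ha, 1-10 ha, 10-50 ha,
## >= 50 ha. Used to stratify generated park areas so each class that the
## configured range permits is represented.
PARK_CLASS_BOUNDS_M2 <- c(5e3, 1e4, 1e5, 5e5, Inf)

#' Synthetic-city configuration
#'
#' Defaults encode the study conditions of the analysis: a 7000 x 6500 m
#' built-up frame (45.5 km2), 1294 points of interest mixing an old-town
#' cluster, secondary clusters and a uniform background, a 100 m population
#' raster totalling 100,000 residents, and 233 demand units.
#'
#' @param seed integer RNG seed.
#' @param extent numeric (width, height) in meters.
#' @param nParks,nBuffers number of park / protective-buffer patches.
#' @param parkAreaRange (min, max) park area in m2; drawn log-uniform and
#'   stratified so every shelter size class inside the range is hit.
#' @param nPoi number of POIs after deduplication.
#' @param poiCenters data.frame(x, y, weight, spread_m): cluster centres in
#'   fractional extent coordinates, mixture weights (remainder is uniform
#'   background) and isotropic Gaussian spreads in meters.
#' @param populationTotal total residents distributed over the raster.
#' @param popCellM population raster resolution (meters).
#' @param demandUnitCount number of demand units in the tessellation.
#' @return a [SynthConfig-class] object.
#' @examples
#' cfg <- synthConfig(seed = 1)
#' cfg
#' @export
synthConfig <- function(seed = 1L,
                        extent = c(7000, 6500),
                        nParks = 24L,
                        nBuffers = 6L,
                        parkAreaRange = c(5e3, 1e6),
                        nPoi = 1294L,
                        poiCenters = data.frame(
                          x = c(0.35, 0.60, 0.28),
                          y = c(0.45, 0.58, 0.68),
                          weight = c(0.45, 0.15, 0.10),
                          spread_m = c(600, 900, 500)),
                        populationTotal = 1e5,
                        popCellM = 100,
                        demandUnitCount = 233L) {
  new("SynthConfig", seed = as.integer(seed), extent = as.numeric(extent),
      nParks = as.integer(nParks), nBuffers = as.integer(nBuffers),
      parkAreaRange = as.numeric(parkAreaRange), nPoi = as.integer(nPoi),
      poiCenters = poiCenters, populationTotal = as.numeric(populationTotal),
      popCellM = as.numeric(popCellM),
      demandUnitCount = as.integer(demandUnitCount))
}

#' Generate the study-area polygon
#'
#' The synthetic built-up area is the rectangle of the configured extent,
#' anchored at the origin of the local metric CRS.
#'
#' @param cfg a [SynthConfig-class].
#' @return a [StudyArea-class].
#' @examples
#' areaM2(generateStudyArea(synthConfig()))  # 45,500,000
#' @export
generateStudyArea <- function(cfg) {
  new("StudyArea", boundary = rectPolygon(0, 0, cfg@extent[1], cfg@extent[2]))
}

#' Generate green-space patches
#'
#' Parks are rectangles with areas drawn log-uniform over `parkAreaRange`,
#' stratified round-robin across the shelter size classes the range permits
#' so each class is exercised. Protective buffers are high-aspect-ratio
#' strips (riverside/roadside green), placed across the frame and clipped to
#' the study area.
#'
#' @param cfg a [SynthConfig-class].
#' @param area a [StudyArea-class].
#' @param strict if TRUE, error when `parkAreaRange` cannot reach every
#'   shelter size class with the requested number of parks.
#' @return a [GreenSpaceSet-class].
#' @export
generateGreenSpaces <- function(cfg, area, strict = FALSE) {
  W <- cfg@extent[1]; H <- cfg@extent[2]
  lo <- cfg@parkAreaRange[1]; hi <- cfg@parkAreaRange[2]
  cls <- lapply(seq_len(length(PARK_CLASS_BOUNDS_M2) - 1L), function(i) {
    c(max(lo, PARK_CLASS_BOUNDS_M2[i]),
      min(hi, PARK_CLASS_BOUNDS_M2[i + 1L]))
  })
  reachable <- vapply(cls, function(b) b[1] < b[2], logical(1))
  if (strict && (sum(reachable) < length(cls) ||
                 cfg@nParks < sum(reachable))) {
    stop("parkAreaRange/nParks cannot cover every shelter size class")
  }
  withSeed(stageSeed(cfg@seed, 2L), {
    geoms <- list(); category <- character(0)
    if (cfg@nParks > 0L) {
      strata <- rep(which(reachable), length.out = cfg@nParks)
      for (s in strata) {
        b <- cls[[s]]
        a <- exp(stats::runif(1, log(b[1]), log(min(b[2], hi))))
        ar <- stats::runif(1, 0.6, 1.8)     # width/height aspect
        w <- min(sqrt(a * ar), 0.9 * W)
        h <- a / w
        x <- stats::runif(1, 0, W - w)
        y <- stats::runif(1, 0, H - h)
        geoms <- c(geoms, list(rectPolygon(x, y, x + w, y + h)))
        category <- c(category, "park")
      }
    }
    if (cfg@nBuffers > 0L) {
      for (i in seq_len(cfg@nBuffers)) {
        horiz <- (i %% 2L == 0L)
        w <- stats::runif(1, 15, 40)        # strip width, meters
        L <- stats::runif(1, 800, 2500)     # strip length
        if (horiz) {
          x <- stats::runif(1, -0.1 * W, W - 0.5 * L)
          y <- stats::runif(1, 0, H - w)
          poly <- rectPolygon(x, y, x + L, y + w)
        } else {
          x <- stats::runif(1, 0, W - w)
          y <- stats::runif(1, -0.1 * H, H - 0.5 * L)
          poly <- rectPolygon(x, y, x + w, y + L)
        }
        poly <- clipPolygonToRect(poly, 0, 0, W, H)
        geoms <- c(geoms, list(poly))
        category <- c(category, "buffer")
      }
    }
    greenSpaceSet(geoms, category = category)
  })
}

#' Generate points of interest
#'
#' Draws `nPoi` points from a mixture of isotropic Gaussian clusters (the
#' old-town centre and secondary centres) plus a uniform background, rejects
#' points outside the study area, and removes exact duplicates — emulating a
#' POI density decaying irregularly from the old town outward.
#'
#' @param cfg a [SynthConfig-class].
#' @param area a [StudyArea-class].
#' @param categories label pool for the daily-life POI classes.
#' @return a [PoiSet-class] with `nPoi` deduplicated points.
#' @export
generatePois <- function(cfg, area, categories = c(
    "life_service", "catering", "shopping", "accommodation",
    "public_facility", "education", "healthcare", "finance", "transport",
    "sport", "culture", "government", "company", "residence", "tourism",
    "auto_service", "telecom", "media", "agriculture")) {
  b <- boundary(area)
  W <- max(b[, 1]) - min(b[, 1]); H <- max(b[, 2]) - min(b[, 2])
  ctr <- cfg@poiCenters
  probs <- c(ctr$weight, max(0, 1 - sum(ctr$weight)))
  withSeed(stageSeed(cfg@seed, 3L), {
    drawBatch <- function(n) {
      comp <- sample.int(length(probs), n, replace = TRUE, prob = probs)
      xy <- matrix(0, n, 2)
      bg <- comp == length(probs)
      if (any(bg)) {
        xy[bg, 1] <- min(b[, 1]) + stats::runif(sum(bg)) * W
        xy[bg, 2] <- min(b[, 2]) + stats::runif(sum(bg)) * H
      }
      for (k in seq_len(nrow(ctr))) {
        m <- comp == k
        if (!any(m)) next
        xy[m, 1] <- min(b[, 1]) + ctr$x[k] * W +
          stats::rnorm(sum(m), 0, ctr$spread_m[k])
        xy[m, 2] <- min(b[, 2]) + ctr$y[k] * H +
          stats::rnorm(sum(m), 0, ctr$spread_m[k])
      }
      keep <- pointInPolygon(xy, b)
      xy[keep, , drop = FALSE]
    }
    xy <- matrix(numeric(0), 0, 2)
    while (nrow(xy) < cfg@nPoi) {
      xy <- rbind(xy, drawBatch(max(64L, cfg@nPoi - nrow(xy))))
      xy <- xy[!duplicated(xy), , drop = FALSE]   # exact-duplicate dedup
    }
    xy <- xy[seq_len(cfg@nPoi), , drop = FALSE]
    cat <- sample(categories, cfg@nPoi, replace = TRUE)
    poiSet(xy, category = cat)
  })
}

## Separable Gaussian blur of a matrix, reflecting at edges.
gaussianBlur <- function(m, sigmaCells) {
  if (sigmaCells <= 0) return(m)
  r <- max(1L, ceiling(3 * sigmaCells))
  k <- stats::dnorm(seq(-r, r), sd = sigmaCells)
  k <- k / sum(k)
  pad <- function(v, r) c(rev(v[seq_len(r)]), v, rev(v[length(v) - seq_len(r) + 1L]))
  smooth1 <- function(v) {
    if (length(v) <= 1L) return(v)
    rr <- min(r, length(v) - 1L)
    kk <- stats::dnorm(seq(-rr, rr), sd = sigmaCells); kk <- kk / sum(kk)
    stats::filter(pad(v, rr), kk, sides = 2)[(rr + 1L):(rr + length(v))]
  }
  m <- apply(m, 2, smooth1)
  t(apply(t(m), 2, smooth1))
}

#' Generate the population raster
#'
#' Residential density follows a Gaussian-blurred POI intensity (people live
#' where daily-life destinations are) plus a uniform background, scaled so
#' the raster sums exactly to `populationTotal`.
#'
#' @param cfg a [SynthConfig-class].
#' @param area a [StudyArea-class].
#' @param pois a [PoiSet-class] (may be empty: the raster is then uniform).
#' @param blurSigmaM Gaussian blur scale in meters (default 300).
#' @param backgroundFrac fraction of population spread uniformly (default 0.15).
#' @return a [PopulationRaster-class].
#' @export
generatePopulation <- function(cfg, area, pois, blurSigmaM = 300,
                               backgroundFrac = 0.15) {
  g <- gridOverArea(area, cfg@popCellM)
  inArea <- studyAreaMask(g, area)
  xy <- poiCoords(pois)
  counts <- matrix(0, g@nrow, g@ncol)
  if (nrow(xy) > 0L) {
    r <- pmin(pmax(1L, floor((xy[, 2] - g@y0) / g@cellSize) + 1L), g@nrow)
    cc <- pmin(pmax(1L, floor((xy[, 1] - g@x0) / g@cellSize) + 1L), g@ncol)
    for (i in seq_along(r)) counts[r[i], cc[i]] <- counts[r[i], cc[i]] + 1
    dens <- gaussianBlur(counts, blurSigmaM / g@cellSize)
    dens[dens < 0] <- 0
  } else {
    dens <- counts
    backgroundFrac <- 1
  }
  dens[!inArea] <- 0
  w <- matrix(0, g@nrow, g@ncol)
  if (sum(dens) > 0) w <- (1 - backgroundFrac) * dens / sum(dens)
  w[inArea] <- w[inArea] + backgroundFrac / sum(inArea)
  w[!inArea] <- 0
  new("PopulationRaster", grid = g,
      counts = w * cfg@populationTotal / sum(w))
}

#' Generate demand units
#'
#' Tessellates the rectangular study frame into `demandUnitCount` near-square
#' cells: rows of equal height, each row split into equal-width cells, with
#' row cell counts differing by at most one so any count (including primes)
#' tessellates exactly. Each unit's population is the sum of population-raster
#' cells whose centres fall inside it.
#'
#' @param cfg a [SynthConfig-class].
#' @param area a [StudyArea-class].
#' @param pop a [PopulationRaster-class].
#' @return a [DemandUnitSet-class].
#' @export
generateDemandUnits <- function(cfg, area, pop) {
  N <- cfg@demandUnitCount
  g <- pop@grid
  if (N > g@nrow * g@ncol) {
    stop("demandUnitCount exceeds the number of population raster cells")
  }
  b <- boundary(area)
  x0 <- min(b[, 1]); y0 <- min(b[, 2])
  W <- max(b[, 1]) - x0; H <- max(b[, 2]) - y0
  nr <- max(1L, min(N, as.integer(round(sqrt(N * H / W)))))
  base <- N %/% nr; extra <- N %% nr
  rowCounts <- rep(base, nr) + c(rep(1L, extra), rep(0L, nr - extra))
  rowH <- H / nr
  geoms <- list(); centroids <- NULL; rowOf <- integer(0); colOf <- integer(0)
  for (r in seq_len(nr)) {
    cw <- W / rowCounts[r]
    for (cidx in seq_len(rowCounts[r])) {
      xmin <- x0 + (cidx - 1) * cw; ymin <- y0 + (r - 1) * rowH
      geoms <- c(geoms, list(rectPolygon(xmin, ymin, xmin + cw, ymin + rowH)))
      centroids <- rbind(centroids, c(xmin + cw / 2, ymin + rowH / 2))
      rowOf <- c(rowOf, r); colOf <- c(colOf, cidx)
    }
  }
  ## Assign raster cells by direct index arithmetic (exact partition).
  cc <- cellCenters(g)
  popv <- as.vector(pop@counts)
  rIdx <- pmin(pmax(1L, floor((cc[, 2] - y0) / rowH) + 1L), nr)
  unitStart <- cumsum(c(0L, rowCounts))
  cIdx <- pmin(pmax(1L, floor((cc[, 1] - x0) / (W / rowCounts[rIdx])) + 1L),
               rowCounts[rIdx])
  uIdx <- unitStart[rIdx] + cIdx
  unitPop <- vapply(seq_len(N), function(u) sum(popv[uIdx == u]), numeric(1))
  new("DemandUnitSet", geoms = geoms,
      centroids = cbind(x = centroids[, 1], y = centroids[, 2]),
      info = data.frame(id = paste0("u", seq_len(N)), population = unitPop,
                        stringsAsFactors = FALSE))
}

#' Generate the full synthetic city
#'
#' Convenience wrapper running every generator stage in order.
#'
#' @param cfg a [SynthConfig-class].
#' @return list with elements `area`, `greens`, `pois`, `population`,
#'   `units` and the `cfg` used.
#' @examples
#' city <- synthesizeCity(synthConfig(seed = 7, nPoi = 50,
#'                                    populationTotal = 1000))
#' names(city)
#' @export
synthesizeCity <- function(cfg) {
  area <- generateStudyArea(cfg)
  greens <- generateGreenSpaces(cfg, area)
  pois <- generatePois(cfg, area)
  pop <- generatePopulation(cfg, area, pois)
  units <- generateDemandUnits(cfg, area, pop)
  list(cfg = cfg, area = area, greens = greens, pois = pois,
       population = pop, units = units)
}
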