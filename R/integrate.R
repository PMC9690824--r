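## Integrated equity zoning: overlay the life-heat level (3 groups from the
## 5 density zones), the accessibility level (3-level collapse), and the
## composite-service enjoyment flag into 18 partitions per cell, then merge
## them into six named areas keyed on supply capacity (the per-unit supply
## flag), heat group and service enjoyment.

ZONE_LEVELS <- c("High-quality living area", "Livable area",
                 "Underdeveloped area", "Green space service blind area",
                 "Under supply and demand area", "Comprehensive blind area")

HEAT_GROUPS <- c("low", "medium", "high")

## 5-zone label index -> 3-level heat group: Cold, Sub-Cold -> low;
## Not-Significant -> medium; Sub-Hot, Hot -> high.
heatGroupOf <- function(label5) {
  c("low", "low", "medium", "high", "high")[label5]
}

#' Default merge mapping
#'
#' The (supply capacity, heat group, service enjoyment) -> named zone table.
#' Six of the eight combinations follow the published partition rows; the
#' two combinations the partition table omits (supply-sufficient, low heat,
#' not enjoying; supply-deficient, low heat, enjoying) default to the
#' nearest row differing in one field: "Green space service blind area" and
#' "Livable area" respectively. Override by editing the returned data.frame
#' and passing it to [mergePartitions()].
#'
#' @return data.frame(supply, heat, service, zone), total over all
#'   2 x 3 x 2 combinations (heat "medium" and "high" share rows, listed
#'   separately).
#' @export
defaultZoneMapping <- function() {
  rows <- rbind(
    c("supply>=demand", "medium", "enjoy",     ZONE_LEVELS[1]),
    c("supply>=demand", "high",   "enjoy",     ZONE_LEVELS[1]),
    c("supply>=demand", "low",    "enjoy",     ZONE_LEVELS[2]),
    c("supply<demand",  "low",    "not-enjoy", ZONE_LEVELS[3]),
    c("supply>=demand", "medium", "not-enjoy", ZONE_LEVELS[4]),
    c("supply>=demand", "high",   "not-enjoy", ZONE_LEVELS[4]),
    c("supply<demand",  "medium", "enjoy",     ZONE_LEVELS[5]),
    c("supply<demand",  "high",   "enjoy",     ZONE_LEVELS[5]),
    c("supply<demand",  "medium", "not-enjoy", ZONE_LEVELS[6]),
    c("supply<demand",  "high",   "not-enjoy", ZONE_LEVELS[6]),
    ## combinations absent from the published table:
    c("supply>=demand", "low",    "not-enjoy", ZONE_LEVELS[4]),
    c("supply<demand",  "low",    "enjoy",     ZONE_LEVELS[2]))
  data.frame(supply = rows[, 1], heat = rows[, 2], service = rows[, 3],
             zone = rows[, 4], stringsAsFactors = FALSE)
}

## Locate, for each grid cell centre, the demand unit containing it.
## Returns an integer vector (NA where no unit contains the centre).
locateUnits <- function(grid, units) {
  g <- gridGeometry(grid)
  cc <- cellCenters(g)
  idx <- rep(NA_integer_, nrow(cc))
  for (u in seq_along(units@geoms)) {
    todo <- which(is.na(idx))
    if (!length(todo)) break
    hit <- pointInPolygon(cc[todo, , drop = FALSE], units@geoms[[u]])
    idx[todo[hit]] <- u
  }
  idx
}

#' Per-cell partition codes
#'
#' Assigns every study-area cell its heat group (from the five-zone map),
#' accessibility level and supply flag (inherited from the demand unit
#' containing the cell centre) and service flag (enjoy iff the centre lies
#' inside the composite three-service space) — the 3 x 3 x 2 = 18 possible
#' partition codes, plus the binary supply flag used for merging.
#'
#' @param zones a [HeatZoneMap-class] (5 levels).
#' @param access an [AccessibilityResult-class].
#' @param units the [DemandUnitSet-class] the accessibility was computed on.
#' @param composite composite-service mask from [compositeService()] (or any
#'   logical matrix on the same grid).
#' @return data.frame with one row per study-area cell: cell (column-major
#'   index), heat, access, service, supply.
#' @export
partitionCodes <- function(zones, access, units, composite) {
  g <- zones@grid
  if (!identical(dim(composite)[1:2], dim(zones@labels))) {
    stop("composite mask and heat zones must share one grid")
  }
  lab <- as.vector(zones@labels)
  inStudy <- which(!is.na(lab))
  uIdx <- locateUnits(g, units)[inStudy]
  if (anyNA(uIdx)) {
    ## study-area cells outside every unit (tolerance slivers): attach to
    ## the nearest unit centroid
    miss <- which(is.na(uIdx))
    cc <- cellCenters(g)[inStudy[miss], , drop = FALSE]
    ctr <- units@centroids
    for (m in seq_along(miss)) {
      uIdx[miss[m]] <- which.min((ctr[, 1] - cc[m, 1])^2 +
                                 (ctr[, 2] - cc[m, 2])^2)
    }
  }
  at <- accessTable(access)
  data.frame(
    cell = inStudy,
    heat = factor(heatGroupOf(lab[inStudy]), HEAT_GROUPS),
    access = factor(as.character(at$class3[uIdx]), ACCESS_LEVELS3),
    service = factor(ifelse(as.vector(composite)[inStudy], "enjoy",
                            "not-enjoy"), c("enjoy", "not-enjoy")),
    supply = factor(at$supplyFlag[uIdx],
                    c("supply>=demand", "supply<demand")),
    stringsAsFactors = FALSE)
}

#' Merge partition codes into the six named zones
#'
#' @param codes output of [partitionCodes()].
#' @param grid the analysis [SpatialGrid-class].
#' @param mapping a (supply, heat, service) -> zone table; must cover all
#'   2 x 3 x 2 combinations. Default [defaultZoneMapping()].
#' @return an [IntegratedZoneMap-class].
#' @export
mergePartitions <- function(codes, grid, mapping = defaultZoneMapping()) {
  combos <- expand.grid(supply = c("supply>=demand", "supply<demand"),
                        heat = HEAT_GROUPS,
                        service = c("enjoy", "not-enjoy"),
                        stringsAsFactors = FALSE)
  key <- function(s, h, v) paste(s, h, v, sep = "|")
  mapKeys <- key(mapping$supply, mapping$heat, mapping$service)
  if (anyDuplicated(mapKeys)) stop("mapping has duplicate combinations")
  missing <- setdiff(key(combos$supply, combos$heat, combos$service), mapKeys)
  if (length(missing)) {
    stop("mapping is not total; missing: ", paste(missing, collapse = "; "))
  }
  if (!all(mapping$zone %in% ZONE_LEVELS)) {
    stop("mapping zones must be the six named areas")
  }
  g <- gridGeometry(grid)
  zoneOf <- mapping$zone[match(key(codes$supply, codes$heat, codes$service),
                               mapKeys)]
  zm <- matrix(NA_integer_, g@nrow, g@ncol)
  zm[codes$cell] <- match(zoneOf, ZONE_LEVELS)
  new("IntegratedZoneMap", grid = g, zone = zm, levels = ZONE_LEVELS,
      mapping = mapping)
}

#' Area report of an integrated zone map
#'
#' @param map an [IntegratedZoneMap-class].
#' @return data.frame(zone, area_km2, percent) over the six named areas
#'   (empty zones kept as 0.00 rows) plus a total row; percents half-up to
#'   two decimals.
#' @export
zoneReport <- function(map) {
  cellKm2 <- cellAreaM2(map) / 1e6
  n <- tabulate(map@zone[!is.na(map@zone)], nbins = length(map@levels))
  areas <- n * cellKm2
  tot <- sum(areas)
  pct <- if (tot > 0) ratioPercent(areas, tot) else rep(0, length(areas))
  rbind(
    data.frame(zone = map@levels, area_km2 = areas, percent = pct,
               stringsAsFactors = FALSE),
    data.frame(zone = "Total", area_km2 = tot,
               percent = if (tot > 0) sum(pct) else 0))
}
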