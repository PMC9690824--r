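## Three green-space service functions and their buffer-analysis layers:
## cooling (log area-radius rule), recreation (420 m / 1250 m walking
## scales, parks only) and disaster-prevention shelter (piecewise radii by
## size class). Layers live on an analysis grid: a cell is covered by a
## source when its centre lies within the source's footprint or outward
## buffer; union = covered by >= 1 source, overlap = covered by >= 2.

SERVICE_FUNS <- c("cooling", "recreation_420", "recreation_1250", "disaster")

#' Cooling (heat-island mitigation) service radius
#'
#' Maximum cooling distance of a green patch, logarithmic in its area:
#' y = 53.668 * ln(x) - 448.33 with x in m2 and y in meters, clamped at 0
#' (patches below the ~4246 m2 zero-crossing cool only themselves). The rule
#' is continuous and nondecreasing in area.
#'
#' @param area_m2 green patch area in m2 (vectorised, must be positive).
#' @return radius in meters (>= 0).
#' @examples
#' coolingRadius(exp(9))   # 53.668 * 9 - 448.33 = 34.682
#' coolingRadius(1000)     # 0 (raw value negative, clamped)
#' @export
coolingRadius <- function(area_m2) {
  if (any(!is.finite(area_m2)) || any(area_m2 <= 0)) {
    stop("area_m2 must be positive")
  }
  pmax(0, 53.668 * log(area_m2) - 448.33)
}

#' Disaster-prevention shelter radius by size class
#'
#' Park green space: 0.5-1 ha -> 500 m, 1-10 ha -> 1000 m, 10-50 ha ->
#' 2000 m, >= 50 ha -> 3000 m; below 0.5 ha no shelter service (radius 0).
#' Protective buffer green: >= 0.5 ha -> 300 m, else 0.
#'
#' @param category "park" or "buffer" (vectorised with `area_m2`).
#' @param area_m2 patch area in m2, positive.
#' @return radius in meters.
#' @examples
#' disasterRadius("park", 5e4)    # 1000 (5 ha)
#' disasterRadius("buffer", 2e4)  # 300
#' @export
disasterRadius <- function(category, area_m2) {
  if (any(!is.finite(area_m2)) || any(area_m2 <= 0)) {
    stop("area_m2 must be positive")
  }
  n <- max(length(category), length(area_m2))
  category <- rep_len(category, n); area_m2 <- rep_len(area_m2, n)
  if (!all(category %in% c("park", "buffer"))) {
    stop("unknown green-space category: ",
         paste(setdiff(category, c("park", "buffer")), collapse = ", "))
  }
  ha <- area_m2 / 1e4
  park <- ifelse(ha >= 50, 3000,
          ifelse(ha >= 10, 2000,
          ifelse(ha >= 1, 1000,
          ifelse(ha >= 0.5, 500, 0))))
  buf <- ifelse(ha >= 0.5, 300, 0)
  ifelse(category == "park", park, buf)
}

#' Recreation walking-scale radii
#'
#' The two recreation scales: an inner disk reachable in under 5 minutes on
#' foot and the full 15-minute life-circle disk. At the 5 km/h walking
#' standard 15 minutes is exactly 1250 m; the inner scale is the
#' conventional 420 m (5 minutes is 416.7 m, rounded up to the planning
#' value). The scales are cumulative: the 1250 m layer is the full 0-1250 m
#' disk containing the 420 m layer.
#'
#' @return named numeric c(inner = 420, outer = 1250), meters.
#' @examples
#' recreationRadii()
#' walkDistance(15)  # 1250
#' @export
recreationRadii <- function() c(inner = 420, outer = 1250)

#' Walking distance for a travel time
#' @param minutes travel time in minutes (>= 0).
#' @param speed_kmh walking speed (default 5 km/h).
#' @return distance in meters.
#' @export
walkDistance <- function(minutes, speed_kmh = 5) {
  if (any(minutes < 0)) stop("minutes must be nonnegative")
  minutes / 60 * speed_kmh * 1000
}

## Which sources does a service function use (Table-1-style eligibility)?
## Cooling and disaster serve parks and protective buffers; recreation is
## parks only.
eligibleCategories <- function(fun) {
  switch(fun,
         cooling = c("park", "buffer"),
         recreation_420 = "park",
         recreation_1250 = "park",
         disaster = c("park", "buffer"))
}

#' Buffer radius of each green patch under a service function
#'
#' @param greens a [GreenSpaceSet-class].
#' @param fun one of "cooling", "recreation_420", "recreation_1250",
#'   "disaster".
#' @return named numeric vector of radii (m) for the eligible sources;
#'   disaster sources below their smallest size class are dropped (they
#'   provide no shelter service).
#' @export
serviceRadii <- function(greens, fun = SERVICE_FUNS) {
  fun <- match.arg(fun)
  info <- greenInfo(greens)
  keep <- info$category %in% eligibleCategories(fun)
  info <- info[keep, , drop = FALSE]
  r <- switch(fun,
    cooling = coolingRadius(info$area_m2),
    recreation_420 = rep(recreationRadii()[["inner"]], nrow(info)),
    recreation_1250 = rep(recreationRadii()[["outer"]], nrow(info)),
    disaster = disasterRadius(info$category, info$area_m2))
  r <- as.numeric(r)
  names(r) <- info$id
  if (fun == "disaster") r <- r[r > 0]
  r
}

#' Build a service layer
#'
#' For every eligible source, its service buffer is the set of grid cells
#' whose centres lie within the rule radius of the patch (measured outward
#' from the polygon boundary; the footprint itself, distance 0, always
#' counts as served). The layer records how many buffers cover each cell,
#' clipped to the study area.
#'
#' @param greens a [GreenSpaceSet-class].
#' @param fun service function tag.
#' @param area a [StudyArea-class].
#' @param grid a [SpatialGrid-class]; default 50 m cells over the area.
#' @return a [ServiceLayer-class].
#' @export
buildServiceLayer <- function(greens, fun = SERVICE_FUNS, area,
                              grid = gridOverArea(area, 50)) {
  fun <- match.arg(fun)
  g <- gridGeometry(grid)
  radii <- serviceRadii(greens, fun)
  mask <- studyAreaMask(g, area)
  counts <- matrix(0L, g@nrow, g@ncol)
  if (length(radii)) {
    cc <- cellCenters(g)
    info <- greenInfo(greens)
    for (id in names(radii)) {
      poly <- geometries(greens)[[match(id, info$id)]]
      if (nrow(poly) < 3L) stop("invalid geometry for source ", id)
      covered <- distanceToPolygon(cc, poly) <= radii[[id]]
      counts <- counts + matrix(as.integer(covered), g@nrow, g@ncol)
    }
  }
  counts[!mask] <- 0L
  new("ServiceLayer", fun = fun, grid = g, counts = counts,
      studyMask = mask, radii = radii)
}

#' Union / overlap area of a service layer in km2
#' @param layer a [ServiceLayer-class].
#' @export
unionAreaKm2 <- function(layer) {
  sum(layer@counts >= 1L) * cellAreaM2(layer) / 1e6
}

#' @rdname unionAreaKm2
#' @export
overlapAreaKm2 <- function(layer) {
  sum(layer@counts >= 2L) * cellAreaM2(layer) / 1e6
}

#' Overlap statistics of a service layer
#'
#' @param layer a [ServiceLayer-class].
#' @return named numeric: overlap_km2 and percent_of_union (half-up, two
#'   decimals; 0 when the union is empty).
#' @examples
#' ratioPercent(2.331, 25.237)  # 9.24, the reported form of the percent
#' @export
overlapStats <- function(layer) {
  u <- unionAreaKm2(layer); o <- overlapAreaKm2(layer)
  c(overlap_km2 = o,
    percent_of_union = if (u > 0) ratioPercent(o, u) else 0)
}

#' Service coverage by heat zone
#'
#' Area of (service union intersect zone) and the coverage ratio per heat
#' zone, with a totals row. Ratios are half-up two-decimal percentages of
#' the zone area.
#'
#' @param layer a [ServiceLayer-class].
#' @param zones a [HeatZoneMap-class] on the same grid.
#' @return data.frame(zone, zone_km2, served_km2, ratio_percent).
#' @export
coverageByZone <- function(layer, zones) {
  if (!identical(dim(zones@labels), dim(layer@counts))) {
    stop("layer and zones must share one analysis grid")
  }
  cellKm2 <- cellAreaM2(layer) / 1e6
  k <- length(zones@levels)
  lab <- zones@labels
  served <- layer@counts >= 1L
  zoneN <- tabulate(lab[!is.na(lab)], nbins = k)
  servN <- tabulate(lab[!is.na(lab) & served], nbins = k)
  zkm <- zoneN * cellKm2; skm <- servN * cellKm2
  ratio <- ifelse(zkm > 0, ratioPercent(skm, pmax(zkm, .Machine$double.xmin)),
                  0)
  rbind(
    data.frame(zone = zones@levels, zone_km2 = zkm, served_km2 = skm,
               ratio_percent = ratio, stringsAsFactors = FALSE),
    data.frame(zone = "Total", zone_km2 = sum(zkm), served_km2 = sum(skm),
               ratio_percent = if (sum(zkm) > 0)
                 ratioPercent(sum(skm), sum(zkm)) else 0))
}

#' Composite three-service space
#'
#' The region enjoying all three services at once: the intersection of the
#' cooling, recreation (1250 m scale) and disaster union geometries, clipped
#' to the study area.
#'
#' @param layers list of three [ServiceLayer-class] objects containing the
#'   "cooling", "recreation_1250" and "disaster" functions (any order).
#' @return logical nrow x ncol matrix (TRUE = inside the composite space)
#'   with attributes `grid` (the shared [SpatialGrid-class]) and `area_km2`.
#' @export
compositeService <- function(layers) {
  tags <- vapply(layers, function(l) l@fun, character(1))
  need <- c("cooling", "recreation_1250", "disaster")
  if (!all(need %in% tags)) {
    stop("composite needs cooling, recreation_1250 and disaster layers; ",
         "missing: ", paste(setdiff(need, tags), collapse = ", "))
  }
  sel <- layers[match(need, tags)]
  g <- sel[[1]]@grid
  for (l in sel[-1]) {
    if (!identical(dim(l@counts), dim(sel[[1]]@counts))) {
      stop("service layers must share one analysis grid")
    }
  }
  m <- sel[[1]]@counts >= 1L & sel[[2]]@counts >= 1L & sel[[3]]@counts >= 1L
  structure(m, grid = g, area_km2 = sum(m) * g@cellSize^2 / 1e6)
}
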