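## Central S4 containers. Coordinates are always projected planar meters in a
## local, dimensionless CRS; rasters store values in a nrow x ncol matrix with
## row 1 the southernmost row of cells and column 1 the westernmost.

#' @import methods
NULL

#' SpatialGrid: a regular raster geometry
#'
#' Origin is the lower-left corner of the lower-left cell; `cellSize` is the
#' square cell edge in meters. Cell (r, c) has its centre at
#' (x0 + (c - 0.5) * cellSize, y0 + (r - 0.5) * cellSize).
#'
#' @slot x0,y0 numeric, lower-left corner.
#' @slot cellSize numeric, cell edge in meters.
#' @slot nrow,ncol integer grid dimensions.
#' @export
setClass("SpatialGrid",
  representation(x0 = "numeric", y0 = "numeric", cellSize = "numeric",
                 nrow = "integer", ncol = "integer"),
  validity = function(object) {
    if (object@cellSize <= 0) return("cellSize must be positive")
    if (object@nrow < 1L || object@ncol < 1L) return("empty grid")
    TRUE
  })

#' Construct a SpatialGrid
#'
#' @param x0,y0 lower-left corner (meters).
#' @param cellSize cell edge (meters).
#' @param nrow,ncol grid dimensions.
#' @return a [SpatialGrid-class] object.
#' @export
spatialGrid <- function(x0, y0, cellSize, nrow, ncol) {
  new("SpatialGrid", x0 = as.numeric(x0), y0 = as.numeric(y0),
      cellSize = as.numeric(cellSize),
      nrow = as.integer(nrow), ncol = as.integer(ncol))
}

#' Grid covering a study area at a given resolution
#'
#' @param area a [StudyArea-class].
#' @param cellSize cell edge in meters.
#' @return a [SpatialGrid-class] spanning the area's bounding box.
#' @export
gridOverArea <- function(area, cellSize) {
  stopifnotScalarPositive(cellSize, "cellSize")
  b <- boundary(area)
  spatialGrid(min(b[, 1]), min(b[, 2]), cellSize,
              ceiling((max(b[, 2]) - min(b[, 2])) / cellSize),
              ceiling((max(b[, 1]) - min(b[, 1])) / cellSize))
}

#' StudyArea: the built-up-area polygon under analysis
#'
#' @slot boundary two-column vertex matrix (meters), simple polygon.
#' @export
setClass("StudyArea", representation(boundary = "matrix"),
  validity = function(object) {
    if (ncol(object@boundary) != 2L) return("boundary must be two-column")
    if (nrow(object@boundary) < 3L) return("boundary needs >= 3 vertices")
    if (polygonArea(object@boundary) <= 0) return("area must be positive")
    TRUE
  })

#' GreenSpaceSet: green-space patches with category and area
#'
#' The supply side of every analysis: park green space provides cooling,
#' recreation and disaster shelter; protective buffer green provides cooling
#' and disaster shelter only.
#'
#' @slot geoms list of two-column vertex matrices.
#' @slot info data.frame with columns id (character), category
#'   ("park" or "buffer") and area_m2 (numeric, shoelace area).
#' @export
setClass("GreenSpaceSet", representation(geoms = "list", info = "data.frame"),
  validity = function(object) {
    n <- length(object@geoms)
    if (nrow(object@info) != n) return("info rows must match geoms")
    need <- c("id", "category", "area_m2")
    if (!all(need %in% names(object@info))) {
      return("info needs id, category, area_m2")
    }
    if (n == 0L) return(TRUE)
    if (!all(object@info$category %in% c("park", "buffer"))) {
      return("category must be 'park' or 'buffer'")
    }
    geo <- vapply(object@geoms, polygonArea, numeric(1))
    if (any(abs(geo - object@info$area_m2) > 1e-6 * pmax(geo, 1))) {
      return("area_m2 must equal geometric area (1e-6 relative)")
    }
    if (anyDuplicated(object@info$id)) return("duplicate ids")
    TRUE
  })

#' Construct a GreenSpaceSet
#'
#' @param geoms list of two-column vertex matrices (meters).
#' @param id character ids (default g1, g2, ...).
#' @param category "park" or "buffer", recycled.
#' @return a [GreenSpaceSet-class].
#' @export
greenSpaceSet <- function(geoms, id = NULL,
                          category = rep("park", length(geoms))) {
  n <- length(geoms)
  if (is.null(id)) id <- if (n) paste0("g", seq_len(n)) else character(0)
  info <- data.frame(id = as.character(id),
                     category = rep_len(as.character(category), n),
                     area_m2 = if (n) vapply(geoms, polygonArea, numeric(1))
                               else numeric(0),
                     stringsAsFactors = FALSE)
  new("GreenSpaceSet", geoms = geoms, info = info)
}

#' PoiSet: points of interest proxying daily human activity
#'
#' @slot coords two-column matrix of point locations (meters).
#' @slot info data.frame with columns id and category (one of the daily-life
#'   POI classes).
#' @export
setClass("PoiSet", representation(coords = "matrix", info = "data.frame"),
  validity = function(object) {
    if (ncol(object@coords) != 2L) return("coords must be two-column")
    if (nrow(object@info) != nrow(object@coords)) {
      return("info rows must match coords")
    }
    TRUE
  })

#' Construct a PoiSet
#' @param coords two-column matrix (meters).
#' @param category character vector of POI classes, recycled.
#' @param id character ids (default p1, p2, ...).
#' @return a [PoiSet-class].
#' @export
poiSet <- function(coords, category = "life_service", id = NULL) {
  coords <- matrix(as.numeric(coords), ncol = 2,
                   dimnames = list(NULL, c("x", "y")))
  n <- nrow(coords)
  if (is.null(id)) id <- if (n) paste0("p", seq_len(n)) else character(0)
  new("PoiSet", coords = coords,
      info = data.frame(id = as.character(id),
                        category = rep_len(as.character(category), n),
                        stringsAsFactors = FALSE))
}

#' PopulationRaster: gridded residential population counts
#'
#' @slot grid a [SpatialGrid-class].
#' @slot counts numeric matrix (persons per cell), nonnegative.
#' @export
setClass("PopulationRaster",
  representation(grid = "SpatialGrid", counts = "matrix"),
  validity = function(object) {
    if (nrow(object@counts) != object@grid@nrow ||
        ncol(object@counts) != object@grid@ncol) {
      return("counts dimensions must match grid")
    }
    if (any(object@counts < 0)) return("counts must be nonnegative")
    TRUE
  })

#' DemandUnitSet: polygonal demand units with population
#'
#' The demand side of the catchment model: each unit is represented by its
#' centroid in distance computations, with population aggregated from the
#' population raster.
#'
#' @slot geoms list of two-column vertex matrices.
#' @slot centroids two-column matrix of unit centroids.
#' @slot info data.frame with columns id and population.
#' @export
setClass("DemandUnitSet",
  representation(geoms = "list", centroids = "matrix", info = "data.frame"),
  validity = function(object) {
    n <- length(object@geoms)
    if (nrow(object@centroids) != n || nrow(object@info) != n) {
      return("centroids/info must match geoms")
    }
    if (n && any(object@info$population < 0)) {
      return("population must be nonnegative")
    }
    TRUE
  })

#' HeatSurface: the residents' life-heat kernel-density raster
#'
#' @slot grid a [SpatialGrid-class].
#' @slot values numeric matrix of density values (per square meter).
#' @slot bandwidth kernel search radius h in meters.
#' @slot kernel "printed" (unnormalised, mass 1/2) or "quartic" (mass 1).
#' @export
setClass("HeatSurface",
  representation(grid = "SpatialGrid", values = "matrix",
                 bandwidth = "numeric", kernel = "character"),
  validity = function(object) {
    if (nrow(object@values) != object@grid@nrow ||
        ncol(object@values) != object@grid@ncol) {
      return("values dimensions must match grid")
    }
    if (object@bandwidth <= 0) return("bandwidth must be positive")
    if (any(object@values < 0)) return("density must be nonnegative")
    TRUE
  })

#' HeatZoneMap: five ordered life-heat density zones
#'
#' Labels are 1..k from coldest to hottest; `levels` names them. Cells outside
#' the study area are NA.
#'
#' @slot grid a [SpatialGrid-class].
#' @slot labels integer matrix of zone indices (NA outside study area).
#' @slot breaks numeric upper class bounds (k - 1 inner breaks).
#' @slot levels character zone names, coldest first.
#' @export
setClass("HeatZoneMap",
  representation(grid = "SpatialGrid", labels = "matrix", breaks = "numeric",
                 levels = "character"),
  validity = function(object) {
    k <- length(object@levels)
    if (length(object@breaks) != k - 1L) return("need k - 1 inner breaks")
    if (is.unsorted(object@breaks, strictly = TRUE)) {
      return("breaks must be strictly increasing")
    }
    lab <- object@labels[!is.na(object@labels)]
    if (length(lab) && (min(lab) < 1L || max(lab) > k)) {
      return("labels out of range")
    }
    TRUE
  })

#' ServiceLayer: one service function's spatial footprint
#'
#' Grid representation of a buffer analysis: per-cell count of individual
#' service buffers (source footprint plus its outward buffer) covering the
#' cell, restricted to the study area. Union = count >= 1, overlap =
#' count >= 2.
#'
#' @slot fun service tag: "cooling", "recreation_420", "recreation_1250" or
#'   "disaster".
#' @slot grid a [SpatialGrid-class].
#' @slot counts integer matrix of covering-buffer counts (0 outside study).
#' @slot studyMask logical matrix, TRUE for cells inside the study area.
#' @slot radii named numeric vector of buffer radii (m) per eligible source.
#' @export
setClass("ServiceLayer",
  representation(fun = "character", grid = "SpatialGrid", counts = "matrix",
                 studyMask = "matrix", radii = "numeric"),
  validity = function(object) {
    if (!object@fun %in% c("cooling", "recreation_420", "recreation_1250",
                           "disaster")) {
      return("unknown service function")
    }
    if (any(dim(object@counts) != c(object@grid@nrow, object@grid@ncol)) ||
        any(dim(object@studyMask) != dim(object@counts))) {
      return("matrix dimensions must match grid")
    }
    if (any(object@counts[!object@studyMask] != 0L)) {
      return("counts must be zero outside the study area")
    }
    if (length(object@radii) && any(object@radii < 0)) {
      return("radii must be nonnegative")
    }
    TRUE
  })

#' AccessibilityResult: per-unit Gaussian 2SFCA accessibility
#'
#' @slot units data.frame with columns id, population, score (m2 per person),
#'   class4 (low/medium/mid-high/high), class3 (low/medium/high collapse) and
#'   supplyFlag ("supply>=demand" or "supply<demand").
#' @slot benchmark per-capita park area (m2/person) used for the supply flag.
#' @slot d0 catchment threshold in meters.
#' @export
setClass("AccessibilityResult",
  representation(units = "data.frame", benchmark = "numeric", d0 = "numeric"),
  validity = function(object) {
    need <- c("id", "population", "score")
    if (!all(need %in% names(object@units))) {
      return("units needs id, population, score")
    }
    if (any(object@units$score < 0)) return("scores must be nonnegative")
    TRUE
  })

#' IntegratedZoneMap: the six named equity zones
#'
#' @slot grid a [SpatialGrid-class].
#' @slot zone integer matrix indexing into `levels` (NA outside study area).
#' @slot levels the six zone names.
#' @slot mapping the (supply, heat group, service) -> zone table used.
#' @export
setClass("IntegratedZoneMap",
  representation(grid = "SpatialGrid", zone = "matrix", levels = "character",
                 mapping = "data.frame"))

#' SynthConfig: parameters of the synthetic-city generator
#'
#' Defaults mirror the study conditions the analysis assumes: a compact
#' built-up frame of 7000 x 6500 m (45.5 km2), 1294 points of interest whose
#' density decays irregularly from an old-town centre, a 100 m population
#' raster, and 233 demand units.
#'
#' @slot seed integer RNG seed; identical configs give identical cities.
#' @slot extent numeric length 2, (width, height) in meters.
#' @slot nParks,nBuffers integer counts of park / protective-buffer patches.
#' @slot parkAreaRange numeric length 2, park area bounds in m2.
#' @slot nPoi integer number of points of interest.
#' @slot poiCenters data.frame(x, y, weight, spread_m) of POI cluster centres
#'   in fractional coordinates of the extent (x, y in \[0, 1\]); remaining
#'   weight is a uniform background.
#' @slot populationTotal numeric total residents.
#' @slot popCellM population raster resolution in meters.
#' @slot demandUnitCount integer number of demand units.
#' @export
setClass("SynthConfig",
  representation(seed = "integer", extent = "numeric", nParks = "integer",
                 nBuffers = "integer", parkAreaRange = "numeric",
                 nPoi = "integer", poiCenters = "data.frame",
                 populationTotal = "numeric", popCellM = "numeric",
                 demandUnitCount = "integer"),
  validity = function(object) {
    if (length(object@extent) != 2L || any(object@extent <= 0)) {
      return("extent must be two positive lengths")
    }
    if (object@nParks < 0L || object@nBuffers < 0L) {
      return("counts must be nonnegative")
    }
    if (length(object@parkAreaRange) != 2L ||
        object@parkAreaRange[1] <= 0 ||
        object@parkAreaRange[1] >= object@parkAreaRange[2]) {
      return("parkAreaRange must be 0 < min < max")
    }
    if (object@nPoi < 1L) return("nPoi must be >= 1")
    if (object@populationTotal <= 0) return("populationTotal must be positive")
    if (object@popCellM <= 0) return("popCellM must be positive")
    if (object@demandUnitCount < 1L) return("demandUnitCount must be >= 1")
    need <- c("x", "y", "weight", "spread_m")
    if (!all(need %in% names(object@poiCenters))) {
      return("poiCenters needs x, y, weight, spread_m")
    }
    if (sum(object@poiCenters$weight) > 1 + 1e-9) {
      return("poiCenters weights must sum to <= 1")
    }
    TRUE
  })
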