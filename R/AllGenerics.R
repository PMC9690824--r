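## Generics, accessors and show methods for the package's S4 containers.

#' @describeIn StudyArea-class boundary vertex matrix
#' @param x,object a package object.
#' @export
setGeneric("boundary", function(x) standardGeneric("boundary"))

#' @export
setMethod("boundary", "StudyArea", function(x) x@boundary)

#' Area in square meters
#' @param x a StudyArea or GreenSpaceSet.
#' @return numeric scalar (StudyArea) or per-patch vector (GreenSpaceSet).
#' @export
setGeneric("areaM2", function(x) standardGeneric("areaM2"))

#' @export
setMethod("areaM2", "StudyArea", function(x) polygonArea(x@boundary))

#' @export
setMethod("areaM2", "GreenSpaceSet", function(x) {
  stats::setNames(x@info$area_m2, x@info$id)
})

#' Raster/grid geometry of an object
#' @param x an object carrying a [SpatialGrid-class].
#' @export
setGeneric("gridGeometry", function(x) standardGeneric("gridGeometry"))

#' @export
setMethod("gridGeometry", "SpatialGrid", function(x) x)
#' @export
setMethod("gridGeometry", "PopulationRaster", function(x) x@grid)
#' @export
setMethod("gridGeometry", "HeatSurface", function(x) x@grid)
#' @export
setMethod("gridGeometry", "HeatZoneMap", function(x) x@grid)
#' @export
setMethod("gridGeometry", "ServiceLayer", function(x) x@grid)
#' @export
setMethod("gridGeometry", "IntegratedZoneMap", function(x) x@grid)

#' Cell-centre coordinates of a grid
#'
#' Returns an (nrow * ncol) x 2 matrix in column-major cell order, matching
#' `as.vector()` of a value matrix on the same grid.
#'
#' @param grid a [SpatialGrid-class] (or object carrying one).
#' @return two-column coordinate matrix (meters).
#' @export
cellCenters <- function(grid) {
  g <- gridGeometry(grid)
  cx <- g@x0 + (seq_len(g@ncol) - 0.5) * g@cellSize
  cy <- g@y0 + (seq_len(g@nrow) - 0.5) * g@cellSize
  cbind(x = rep(cx, each = g@nrow), y = rep(cy, times = g@ncol))
}

#' Cell area of a grid in square meters
#' @param grid a [SpatialGrid-class] (or object carrying one).
#' @export
cellAreaM2 <- function(grid) gridGeometry(grid)@cellSize^2

#' Logical mask of grid cells whose centres fall inside the study area
#' @param grid a [SpatialGrid-class] (or carrier).
#' @param area a [StudyArea-class].
#' @return logical nrow x ncol matrix.
#' @export
studyAreaMask <- function(grid, area) {
  g <- gridGeometry(grid)
  matrix(pointInPolygon(cellCenters(g), boundary(area)), g@nrow, g@ncol)
}

#' Total population
#' @param x a PopulationRaster or DemandUnitSet.
#' @export
setGeneric("totalPopulation", function(x) standardGeneric("totalPopulation"))

#' @export
setMethod("totalPopulation", "PopulationRaster", function(x) sum(x@counts))
#' @export
setMethod("totalPopulation", "DemandUnitSet", function(x) {
  sum(x@info$population)
})

#' Green-space attribute table
#' @param x a [GreenSpaceSet-class].
#' @return data.frame(id, category, area_m2).
#' @export
greenInfo <- function(x) x@info

#' Green-space or demand-unit geometries
#' @param x a GreenSpaceSet or DemandUnitSet.
#' @return list of vertex matrices.
#' @export
geometries <- function(x) x@geoms

#' POI coordinates
#' @param x a [PoiSet-class].
#' @return two-column matrix.
#' @export
poiCoords <- function(x) x@coords

#' Demand-unit attribute table (id, population, centroid coordinates)
#' @param x a [DemandUnitSet-class].
#' @export
unitInfo <- function(x) {
  cbind(x@info, cx = x@centroids[, 1], cy = x@centroids[, 2])
}

#' Per-unit accessibility table
#' @param x an [AccessibilityResult-class].
#' @return data.frame with id, population, score, class4, class3, supplyFlag.
#' @export
accessTable <- function(x) x@units

#' Per-capita benchmark stored in an accessibility result
#' @param x an [AccessibilityResult-class].
#' @export
accessBenchmark <- function(x) x@benchmark

setMethod("show", "SpatialGrid", function(object) {
  cat(sprintf("SpatialGrid: %d x %d cells of %g m (origin %g, %g)\n",
              object@nrow, object@ncol, object@cellSize,
              object@x0, object@y0))
})

setMethod("show", "StudyArea", function(object) {
  cat(sprintf("StudyArea: %d-vertex polygon, %.3f km2\n",
              nrow(object@boundary), polygonArea(object@boundary) / 1e6))
})

setMethod("show", "GreenSpaceSet", function(object) {
  tab <- table(factor(object@info$category, c("park", "buffer")))
  cat(sprintf(
    "GreenSpaceSet: %d patches (%d park, %d buffer), total %.3f km2\n",
    length(object@geoms), tab[["park"]], tab[["buffer"]],
    sum(object@info$area_m2) / 1e6))
})

setMethod("show", "PoiSet", function(object) {
  cat(sprintf("PoiSet: %d points, %d categories\n", nrow(object@coords),
              length(unique(object@info$category))))
})

setMethod("show", "PopulationRaster", function(object) {
  cat(sprintf("PopulationRaster: %d x %d cells of %g m, %.1f persons\n",
              object@grid@nrow, object@grid@ncol, object@grid@cellSize,
              sum(object@counts)))
})

setMethod("show", "DemandUnitSet", function(object) {
  cat(sprintf("DemandUnitSet: %d units, %.1f persons\n",
              length(object@geoms), sum(object@info$population)))
})

setMethod("show", "HeatSurface", function(object) {
  cat(sprintf(
    "HeatSurface: %d x %d cells of %g m, h = %g m, kernel = %s\n",
    object@grid@nrow, object@grid@ncol, object@grid@cellSize,
    object@bandwidth, object@kernel))
})

setMethod("show", "HeatZoneMap", function(object) {
  cat("HeatZoneMap:", paste(object@levels, collapse = " < "), "\n")
})

setMethod("show", "ServiceLayer", function(object) {
  cat(sprintf("ServiceLayer '%s': %d sources, union %.3f km2, overlap %.3f km2\n",
              object@fun, length(object@radii), unionAreaKm2(object),
              overlapAreaKm2(object)))
})

setMethod("show", "AccessibilityResult", function(object) {
  cat(sprintf(
    "AccessibilityResult: %d units, d0 = %g m, benchmark %.2f m2/person\n",
    nrow(object@units), object@d0, object@benchmark))
})

setMethod("show", "IntegratedZoneMap", function(object) {
  cat("IntegratedZoneMap:", length(object@levels), "named zones\n")
})

setMethod("show", "SynthConfig", function(object) {
  cat(sprintf(
    "SynthConfig: seed %d, %g x %g m, %d parks + %d buffers, %d POIs, %g persons, %d units\n",
    object@seed, object@extent[1], object@extent[2], object@nParks,
    object@nBuffers, object@nPoi, object@populationTotal,
    object@demandUnitCount))
})
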