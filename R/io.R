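## Plain-text geospatial I/O. Vector layers travel as GeoJSON
## FeatureCollections carrying a named local-meter CRS member; rasters as
## ESRI ASCII grids (.asc); tables as CSV; configuration as YAML. All
## coordinates are projected meters — a file announcing a geographic
## (degree) CRS is refused unless the caller overrides.

LOCAL_CRS_NAME <- "urn:greenserv:local-meters"
GEOGRAPHIC_CRS <- c("urn:ogc:def:crs:OGC:1.3:CRS84", "EPSG:4326",
                    "urn:ogc:def:crs:EPSG::4326", "CRS84")

closeRing <- function(xy) rbind(xy, xy[1, , drop = FALSE])

featureOf <- function(geomType, coords, props) {
  list(type = "Feature", properties = props,
       geometry = list(type = geomType, coordinates = coords))
}

polygonCoords <- function(xy) list(lapply(seq_len(nrow(xy) + 1L), function(i) {
  r <- closeRing(xy)
  c(r[i, 1], r[i, 2])
}))

#' Write a vector layer as GeoJSON
#'
#' Supports [StudyArea-class], [GreenSpaceSet-class], [PoiSet-class] and
#' [DemandUnitSet-class]. Coordinates are written at full double precision
#' so a write/read round trip preserves geometry to better than 1e-9 m.
#'
#' @param x the layer.
#' @param path output file path (.geojson).
#' @return `path`, invisibly.
#' @export
writeVector <- function(x, path) {
  feats <- if (is(x, "StudyArea")) {
    list(featureOf("Polygon", polygonCoords(boundary(x)),
                   list(layer = "study_area")))
  } else if (is(x, "GreenSpaceSet")) {
    info <- greenInfo(x)
    lapply(seq_along(x@geoms), function(i) {
      featureOf("Polygon", polygonCoords(x@geoms[[i]]),
                list(layer = "green_space", id = info$id[i],
                     category = info$category[i],
                     area_m2 = info$area_m2[i]))
    })
  } else if (is(x, "PoiSet")) {
    lapply(seq_len(nrow(x@coords)), function(i) {
      featureOf("Point", c(x@coords[i, 1], x@coords[i, 2]),
                list(layer = "poi", id = x@info$id[i],
                     category = x@info$category[i]))
    })
  } else if (is(x, "DemandUnitSet")) {
    lapply(seq_along(x@geoms), function(i) {
      featureOf("Polygon", polygonCoords(x@geoms[[i]]),
                list(layer = "demand_unit", id = x@info$id[i],
                     population = x@info$population[i],
                     cx = x@centroids[i, 1], cy = x@centroids[i, 2]))
    })
  } else stop("unsupported layer class: ", class(x)[1])
  fc <- list(type = "FeatureCollection",
             crs = list(type = "name",
                        properties = list(name = LOCAL_CRS_NAME)),
             features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}

#' Read a vector layer from GeoJSON
#'
#' Reconstructs the package object the file was written from (dispatching on
#' the per-feature `layer` property). Files declaring a geographic (degree)
#' CRS are refused unless `assumeProjected = TRUE`.
#'
#' @param path GeoJSON file path.
#' @param assumeProjected treat coordinates as projected meters even if the
#'   file declares a geographic CRS.
#' @return a StudyArea, GreenSpaceSet, PoiSet or DemandUnitSet.
#' @export
readVector <- function(path, assumeProjected = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  fc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(fc$type, "FeatureCollection")) {
    stop("not a GeoJSON FeatureCollection: ", path)
  }
  crs <- tryCatch(fc$crs$properties$name, error = function(e) NULL)
  if (!assumeProjected &&
      (is.null(crs) || crs %in% GEOGRAPHIC_CRS)) {
    stop("geographic (degree) CRS '", if (is.null(crs)) "default WGS84"
         else crs,
         "' in ", path,
         ": reproject to planar meters or set assumeProjected = TRUE")
  }
  feats <- fc$features
  if (!length(feats)) stop("empty FeatureCollection: ", path)
  ringToMatrix <- function(ring) {
    m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    m[-nrow(m), , drop = FALSE]   # drop closing vertex
  }
  layer <- feats[[1]]$properties$layer
  if (identical(layer, "study_area")) {
    new("StudyArea",
        boundary = ringToMatrix(feats[[1]]$geometry$coordinates[[1]]))
  } else if (identical(layer, "green_space")) {
    geoms <- lapply(feats, function(f) {
      ringToMatrix(f$geometry$coordinates[[1]])
    })
    greenSpaceSet(geoms,
                  id = vapply(feats, function(f) f$properties$id,
                              character(1)),
                  category = vapply(feats, function(f) f$properties$category,
                                    character(1)))
  } else if (identical(layer, "poi")) {
    xy <- do.call(rbind, lapply(feats, function(f) {
      c(f$geometry$coordinates[[1]], f$geometry$coordinates[[2]])
    }))
    poiSet(xy,
           category = vapply(feats, function(f) f$properties$category,
                             character(1)),
           id = vapply(feats, function(f) f$properties$id, character(1)))
  } else if (identical(layer, "demand_unit")) {
    geoms <- lapply(feats, function(f) {
      ringToMatrix(f$geometry$coordinates[[1]])
    })
    new("DemandUnitSet", geoms = geoms,
        centroids = do.call(rbind, lapply(feats, function(f) {
          c(x = f$properties$cx, y = f$properties$cy)
        })),
        info = data.frame(
          id = vapply(feats, function(f) f$properties$id, character(1)),
          population = vapply(feats, function(f) f$properties$population,
                              numeric(1)),
          stringsAsFactors = FALSE))
  } else stop("unknown layer type in ", path)
}

#' Write a raster as an ESRI ASCII grid
#'
#' @param x a [PopulationRaster-class], [HeatSurface-class], or numeric
#'   matrix (then `grid` is required).
#' @param path output .asc path.
#' @param grid the [SpatialGrid-class] when `x` is a bare matrix.
#' @return `path`, invisibly.
#' @export
writeRasterAsc <- function(x, path, grid = NULL) {
  if (is(x, "PopulationRaster")) { m <- x@counts; g <- x@grid }
  else if (is(x, "HeatSurface")) { m <- x@values; g <- x@grid }
  else { m <- as.matrix(x); g <- gridGeometry(grid) }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", ncol(m)),
               sprintf("nrows %d", nrow(m)),
               sprintf("xllcorner %.10g", g@x0),
               sprintf("yllcorner %.10g", g@y0),
               sprintf("cellsize %.10g", g@cellSize),
               "NODATA_value -9999"), con)
  mm <- m; mm[is.na(mm)] <- -9999
  for (r in rev(seq_len(nrow(mm)))) {      # top row first
    writeLines(paste(formatC(mm[r, ], format = "g", digits = 15),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path .asc file path.
#' @return list(grid = [SpatialGrid-class], values = matrix) with NODATA
#'   cells as NA.
#' @export
readRasterAsc <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  vals <- do.call(rbind, lapply(lines[i:length(lines)], function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  }))
  vals <- vals[rev(seq_len(nrow(vals))), , drop = FALSE]  # back to south-up
  if (!is.null(hdr$nodata_value)) vals[vals == hdr$nodata_value] <- NA
  list(grid = spatialGrid(hdr$xllcorner, hdr$yllcorner, hdr$cellsize,
                          hdr$nrows, hdr$ncols),
       values = vals)
}

#' Read / write a pipeline configuration as YAML
#'
#' The YAML mirrors the arguments of [pipelineConfig()]; `poi_centers` is a
#' list of (x, y, weight, spread_m) records.
#'
#' @param path YAML file path.
#' @return for the reader, a pipeline configuration list.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  y <- yaml::read_yaml(path)
  syn <- y$synth %||% list()
  centers <- if (!is.null(syn$poi_centers)) {
    do.call(rbind.data.frame, syn$poi_centers)
  } else NULL
  synArgs <- list(
    seed = syn$seed %||% y$seed %||% 1L,
    extent = unlist(syn$extent %||% c(7000, 6500)),
    nParks = syn$n_parks %||% 24L, nBuffers = syn$n_buffers %||% 6L,
    parkAreaRange = unlist(syn$park_area_range %||% c(5e3, 1e6)),
    nPoi = syn$n_poi %||% 1294L,
    populationTotal = syn$population_total %||% 1e5,
    popCellM = syn$pop_cell_m %||% 100,
    demandUnitCount = syn$demand_unit_count %||% 233L)
  if (!is.null(centers)) synArgs$poiCenters <- centers
  pipelineConfig(synth = do.call(synthConfig, synArgs),
                 bandwidth = y$bandwidth %||% 1250,
                 heatCellM = y$heat_cell_m %||% 50,
                 heatMethod = y$heat_method %||% "jenks",
                 accessMethod = y$access_method %||% "quantile",
                 d0 = y$d0 %||% 1250,
                 outDir = y$out_dir)
}

#' @rdname readPipelineConfig
#' @param cfg a pipeline configuration list from [pipelineConfig()].
#' @export
writePipelineConfig <- function(cfg, path) {
  syn <- cfg$synth
  yaml::write_yaml(list(
    seed = syn@seed,
    bandwidth = cfg$bandwidth, heat_cell_m = cfg$heatCellM,
    heat_method = cfg$heatMethod, access_method = cfg$accessMethod,
    d0 = cfg$d0, out_dir = cfg$outDir,
    synth = list(seed = syn@seed, extent = as.list(syn@extent),
                 n_parks = syn@nParks, n_buffers = syn@nBuffers,
                 park_area_range = as.list(syn@parkAreaRange),
                 n_poi = syn@nPoi,
                 population_total = syn@populationTotal,
                 pop_cell_m = syn@popCellM,
                 demand_unit_count = syn@demandUnitCount,
                 poi_centers = lapply(seq_len(nrow(syn@poiCenters)),
                                      function(i) as.list(syn@poiCenters[i, ])))),
    path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
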