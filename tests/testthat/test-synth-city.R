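cfgSmall <- synthConfig(seed = 11, extent = c(3000, 2500), nParks = 12,
                        nBuffers = 3, nPoi = 150, populationTotal = 5000,
                        demandUnitCount = 40)

test_that("study area matches the configured extent", {
  expect_equal(areaM2(generateStudyArea(synthConfig())), 45.5e6)
  expect_equal(areaM2(generateStudyArea(synthConfig(extent = c(1000, 1000)))),
               1e6)
  a1 <- generateStudyArea(cfgSmall); a2 <- generateStudyArea(cfgSmall)
  expect_identical(boundary(a1), boundary(a2))
})

test_that("generated parks span all four shelter size classes", {
  cfg <- synthConfig(seed = 5, nParks = 20L, nBuffers = 0L,
                     parkAreaRange = c(5e3, 1e6))
  gs <- generateGreenSpaces(cfg, generateStudyArea(cfg))
  a <- greenInfo(gs)$area_m2
  counts <- table(cut(a, c(5e3, 1e4, 1e5, 5e5, Inf), right = FALSE))
  expect_true(all(counts >= 1))
  expect_equal(length(a), 20L)
})

test_that("green-space generation handles empty and strict configs", {
  cfg0 <- synthConfig(seed = 1, nParks = 0L, nBuffers = 0L)
  expect_length(geometries(generateGreenSpaces(cfg0, generateStudyArea(cfg0))),
                0L)
  narrow <- synthConfig(seed = 1, parkAreaRange = c(5e3, 9e3), nParks = 10L)
  expect_error(
    generateGreenSpaces(narrow, generateStudyArea(narrow), strict = TRUE),
    "size class")
  # non-strict: draws stay within the permitted range
  gs <- generateGreenSpaces(narrow, generateStudyArea(narrow))
  parkAreas <- greenInfo(gs)$area_m2[greenInfo(gs)$category == "park"]
  expect_true(all(parkAreas <= 9e3 * 1.001))
})

test_that("green spaces, POIs and population are seed-deterministic", {
  c1 <- synthesizeCity(cfgSmall)
  c2 <- synthesizeCity(cfgSmall)
  expect_identical(greenInfo(c1$greens), greenInfo(c2$greens))
  expect_identical(geometries(c1$greens), geometries(c2$greens))
  expect_identical(poiCoords(c1$pois), poiCoords(c2$pois))
  expect_identical(c1$population@counts, c2$population@counts)
  expect_identical(unitInfo(c1$units), unitInfo(c2$units))
  # a different seed changes the draw
  c3 <- synthesizeCity(synthConfig(seed = 12, extent = c(3000, 2500),
                                   nParks = 12, nBuffers = 3, nPoi = 150,
                                   populationTotal = 5000,
                                   demandUnitCount = 40))
  expect_false(identical(poiCoords(c1$pois), poiCoords(c3$pois)))
})

test_that("POI counts honour the config and points cluster around the centre", {
  area <- generateStudyArea(cfgSmall)
  pois <- generatePois(cfgSmall, area)
  expect_equal(nrow(poiCoords(pois)), 150L)
  expect_false(any(duplicated(poiCoords(pois))))
  expect_true(all(pointInPolygon(poiCoords(pois), boundary(area))))
  one <- synthConfig(seed = 2, nPoi = 1L)
  expect_equal(nrow(poiCoords(generatePois(one, generateStudyArea(one)))), 1L)

  # single tight cluster: mean distance to the centre is far below the
  # uniform-draw expectation (Monte-Carlo reference under the same seed)
  cl <- synthConfig(seed = 9, extent = c(4000, 4000), nPoi = 400,
                    poiCenters = data.frame(x = 0.5, y = 0.5, weight = 0.95,
                                            spread_m = 500))
  xy <- poiCoords(generatePois(cl, generateStudyArea(cl)))
  dCl <- mean(sqrt((xy[, 1] - 2000)^2 + (xy[, 2] - 2000)^2))
  set.seed(1)
  u <- cbind(runif(4000, 0, 4000), runif(4000, 0, 4000))
  dU <- mean(sqrt((u[, 1] - 2000)^2 + (u[, 2] - 2000)^2))
  expect_lt(dCl, dU * 0.6)
})

test_that("population raster normalises exactly and follows POI density", {
  area <- generateStudyArea(cfgSmall)
  pois <- generatePois(cfgSmall, area)
  pop <- generatePopulation(cfgSmall, area, pois)
  expect_equal(totalPopulation(pop), 5000, tolerance = 0.5 / 5000)
  expect_true(all(pop@counts >= 0))

  # no POIs: uniform over the study area
  pop0 <- generatePopulation(cfgSmall, area, poiSet(matrix(numeric(0), 0, 2)))
  v <- pop0@counts[pop0@counts > 0]
  expect_equal(max(v), min(v))

  # the cell holding the main cluster centre is at least as populated as the
  # median study-area cell
  ctr <- cfgSmall@poiCenters[1, ]
  g <- gridGeometry(pop)
  r <- floor(ctr$y * 2500 / g@cellSize) + 1L
  cc <- floor(ctr$x * 3000 / g@cellSize) + 1L
  expect_gte(pop@counts[r, cc], median(pop@counts))
})

test_that("demand units tessellate the study area and conserve population", {
  city <- synthesizeCity(cfgSmall)
  units <- city$units
  expect_length(geometries(units), 40L)
  areas <- vapply(geometries(units), polygonArea, numeric(1))
  expect_equal(sum(areas), areaM2(city$area), tolerance = 1e-9)
  expect_equal(totalPopulation(units), totalPopulation(city$population),
               tolerance = 1e-9)
  # prime counts tessellate too (row splitting handles any N)
  cfgP <- synthConfig(seed = 3, extent = c(3000, 2500), nPoi = 50,
                      populationTotal = 1000, demandUnitCount = 233L)
  cityP <- synthesizeCity(cfgP)
  expect_length(geometries(cityP$units), 233L)
  expect_equal(sum(vapply(geometries(cityP$units), polygonArea, numeric(1))),
               areaM2(cityP$area), tolerance = 1e-9)
})

test_that("a 2 x 2 tessellation of a uniform raster splits population evenly", {
  cfg <- synthConfig(seed = 1, extent = c(2000, 2000), nPoi = 1,
                     populationTotal = 100, demandUnitCount = 4L)
  area <- generateStudyArea(cfg)
  pop <- generatePopulation(cfg, area, poiSet(matrix(numeric(0), 0, 2)))
  units <- generateDemandUnits(cfg, area, pop)
  expect_equal(unname(unitInfo(units)$population), rep(25, 4))
})

test_that("demand-unit count beyond the raster size is rejected", {
  cfg <- synthConfig(seed = 1, extent = c(300, 300), nPoi = 5,
                     populationTotal = 10, demandUnitCount = 100L)
  area <- generateStudyArea(cfg)
  pop <- generatePopulation(cfg, area, generatePois(cfg, area))
  expect_error(generateDemandUnits(cfg, area, pop), "exceeds")
})

test_that("invalid configurations are rejected by class validity", {
  expect_error(synthConfig(extent = c(-1, 100)), "positive")
  expect_error(synthConfig(parkAreaRange = c(10, 5)), "min < max")
  expect_error(synthConfig(nPoi = 0), "nPoi")
})
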