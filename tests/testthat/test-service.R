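test_that("cooling radius follows the logarithmic rule with clamping", {
  expect_equal(coolingRadius(exp(9)), 53.668 * 9 - 448.33)   # 34.682 m
  expect_equal(coolingRadius(1000), 0)                        # raw negative
  x0 <- exp(448.33 / 53.668)                                  # zero crossing
  expect_equal(coolingRadius(x0), 0, tolerance = 1e-9)
  expect_gt(coolingRadius(x0 * 1.01), 0)
  # continuous, nondecreasing over a wide area sweep
  a <- exp(seq(log(100), log(5e6), length.out = 400))
  r <- coolingRadius(a)
  expect_true(all(diff(r) >= 0))
  expect_lt(max(abs(diff(r))), 5)   # no jumps on a fine log grid
  expect_error(coolingRadius(0), "positive")
  expect_error(coolingRadius(-10), "positive")
})

test_that("disaster radii reproduce the shelter size-class table", {
  expect_equal(disasterRadius("park", 0.7e4), 500)    # 0.5-1 ha
  expect_equal(disasterRadius("park", 5e4), 1000)     # 1-10 ha
  expect_equal(disasterRadius("park", 2e5), 2000)     # 10-50 ha
  expect_equal(disasterRadius("park", 6e5), 3000)     # >= 50 ha
  expect_equal(disasterRadius("park", 0.4e4), 0)      # below the table
  expect_equal(disasterRadius("buffer", 2e4), 300)
  expect_equal(disasterRadius("buffer", 0.3e4), 0)
  expect_error(disasterRadius("forest", 1e4), "unknown")
})

test_that("recreation radii come from the 5 km/h walking standard", {
  expect_equal(recreationRadii(), c(inner = 420, outer = 1250))
  expect_equal(walkDistance(15), 1250)
  expect_equal(walkDistance(5), 416.6667, tolerance = 1e-4)
  expect_equal(walkDistance(0), 0)
})

test_that("service eligibility follows the function table", {
  greens <- mkParks(rbind(c(500, 500), c(1500, 500)), c(2e4, 1e4),
                    category = c("park", "buffer"))
  expect_setequal(names(serviceRadii(greens, "cooling")), c("g1", "g2"))
  expect_setequal(names(serviceRadii(greens, "disaster")), c("g1", "g2"))
  # recreation never serves protective buffers
  expect_setequal(names(serviceRadii(greens, "recreation_420")), "g1")
  expect_setequal(names(serviceRadii(greens, "recreation_1250")), "g1")
  # disaster drops sub-0.5 ha sources entirely
  small <- mkParks(rbind(c(500, 500)), 0.4e4)
  expect_length(serviceRadii(small, "disaster"), 0L)
})

test_that("disjoint buffers have empty overlap; identical sources overlap fully", {
  area <- new("StudyArea", boundary = rectPolygon(0, 0, 6000, 2000))
  g <- gridOverArea(area, 25)
  far <- mkParks(rbind(c(800, 1000), c(5200, 1000)), c(2e4, 2e4))
  layer <- buildServiceLayer(far, "disaster", area, g)   # 1000 m each
  expect_equal(overlapAreaKm2(layer), 0)
  expect_gt(unionAreaKm2(layer), 0)
  twin <- greenSpaceSet(list(squarePoly(1000, 1000, 2e4),
                             squarePoly(1000, 1000, 2e4)))
  lTwin <- buildServiceLayer(twin, "disaster", area, g)
  expect_equal(overlapAreaKm2(lTwin), unionAreaKm2(lTwin))
})

test_that("union area is subadditive and monotone in buffer radius", {
  area <- new("StudyArea", boundary = rectPolygon(0, 0, 4000, 4000))
  g <- gridOverArea(area, 25)
  parks <- mkParks(rbind(c(1200, 2000), c(2400, 2000)), c(3e4, 3e4))
  dis <- buildServiceLayer(parks, "disaster", area, g)        # 1000 m
  r420 <- buildServiceLayer(parks, "recreation_420", area, g)
  r1250 <- buildServiceLayer(parks, "recreation_1250", area, g)
  # union <= sum of individual buffer footprints
  perSource <- sum(vapply(seq_len(2), function(i) {
    sum(distanceToPolygon(cellCenters(g), geometries(parks)[[i]]) <= 1000)
  }, numeric(1))) * cellAreaM2(g) / 1e6
  expect_lte(unionAreaKm2(dis), perSource)
  # growing the radius never shrinks the union
  expect_lte(unionAreaKm2(r420), unionAreaKm2(r1250))
  # sources sit inside their own service space
  expect_true(all(dis@counts[studyAreaMask(g, area) &
    matrix(distanceToPolygon(cellCenters(g), geometries(parks)[[1]]) == 0,
           g@nrow, g@ncol)] >= 1L))
})

test_that("layer union/overlap areas match the analytic circle-counting oracle", {
  area <- new("StudyArea", boundary = rectPolygon(0, 0, 2000, 2000))
  g <- gridOverArea(area, 5)     # fine 5 m counting grid
  set.seed(14)
  n <- 6
  centers <- cbind(runif(n, 500, 1500), runif(n, 500, 1500))
  parkR <- runif(n, 60, 120)
  geoms <- lapply(seq_len(n), function(i) {
    circlePolygon(centers[i, ], parkR[i], n = 64L)
  })
  greens <- greenSpaceSet(geoms)
  layer <- buildServiceLayer(greens, "recreation_420", area, g)
  oracle <- circleCoverCounts(g, centers, parkR + 420)
  expect_equal(unionAreaKm2(layer), sum(oracle >= 1) * 25 / 1e6,
               tolerance = 5e-3)
  expect_equal(overlapAreaKm2(layer), sum(oracle >= 2) * 25 / 1e6,
               tolerance = 5e-3)
})

test_that("two-source overlap matches the closed-form lens area", {
  area <- new("StudyArea", boundary = rectPolygon(0, 0, 2500, 1600))
  g <- gridOverArea(area, 5)
  buf <- 500; d <- 700
  R <- sqrt(0.6e4 / pi)              # 0.6 ha park -> 500 m shelter radius
  centers <- rbind(c(900, 800), c(900 + d, 800))
  geoms <- lapply(1:2, function(i) circlePolygon(centers[i, ], R, n = 128L))
  greens <- greenSpaceSet(geoms)
  layer <- buildServiceLayer(greens, "disaster", area, g)
  expect_equal(unname(serviceRadii(greens, "disaster")), c(buf, buf))
  expect_equal(overlapAreaKm2(layer), lensArea(R + buf, d) / 1e6,
               tolerance = 5e-3)
})

test_that("coverage by zone reports served share per heat zone", {
  area <- new("StudyArea", boundary = rectPolygon(0, 0, 1000, 1000))
  g <- gridOverArea(area, 50)
  zones <- new("HeatZoneMap", grid = g,
               labels = matrix(rep(1:5, each = 80), 20, 20),
               breaks = 1:4 + 0.5, levels = greenserv:::HEAT_LEVELS)
  # a layer covering everything: every ratio 100
  big <- greenSpaceSet(list(squarePoly(500, 500, 9e5)))  # 90 ha park
  full <- buildServiceLayer(big, "recreation_1250", area, g)
  tab <- coverageByZone(full, zones)
  expect_equal(tab$ratio_percent[1:5], rep(100, 5))
  # an empty layer: every ratio 0
  none <- buildServiceLayer(greenSpaceSet(list()), "cooling", area, g)
  tab0 <- coverageByZone(none, zones)
  expect_equal(tab0$ratio_percent[1:5], rep(0, 5))
  expect_equal(tab0$served_km2[6], 0)
  # served area never exceeds zone area
  expect_true(all(tab$served_km2 <= tab$zone_km2 + 1e-12))
})

test_that("overlap statistics use the half-up percentage convention", {
  # reported-arithmetic forms: overlap / union
  expect_equal(ratioPercent(2.331, 25.237), 9.24)
  expect_equal(ratioPercent(39.71, 43.69), 90.89)
  area <- new("StudyArea", boundary = rectPolygon(0, 0, 2000, 2000))
  g <- gridOverArea(area, 25)
  far <- mkParks(rbind(c(300, 300), c(1700, 1700)), c(0.6e4, 0.6e4))
  st <- overlapStats(buildServiceLayer(far, "disaster", area, g))  # 500 m apart buffers
  expect_equal(unname(st["overlap_km2"]), 0)
  expect_equal(unname(st["percent_of_union"]), 0)
})

test_that("composite space is the intersection of the three service unions", {
  area <- new("StudyArea", boundary = rectPolygon(0, 0, 3000, 3000))
  g <- gridOverArea(area, 50)
  greens <- mkParks(rbind(c(1000, 1500), c(2000, 1500)), c(5e4, 8e4))
  layers <- lapply(c("cooling", "recreation_1250", "disaster"), function(f) {
    buildServiceLayer(greens, f, area, g)
  })
  comp <- compositeService(layers)
  u <- lapply(layers, function(l) l@counts >= 1L)
  expect_identical(unclass(comp)[, ], u[[1]] & u[[2]] & u[[3]])
  expect_lte(attr(comp, "area_km2"),
             min(vapply(layers, unionAreaKm2, numeric(1))))
  # idempotence: three identical layers give that layer's union
  same <- compositeService(list(layers[[1]],
    new("ServiceLayer", fun = "recreation_1250", grid = g,
        counts = layers[[1]]@counts, studyMask = layers[[1]]@studyMask,
        radii = layers[[1]]@radii),
    new("ServiceLayer", fun = "disaster", grid = g,
        counts = layers[[1]]@counts, studyMask = layers[[1]]@studyMask,
        radii = layers[[1]]@radii)))
  expect_equal(attr(same, "area_km2"), unionAreaKm2(layers[[1]]))
  # an empty layer absorbs the composite
  none <- buildServiceLayer(greenSpaceSet(list()), "disaster", area, g)
  comp0 <- compositeService(list(layers[[1]], layers[[2]], none))
  expect_equal(attr(comp0, "area_km2"), 0)
  expect_error(compositeService(layers[1:2]), "missing")
})
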