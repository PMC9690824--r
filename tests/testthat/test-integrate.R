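# A tiny fully-specified overlay scene used across integration tests:
# 10 x 10 grid, two demand units (west supply-sufficient/high access,
# east supply-deficient/low access), heat increasing south to north.
mkScene <- function(compositeAll = FALSE) {
  area <- new("StudyArea", boundary = rectPolygon(0, 0, 1000, 1000))
  g <- gridOverArea(area, 100)
  zones <- new("HeatZoneMap", grid = g,
               labels = matrix(rep(1:5, each = 2)[row(matrix(0, 10, 10))],
                               10, 10),
               breaks = 1:4 + 0.5, levels = greenserv:::HEAT_LEVELS)
  units <- new("DemandUnitSet",
               geoms = list(rectPolygon(0, 0, 500, 1000),
                            rectPolygon(500, 0, 1000, 1000)),
               centroids = cbind(x = c(250, 750), y = c(500, 500)),
               info = data.frame(id = c("west", "east"),
                                 population = c(100, 200),
                                 stringsAsFactors = FALSE))
  access <- new("AccessibilityResult",
                units = data.frame(id = c("west", "east"),
                                   population = c(100, 200),
                                   score = c(120, 5),
                                   class4 = factor(c("high", "low"),
                                     c("low", "medium", "mid-high", "high")),
                                   class3 = factor(c("high", "low"),
                                     c("low", "medium", "high")),
                                   supplyFlag = c("supply>=demand",
                                                  "supply<demand"),
                                   stringsAsFactors = FALSE),
                benchmark = 50, d0 = 1250)
  comp <- matrix(compositeAll, 10, 10)
  if (!compositeAll) comp[, 1:3] <- TRUE    # west strip enjoys all services
  list(area = area, grid = g, zones = zones, units = units, access = access,
       composite = comp)
}

test_that("every study-area cell gets exactly one of the 18 partition codes", {
  sc <- mkScene()
  codes <- partitionCodes(sc$zones, sc$access, sc$units, sc$composite)
  expect_equal(nrow(codes), 100)
  expect_equal(anyDuplicated(codes$cell), 0)
  expect_true(all(!is.na(codes$heat) & !is.na(codes$access) &
                  !is.na(codes$service)))
  # 3 x 3 x 2 possible codes
  expect_lte(nrow(unique(codes[c("heat", "access", "service")])), 18)
})

test_that("composite covering everything marks every cell as enjoying", {
  sc <- mkScene(compositeAll = TRUE)
  codes <- partitionCodes(sc$zones, sc$access, sc$units, sc$composite)
  expect_true(all(codes$service == "enjoy"))
})

test_that("default mapping reproduces the published partition rows", {
  m <- defaultZoneMapping()
  pick <- function(s, h, v) m$zone[m$supply == s & m$heat == h & m$service == v]
  # supply-sufficient, medium/high heat, enjoying -> high-quality living
  expect_equal(pick("supply>=demand", "medium", "enjoy"),
               "High-quality living area")
  expect_equal(pick("supply>=demand", "high", "enjoy"),
               "High-quality living area")
  expect_equal(pick("supply>=demand", "low", "enjoy"), "Livable area")
  expect_equal(pick("supply<demand", "low", "not-enjoy"),
               "Underdeveloped area")
  expect_equal(pick("supply>=demand", "high", "not-enjoy"),
               "Green space service blind area")
  expect_equal(pick("supply<demand", "medium", "enjoy"),
               "Under supply and demand area")
  expect_equal(pick("supply<demand", "high", "not-enjoy"),
               "Comprehensive blind area")
  # the two combinations the published table omits get nearest-row defaults
  expect_equal(pick("supply>=demand", "low", "not-enjoy"),
               "Green space service blind area")
  expect_equal(pick("supply<demand", "low", "enjoy"), "Livable area")
  # total over all 12 combinations
  expect_equal(nrow(m), 12)
  expect_equal(anyDuplicated(m[c("supply", "heat", "service")]), 0)
})

test_that("merging is exhaustive, idempotent and respects the mapping", {
  sc <- mkScene()
  codes <- partitionCodes(sc$zones, sc$access, sc$units, sc$composite)
  zmap <- mergePartitions(codes, sc$grid)
  expect_equal(sum(!is.na(zmap@zone)), 100)
  zmap2 <- mergePartitions(codes, sc$grid)
  expect_identical(zmap@zone, zmap2@zone)
  # a truncated mapping is rejected
  expect_error(mergePartitions(codes, sc$grid, defaultZoneMapping()[-1, ]),
               "not total")
  # spot-check one cell: east column, Hot row, outside composite =>
  # supply<demand, high heat, not-enjoy -> Comprehensive blind area
  idx <- matrix(seq_len(100), 10, 10)
  expect_equal(zmap@levels[zmap@zone[10, 10]], "Comprehensive blind area")
  # west strip, Hot row, inside composite, supply>=demand -> High-quality
  expect_equal(zmap@levels[zmap@zone[10, 1]], "High-quality living area")
})

test_that("turning service on never moves a cell into a blind zone", {
  m <- defaultZoneMapping()
  pick <- function(s, h, v) m$zone[m$supply == s & m$heat == h & m$service == v]
  blind <- c("Green space service blind area", "Comprehensive blind area")
  for (s in c("supply>=demand", "supply<demand")) {
    for (h in c("low", "medium", "high")) {
      expect_false(pick(s, h, "enjoy") %in% blind,
                   label = sprintf("enjoy cell (%s, %s) not blind", s, h))
    }
  }
})

test_that("zone report conserves area and keeps empty zones as zero rows", {
  sc <- mkScene()
  codes <- partitionCodes(sc$zones, sc$access, sc$units, sc$composite)
  zmap <- mergePartitions(codes, sc$grid)
  rep <- zoneReport(zmap)
  expect_equal(nrow(rep), 7)                 # six zones + total
  expect_equal(rep$area_km2[7], 1, tolerance = 1e-9)   # 1 km2 scene
  expect_equal(sum(rep$area_km2[1:6]), rep$area_km2[7], tolerance = 1e-9)
  expect_equal(sum(rep$percent[1:6]), 100, tolerance = 0.05)
  expect_true(all(rep$percent >= 0))
  # single-code map: one zone holds 100%
  allEnjoy <- mkScene(compositeAll = TRUE)
  codes1 <- partitionCodes(allEnjoy$zones, allEnjoy$access, allEnjoy$units,
                           allEnjoy$composite)
  codes1$heat <- factor("high", greenserv:::HEAT_GROUPS)
  codes1$supply <- factor("supply>=demand",
                          c("supply>=demand", "supply<demand"))
  rep1 <- zoneReport(mergePartitions(codes1, allEnjoy$grid))
  expect_equal(rep1$percent[1], 100)         # all High-quality living area
})
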