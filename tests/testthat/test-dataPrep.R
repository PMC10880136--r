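# Occurrence thinning, native-range filtering, checklist conversion, and
# record classification.

test_that("thinRecords keeps exactly one record per thinning cell", {
  g <- gridSpec(1, origin = c(0, 0))
  rec <- data.frame(lon = c(0.1, 0.2, 0.9, 1.5, 2.2),
                    lat = c(0.1, 0.3, 0.8, 0.5, 0.2))
  occ <- thinRecords(rec, grid = g, seed = 7)
  d <- occurrenceData(occ)
  expect_equal(nrow(d), 3)   # cells (0,0), (1,0), (2,0)
  ids <- cellId(d$lon, d$lat, g)
  expect_false(anyDuplicated(paste(ids[, 1], ids[, 2])) > 0)
  expect_true(occ@thinned)
  expect_true(all(d$status == "unclassified"))
})

test_that("thinRecords is seed-deterministic and order-insensitive", {
  set.seed(99)
  rec <- data.frame(lon = runif(200, 0, 0.5), lat = runif(200, 0, 0.5))
  a <- occurrenceData(thinRecords(rec, seed = 3))
  b <- occurrenceData(thinRecords(rec, seed = 3))
  expect_identical(a, b)
  c_ <- occurrenceData(thinRecords(rec, seed = 4))
  expect_false(identical(a, c_))   # pick within cells depends on the seed
})

test_that("filterNativeRange drops introduced and unknown features", {
  fs <- list(list(polygon = rectPolygon(0, 1, 0, 1), status = "Native"),
             list(polygon = rectPolygon(2, 3, 0, 1), status = "Introduced"),
             list(polygon = rectPolygon(4, 5, 0, 1), status = "Unknown"),
             list(polygon = rectPolygon(6, 7, 0, 1), status = "Extant (resident)"))
  kept <- filterNativeRange(fs)
  expect_equal(length(kept), 2)
  expect_error(filterNativeRange(list()), "no features")
})

test_that("rangemapToChecklist respects the overlap fraction", {
  regions <- list(A = rectPolygon(0, 1, 0, 1),
                  B = rectPolygon(1, 2, 0, 1),
                  C = rectPolygon(5, 6, 0, 1))
  alien <- rectPolygon(0.8, 1.3, 0, 1)   # 20% of A, 30% of B, none of C
  expect_equal(rangemapToChecklist(alien, regions), c("A", "B"))
  expect_equal(rangemapToChecklist(alien, regions, minOverlapFraction = 0.25), "B")
  expect_equal(rangemapToChecklist(alien, regions, minOverlapFraction = 0.5),
               character(0))
})

test_that("classifyRecords applies native precedence and the id tie-break", {
  g <- gridSpec(0.01, origin = c(0, 0))
  rec <- data.frame(lon = c(0.5, 1.5, 1.5, 3.5, 9.0),
                    lat = c(0.5, 0.5, 0.8, 0.5, 9.0))
  occ <- thinRecords(rec, grid = g, seed = 1)
  native <- list(rectPolygon(0, 1, 0, 1))
  # regB and regA overlap where lat > 0.6: the tie goes to "regA"
  regions <- list(regB = rectPolygon(1, 2, 0, 1),
                  regA = rectPolygon(1, 2, 0.6, 1),
                  regC = rectPolygon(3, 4, 0, 1))
  out <- occurrenceData(classifyRecords(occ, native, regions))
  expect_equal(out$status[out$lon == 0.5], "native")
  expect_equal(out$region_id[out$lon == 1.5 & out$lat == 0.5], "regB")
  expect_equal(out$region_id[out$lon == 1.5 & out$lat == 0.8], "regA")
  expect_equal(out$region_id[out$lon == 3.5], "regC")
  expect_equal(out$status[out$lon == 9], "discarded")
})

test_that("native precedence wins over alien region membership", {
  g <- gridSpec(0.01, origin = c(0, 0))
  occ <- thinRecords(data.frame(lon = 0.5, lat = 0.5), grid = g, seed = 1)
  out <- occurrenceData(classifyRecords(occ, list(rectPolygon(0, 1, 0, 1)),
                                        list(R = rectPolygon(0, 1, 0, 1))))
  expect_equal(out$status, "native")
  expect_true(is.na(out$region_id))
})

test_that("classifying an unthinned set warns", {
  occ <- new("OccurrenceSet", species = "sp",
             data = data.frame(lon = 0.5, lat = 0.5, status = "unclassified",
                               region_id = NA_character_),
             thinned = FALSE)
  expect_warning(classifyRecords(occ, list(), list()), "unthinned")
})

test_that("occurrence and checklist readers handle common column aliases", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(species = c("x", "y"),
                       decimalLongitude = c(1, 2), decimalLatitude = c(3, 4)),
            f, row.names = FALSE)
  d <- readOccurrences(f, species = "x")
  expect_true(all(c("lon", "lat") %in% names(d)))
  expect_equal(d$lon, 1)
  expect_equal(d$lat, 3)
  expect_equal(nrow(d), 1)
  f2 <- tempfile(fileext = ".csv")
  write.csv(data.frame(species = c("x", "x", "y"), region_id = c("r2", "r1", "r3")),
            f2, row.names = FALSE)
  expect_equal(readChecklist(f2, species = "x"), c("r1", "r2"))
})

test_that("GeoJSON feature round trip preserves polygons and properties", {
  f <- tempfile(fileext = ".geojson")
  writeFeaturesGeoJSON(list(R1 = rectPolygon(0, 1, 0, 1),
                            R2 = rectPolygon(2, 3, 0, 1)), f)
  regs <- readRegionsGeoJSON(f)
  expect_equal(names(regs), c("R1", "R2"))
  expect_true(pointInPolygon(0.5, 0.5, regs$R1))
  expect_false(pointInPolygon(0.5, 0.5, regs$R2))
  f2 <- tempfile(fileext = ".geojson")
  writeFeaturesGeoJSON(list(list(polygon = rectPolygon(0, 1, 0, 1),
                                 status = "Native")), f2)
  fs <- readFeaturesGeoJSON(f2)
  expect_equal(fs[[1]]$status, "Native")
  expect_equal(polygonArea(fs[[1]]$polygon), 1)
})
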