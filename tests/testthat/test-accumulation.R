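# Fold plans, the three accumulation curves, background sampling, and
# curve serialisation.

test_that("makeFoldPlan implements the three occurrence regimes", {
  expect_equal(makeFoldPlan(2500)@rule, "per100")
  expect_equal(makeFoldPlan(1001)@rule, "per100")
  expect_equal(makeFoldPlan(1000)@rule, "per10")   # 'more than 1000' is strict
  expect_equal(makeFoldPlan(31)@rule, "per10")
  expect_equal(makeFoldPlan(30)@rule, "per1")
  expect_equal(makeFoldPlan(1)@rule, "per1")
  # remainder goes into a smaller final fold
  p <- makeFoldPlan(45)
  expect_equal(p@sizes, c(10L, 10L, 10L, 10L, 5L))
  expect_equal(sum(makeFoldPlan(1234)@sizes), 1234L)
  expect_error(makeFoldPlan(0), "at least one")
})

test_that("nativeCurve rows are non-decreasing and end at exactly 1", {
  set.seed(21)
  v <- matrix(rnorm(200 * 3), 200, 3, dimnames = list(NULL, c("a", "b", "c")))
  cur <- nativeCurve(v, seed = 1)
  reps <- curveReps(cur)
  expect_equal(dim(reps), c(10, 20))   # 200 records -> 20 folds of 10
  expect_true(all(apply(reps, 1, function(r) all(diff(r) >= 0))))
  expect_identical(unname(reps[, 20]), rep(1, 10))   # exact, not approximate
  expect_equal(curveKind(cur), "native")
  expect_equal(length(curveMean(cur)), 20)
})

test_that("nativeCurve is deterministic in the seed", {
  v <- matrix(rnorm(50 * 2), 50, 2)
  a <- nativeCurve(v, seed = 5)
  b <- nativeCurve(v, seed = 5)
  expect_identical(curveReps(a), curveReps(b))
  c_ <- nativeCurve(v, seed = 6)
  expect_false(identical(curveReps(a), curveReps(c_)))
})

test_that("alienCurve starts at >= 1, is non-decreasing, and flags empties", {
  set.seed(22)
  nat <- matrix(rnorm(40 * 2), 40, 2, dimnames = list(NULL, c("a", "b")))
  regs <- list(r1 = matrix(rnorm(10 * 2, sd = 2), 10, 2, dimnames = list(NULL, c("a", "b"))),
               r2 = matrix(rnorm(5 * 2), 5, 2, dimnames = list(NULL, c("a", "b"))),
               r3 = matrix(numeric(0), 0, 2, dimnames = list(NULL, c("a", "b"))))
  cur <- alienCurve(nat, regs, seed = 2)
  reps <- curveReps(cur)
  expect_equal(dim(reps), c(10, 3))
  expect_true(all(reps >= 1))
  expect_true(all(apply(reps, 1, function(r) all(diff(r) >= 0))))
  expect_equal(cur@flags$emptyRegions, "r3")
  ord <- regionOrder(cur)
  expect_equal(dim(ord), c(10, 3))
  expect_true(all(apply(ord, 1, function(r) setequal(r, names(regs)))))
})

test_that("alien records inside the native envelope give a curve of exactly 1", {
  nat <- cbind(a = c(0, 10), b = c(0, 10))
  regs <- list(r1 = cbind(a = c(2, 3), b = c(2, 3)),
               r2 = cbind(a = 5, b = 5))
  cur <- alienCurve(nat, regs, seed = 3)
  expect_identical(unname(as.vector(curveReps(cur))), rep(1, 20))
})

test_that("alienCurve rejects degenerate inputs", {
  nat <- cbind(a = c(0, 1), b = c(0, 1))
  expect_error(alienCurve(nat, list(), seed = 1), "no alien regions")
  empt <- list(r1 = matrix(numeric(0), 0, 2, dimnames = list(NULL, c("a", "b"))))
  expect_error(alienCurve(nat, empt, seed = 1), "no alien records")
})

test_that("sampleBackgroundPoints draws one point per cell inside the region", {
  s <- standardizeStack(tinyStack())
  region <- rectPolygon(0.25, 1.25, 0.25, 1.25)   # 4 x 4 background cells
  bgGrid <- gridSpec(0.25, origin = c(0, 0))
  smp <- sampleBackgroundPoints(region, s, grid = bgGrid, seed = 9)
  expect_equal(nrow(smp$points), 16)
  expect_true(all(pointInPolygon(smp$points[, "lon"], smp$points[, "lat"], region)))
  ids <- cellId(smp$points[, "lon"], smp$points[, "lat"], bgGrid)
  expect_false(anyDuplicated(paste(ids[, 1], ids[, 2])) > 0)
  expect_equal(colnames(smp$values), c("alpha", "beta"))
  # identical seed, identical draw
  smp2 <- sampleBackgroundPoints(region, s, grid = bgGrid, seed = 9)
  expect_identical(smp, smp2)
})

test_that("cell modes differ on partially overlapping cells", {
  s <- standardizeStack(tinyStack())
  region <- rectPolygon(0.26, 0.36, 0.26, 0.36)   # inside one cell, no center
  bgGrid <- gridSpec(0.25, origin = c(0, 0))
  none <- sampleBackgroundPoints(region, s, grid = bgGrid, seed = 1)
  expect_equal(nrow(none$points), 0)
  ovl <- sampleBackgroundPoints(region, s, grid = bgGrid, seed = 1,
                                cellMode = "overlap")
  expect_equal(nrow(ovl$points), 1)
})

test_that("backgroundCurve reuses the alien region order and can dominate", {
  s <- standardizeStack(tinyStack())
  nat <- extractValues(s, c(0.3, 0.8, 1.2), c(0.3, 0.8, 1.2))
  regs <- list(rA = rectPolygon(1.5, 2, 0, 0.5), rB = rectPolygon(1.5, 2, 0.5, 1))
  alien <- list(rA = extractValues(s, c(1.6, 1.9), c(0.1, 0.4)),
                rB = extractValues(s, 1.7, 0.7))
  ac <- alienCurve(nat, alien, seed = 4)
  bc <- backgroundCurve(nat, regs, s, order = regionOrder(ac),
                        grid = gridSpec(0.25, origin = c(0, 0)), seed = 4,
                        includeAlienOccurrences = TRUE,
                        alienValuesByRegion = alien)
  expect_equal(dim(curveReps(bc)), dim(curveReps(ac)))
  expect_true(all(curveReps(bc) >= curveReps(ac)))
  expect_true(all(curveReps(bc) >= 1))
})

test_that("curve CSV serialisation is long-form and complete", {
  v <- matrix(rnorm(40), 20, 2)
  cur <- nativeCurve(v, seed = 8)
  f <- tempfile(fileext = ".csv")
  writeCurveCSV(cur, f)
  d <- read.csv(f)
  expect_equal(names(d), c("curve_kind", "repetition", "step", "label", "ratio"))
  expect_equal(nrow(d), 10 * 20)
  expect_true(all(d$curve_kind == "native"))
})

test_that("plotCurves builds a plot and can write a file", {
  v <- matrix(rnorm(60), 30, 2)
  cur <- nativeCurve(v, seed = 8)
  p <- plotCurves(native = cur)
  expect_s3_class(p, "ggplot")
  f <- tempfile(fileext = ".png")
  plotCurves(native = cur, path = f)
  expect_true(file.exists(f) && file.size(f) > 0)
})
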