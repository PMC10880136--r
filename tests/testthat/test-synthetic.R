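# Synthetic landscape, region, and virtual-species generators.

test_that("generateStack with identity mixing gives near-uncorrelated layers", {
  s <- generateStack(seed = 1, kVars = 3)
  v <- sapply(s@layers, as.vector)
  cm <- abs(stats::cor(v))
  diag(cm) <- 0
  expect_lt(max(cm), 0.2)
  # standardised layers
  expect_equal(unname(colMeans(v)), rep(0, 3), tolerance = 1e-8)
  expect_equal(unname(apply(v, 2, sd)), rep(1, 3), tolerance = 1e-8)
})

test_that("generateStack is seed-deterministic and smoothness 0 is a pure gradient", {
  a <- generateStack(seed = 7, kVars = 2)
  b <- generateStack(seed = 7, kVars = 2)
  expect_identical(a@layers, b@layers)
  expect_false(identical(a@layers, generateStack(seed = 8, kVars = 2)@layers))
  g <- generateStack(seed = 3, kVars = 1, smoothness = 0, orthogonalize = FALSE)
  m <- g@layers[[1]]
  # a pure linear gradient is perfectly predicted by the two coordinates
  X <- rep((seq_len(ncol(m)) - 0.5), each = nrow(m))
  Y <- rep((seq_len(nrow(m)) - 0.5), ncol(m))
  resid <- qr.resid(qr(cbind(1, X, Y)), as.vector(m))
  expect_lt(var(resid) / var(as.vector(m)), 1e-6)
})

test_that("a mixing matrix induces the collinearity it asks for", {
  mix <- rbind(c(1, 0, 0), c(0.9, sqrt(1 - 0.81), 0), c(0, 0, 1))
  s <- generateStack(seed = 2, kVars = 3, mixing = mix)
  v <- sapply(s@layers, as.vector)
  expect_gt(abs(cor(v[, 1], v[, 2])), 0.7)
})

test_that("the scenario stack is deterministic, standardised, and decoy-collinear", {
  s <- generateScenarioStack(seed = 1)
  expect_identical(s@layers, generateScenarioStack(seed = 1)@layers)
  expect_equal(layerNames(s), c("bio1", "bio2", "bio3"))
  expect_equal(gridDim(s), c(nrow = 192L, ncol = 192L))
  expect_equal(s@cellSize, 0.25 / 3)
  v <- sapply(s@layers, as.vector)
  expect_equal(unname(colMeans(v)), rep(0, 3), tolerance = 1e-8)
  expect_gt(abs(cor(v[, "bio1"], v[, "bio3"])), 0.7)
  expect_lt(abs(cor(v[, "bio1"], v[, "bio2"])), 0.2)
})

test_that("nested regions are environmentally contained in the native box", {
  s <- generateScenarioStack(seed = 1)
  geo <- generateRegions(s, layout = "nested", seed = 1)
  expect_equal(length(geo$regions), 10)
  natBox <- cumniche:::regionEnvBox(s, geo$native)
  for (p in geo$regions) {
    box <- cumniche:::regionEnvBox(s, p)
    expect_true(all(box["low", ] >= natBox["low", ]))
    expect_true(all(box["high", ] <= natBox["high", ]))
    # geographically disjoint from the native range
    expect_false(polygonsIntersect(p, geo$native))
  }
})

test_that("novel regions at least double the pooled amplitude", {
  s <- generateScenarioStack(seed = 2)
  for (layout in c("novel", "novel_uniform")) {
    geo <- generateRegions(s, layout = layout, seed = 2, noveltyTarget = 2)
    natBox <- cumniche:::regionEnvBox(s, geo$native)
    boxes <- lapply(geo$regions, function(p) cumniche:::regionEnvBox(s, p))
    lows <- apply(sapply(boxes, function(b) b["low", ]), 1, min)
    highs <- apply(sapply(boxes, function(b) b["high", ]), 1, max)
    combined <- pmax(highs, natBox["high", ]) - pmin(lows, natBox["low", ])
    expect_true(any(combined >= 2 * (natBox["high", ] - natBox["low", ])))
  }
})

test_that("virtual species boxes and suitability behave", {
  sp <- virtualSpecies(cbind(t = c(0, 1), p = c(-1, 1)))
  expect_equal(trueBreadth(sp), 2)
  v <- cbind(t = c(0.5, 2, 0), p = c(0, 0, 1))
  expect_equal(unname(cumniche:::suitabilityOf(sp, v)), c(TRUE, FALSE, TRUE))
  soft <- virtualSpecies(cbind(t = c(0, 1), p = c(-1, 1)), softening = 0.1)
  ps <- cumniche:::suitabilityOf(soft, v)
  expect_true(all(ps >= 0 & ps <= 1))
  expect_gt(ps[1], ps[2])
})

test_that("sampleOccurrences respects suitability, polygon, cap, and seed", {
  s <- generateScenarioStack(seed = 3)
  sp <- cumniche:::presetSpecies(s, "capped")
  native <- cumniche:::relRect(s, 1 / 64, 12 / 64, 1 / 64, 12 / 64)
  occ <- sampleOccurrences(sp, s, native, n = 100, seed = 5)
  expect_equal(nrow(occ), 100)
  expect_true(all(pointInPolygon(occ$lon, occ$lat, native)))
  vals <- extractValues(s, occ$lon, occ$lat)
  expect_true(all(cumniche:::suitabilityOf(sp, vals)))
  expect_identical(occ, sampleOccurrences(sp, s, native, n = 100, seed = 5))
  # n larger than the suitable-cell count is capped, not an error
  tiny <- cumniche:::relRect(s, 1 / 64, 2 / 64, 1 / 64, 2 / 64)
  many <- sampleOccurrences(sp, s, tiny, n = 10000, seed = 5)
  expect_lte(nrow(many), 9)
})

test_that("completeness truncates the sampled niche from above", {
  s <- generateScenarioStack(seed = 3)
  sp <- cumniche:::presetSpecies(s, "wide")
  native <- cumniche:::relRect(s, 1 / 64, 12 / 64, 1 / 64, 12 / 64)
  full <- sampleOccurrences(sp, s, native, n = 300, seed = 6)
  part <- sampleOccurrences(sp, s, native, n = 300, completeness = 0.7, seed = 6)
  vFull <- extractValues(s, full$lon, full$lat)
  vPart <- extractValues(s, part$lon, part$lat)
  expect_lt(max(vPart[, "bio1"]), max(vFull[, "bio1"]))
  cap <- sp@niche["low", "bio1"] + 0.7 * diff(sp@niche[, "bio1"])
  expect_true(all(vPart[, "bio1"] <= cap))
})

test_that("makeScenario bundles are deterministic and carry the truth label", {
  b1 <- makeScenario("a", seed = 1)
  b2 <- makeScenario("a", seed = 1)
  expect_identical(b1$occurrences, b2$occurrences)
  expect_identical(b1$stack@layers, b2$stack@layers)
  expect_equal(b1$trueLabel, "a")
  expect_equal(makeScenario("nested", seed = 1, nAlien = 2)$trueLabel, "a")
  expect_equal(b1$checklist, names(b1$regions))
  expect_s4_class(b1$species, "VirtualSpecies")
  # preset b only changes the native sample size
  bb <- makeScenario("b", seed = 1)
  expect_equal(sum(pointInPolygon(bb$occurrences$lon, bb$occurrences$lat,
                                  bb$native)), 24)
})
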