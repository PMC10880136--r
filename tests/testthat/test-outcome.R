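# Asymptote detection, outcome classification, and the bias screen.

test_that("detectAsymptote judges the canonical shapes", {
  # linear rise: 95% of the rise is only reached at 95% of the steps
  lin <- detectAsymptote(seq(0.01, 1, length.out = 100))
  expect_false(lin@reached)
  expect_equal(lin@fractionAt95, 0.95)
  # geometric saturation 1 - 2^-k over 20 steps: 95% by step 5
  geo <- detectAsymptote(1 - 2^-(1:20))
  expect_true(geo@reached)
  expect_equal(geo@fractionAt95, 0.25)
  expect_lt(geo@tailSlope, 0.01)
})

test_that("detectAsymptote baselines follow the curve kind", {
  # an alien-style curve rising from 1: same shape, baseline 1
  reps <- matrix(rep(1 + (1 - 2^-(1:20)), each = 2), 2, 20, byrow = FALSE)
  cur <- new("CNACurve", kind = "alien", reps = reps,
             stepLabels = paste0("s", 1:20), regionOrder = NULL, flags = list())
  v <- detectAsymptote(cur)
  expect_true(v@reached)
  expect_equal(v@fractionAt95, 0.25)
})

test_that("flat curves count as saturated and short curves as undetermined", {
  flat <- detectAsymptote(rep(1, 10), baseline = 1)
  expect_true(flat@reached)
  expect_equal(flat@tailSlope, 0)
  expect_warning(short <- detectAsymptote(c(0.2, 1)), "fewer than 3")
  expect_true(short@undetermined)
  expect_false(short@reached)
})

test_that("classifyOutcome maps verdict combinations to the four scenarios", {
  verdict <- function(reached) new("AsymptoteVerdict", reached = reached,
                                   fractionAt95 = 0.3, tailSlope = 0,
                                   undetermined = FALSE)
  curve <- function(kind, final) new("CNACurve", kind = kind,
                                     reps = matrix(c(1, final), 1, 2),
                                     stepLabels = c("s1", "s2"),
                                     regionOrder = NULL, flags = list())
  ali <- curve("alien", 1.5)
  bgHead <- curve("background", 2.0)   # headroom over 1.5
  bgFlat <- curve("background", 1.5)   # none
  combos <- list(a = c(TRUE, TRUE), b = c(FALSE, TRUE),
                 c = c(TRUE, FALSE), d = c(FALSE, FALSE))
  for (lab in names(combos)) {
    o <- classifyOutcome(verdict(combos[[lab]][1]), verdict(combos[[lab]][2]),
                         bgHead, ali)
    expect_equal(o@scenario, lab)
  }
  # confidence wiring
  oa <- classifyOutcome(verdict(TRUE), verdict(TRUE), bgHead, ali)
  expect_equal(oa@nicheComparisonConfidence, "high")
  expect_equal(oa@projectionConfidence, "high")
  expect_false(oa@nestednessFlag)
  expect_equal(oa@expansionRatio, 1.5)
})

test_that("an alien asymptote without headroom raises the nestedness flag", {
  verdict <- function(reached) new("AsymptoteVerdict", reached = reached,
                                   fractionAt95 = 0.3, tailSlope = 0,
                                   undetermined = FALSE)
  ali <- new("CNACurve", kind = "alien", reps = matrix(c(1, 1.5), 1, 2),
             stepLabels = c("s1", "s2"), regionOrder = NULL, flags = list())
  bg <- new("CNACurve", kind = "background", reps = matrix(c(1, 1.52), 1, 2),
            stepLabels = c("s1", "s2"), regionOrder = NULL, flags = list())
  o <- classifyOutcome(verdict(TRUE), verdict(TRUE), bg, ali)
  expect_equal(o@scenario, "a")
  expect_true(o@nestednessFlag)
  expect_equal(o@projectionConfidence, "low")
  expect_false(o@backgroundHeadroom)
})

test_that("outcome report JSON round-trips the key fields", {
  verdict <- new("AsymptoteVerdict", reached = TRUE, fractionAt95 = 0.2,
                 tailSlope = 0.001, undetermined = FALSE)
  ali <- new("CNACurve", kind = "alien", reps = matrix(c(1, 1.5), 1, 2),
             stepLabels = c("s1", "s2"), regionOrder = NULL, flags = list())
  bg <- new("CNACurve", kind = "background", reps = matrix(c(1, 2), 1, 2),
            stepLabels = c("s1", "s2"), regionOrder = NULL, flags = list())
  o <- classifyOutcome(verdict, verdict, bg, ali)
  f <- tempfile(fileext = ".json")
  writeOutcomeReport(o, f)
  j <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(j$scenario, "a")
  expect_equal(j$expansion_ratio, 1.5)
  expect_true(j$verdicts$native$reached)
})

test_that("biasScreen flags a focal set much narrower than its reference", {
  set.seed(31)
  ref <- matrix(rnorm(400), 200, 2, dimnames = list(NULL, c("a", "b")))
  focal <- ref[abs(ref[, 1]) < 0.3 & abs(ref[, 2]) < 0.3, , drop = FALSE]
  res <- biasScreen(focal, ref, seed = 1)
  expect_true(res$flagged)
  expect_lt(res$ratio, 0.5)
  expect_s4_class(res$focalCurve, "CNACurve")
  # a focal set as broad as the reference passes
  res2 <- biasScreen(ref, ref, seed = 1)
  expect_false(res2$flagged)
  expect_equal(res2$ratio, 1)
})

test_that("biasScreen validates its inputs", {
  a <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  b <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("x", "y")))
  expect_error(biasScreen(a, b), "share variables")
  expect_error(biasScreen(a, a[0, , drop = FALSE]), "empty reference")
})
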