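# Two-step variable selection: collinearity exclusion by |r| and VIF, then
# the percentage-contribution importance filter.

makeCorrelated <- function(n = 500, seed = 5) {
  set.seed(seed)
  z1 <- rnorm(n); z2 <- rnorm(n); z3 <- rnorm(n)
  cbind(a = z1,
        b = 0.95 * z1 + sqrt(1 - 0.95^2) * rnorm(n),   # |r(a,b)| ~ 0.95
        c = z2,
        d = 0.5 * z2 + sqrt(0.75) * z3)                # moderate r(c,d)
}

test_that("vif matches the closed form from the correlation matrix", {
  v <- makeCorrelated()
  got <- vif(v)
  # closed form: VIF_k = [(R^-1)]_kk for the correlation matrix R
  expected <- diag(solve(stats::cor(v)))
  expect_equal(unname(got), unname(expected[names(got)]), tolerance = 1e-9)
})

test_that("vif flags perfect collinearity as Inf and handles one column", {
  set.seed(1)
  x <- rnorm(50)
  v <- cbind(a = x, b = 2 * x + 1)
  expect_true(is.infinite(vif(v)[["a"]]))
  expect_equal(vif(cbind(only = x)), c(only = 1))
  expect_error(vif(cbind(a = x, k = rep(1, 50))), "constant")
})

test_that("collinearityFilter leaves all surviving pairs below the threshold", {
  v <- makeCorrelated()
  res <- collinearityFilter(v, threshold = 0.7)
  cm <- abs(stats::cor(v[, res$kept, drop = FALSE]))
  diag(cm) <- 0
  expect_true(all(cm < 0.7))
  # exactly one of the a/b pair was dropped, by larger VIF
  expect_true(xor("a" %in% res$kept, "b" %in% res$kept))
  expect_true(all(c("c", "d") %in% res$kept))
  expect_equal(nrow(res$dropped), 1)
})

test_that("collinearityFilter tie-break drops the lexicographically later name", {
  set.seed(2)
  x <- rnorm(100)
  # two exact copies: identical VIFs, so "z2" loses against "z1"
  v <- cbind(z2 = x, z1 = x, w = rnorm(100))
  res <- collinearityFilter(v)
  expect_true("z1" %in% res$kept)
  expect_false("z2" %in% res$kept)
})

test_that("jackknife contributions are non-negative and sum to 100", {
  set.seed(3)
  n <- 300
  pres <- cbind(a = rnorm(n, 1, 0.5), b = rnorm(n), c = rnorm(n))
  bg <- cbind(a = rnorm(n, -1, 0.5), b = rnorm(n), c = rnorm(n))
  contrib <- jackknifeGain(pres, bg)
  expect_equal(sum(contrib), 100, tolerance = 1e-9)
  expect_true(all(contrib >= 0))
  # the only informative variable dominates
  expect_gt(contrib[["a"]], 50)
})

test_that("importanceFilter keeps contributors at or above the threshold", {
  fakeEstimator <- function(presence, background)
    setNames(c(80, 14, 4.5, 1.5), colnames(presence))
  m <- matrix(rnorm(80), 20, 4, dimnames = list(NULL, c("a", "b", "c", "d")))
  res <- importanceFilter(m, m, contributionThreshold = 5,
                          estimator = fakeEstimator)
  expect_equal(res$kept, c("a", "b"))
  expect_equal(res$dropped$name, c("c", "d"))
})

test_that("importanceFilter keeps the best variable when none qualify", {
  fakeEstimator <- function(presence, background)
    setNames(c(60, 40), colnames(presence))
  m <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  expect_warning(res <- importanceFilter(m, m, contributionThreshold = 90,
                                         estimator = fakeEstimator),
                 "keeping the best")
  expect_equal(res$kept, "a")
})

test_that("importanceFilter validates estimator output and small samples", {
  m <- matrix(rnorm(8), 4, 2, dimnames = list(NULL, c("a", "b")))
  badEstimator <- function(presence, background)
    setNames(c(10, 10), colnames(presence))
  expect_warning(
    expect_error(importanceFilter(m, m, estimator = badEstimator), "summing to 100"),
    "fewer than 10")
})

test_that("selectVariables removes the scenario stack's collinear decoy", {
  stack <- generateScenarioStack(seed = 4)
  set.seed(4)
  cells <- cbind(sample.int(192, 400, replace = TRUE),
                 sample.int(192, 400, replace = TRUE))
  vals <- sapply(stack@layers, function(m) m[cells])
  pres <- vals[1:200, ]; bg <- vals[201:400, ]
  sel <- selectVariables(pres, bg)
  expect_false("bio3" %in% sel$kept)
  expect_true(all(c("bio1", "bio2") %in% sel$kept))
  expect_equal(sum(sel$contributions), 100, tolerance = 1e-9)
  f <- tempfile(fileext = ".json")
  writeSelectionReport(sel, f)
  rep <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(rep$kept, sel$kept)
})
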