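#' @import methods
NULL

setClassUnion("listOrNULL", c("list", "NULL"))

#' EnvStack: aligned environmental raster layers
#'
#' An `EnvStack` holds an ordered set of co-registered environmental layers on
#' a common regular lon/lat grid (WGS84). Each layer is a numeric matrix with
#' row 1 at the southern edge and column 1 at the western edge; `NA` cells are
#' nodata. When the stack has been standardised, the per-layer means and
#' standard deviations used are carried in the `standardization` slot so the
#' transformation can be replayed exactly.
#'
#' @slot layers named list of numeric matrices sharing identical dimensions.
#' @slot origin numeric(2), lon/lat of the grid's lower-left corner (degrees).
#' @slot cellSize numeric(1), degrees per (square) cell.
#' @slot standardization `NULL`, or a list with numeric vectors `mean` and
#'   `sd` (one element per layer, named) recording the standardisation
#'   parameters applied to produce this stack.
#'
#' @seealso [envStack()], [standardizeStack()], [extractValues()]
#' @export
setClass("EnvStack",
  representation(
    layers = "list",
    origin = "numeric",
    cellSize = "numeric",
    standardization = "listOrNULL"
  )
)

setValidity("EnvStack", function(object) {
  msgs <- character()
  if (length(object@layers) < 1L) msgs <- c(msgs, "stack must contain at least one layer")
  nm <- names(object@layers)
  if (is.null(nm) || any(!nzchar(nm))) msgs <- c(msgs, "layers must be named")
  if (anyDuplicated(nm)) msgs <- c(msgs, "layer names must be unique")
  if (length(object@cellSize) != 1L || !is.finite(object@cellSize) || object@cellSize <= 0)
    msgs <- c(msgs, "cellSize must be a single positive number")
  if (length(object@origin) != 2L || any(!is.finite(object@origin)))
    msgs <- c(msgs, "origin must be finite lon/lat")
  dims <- lapply(object@layers, dim)
  if (length(dims) && !all(vapply(dims, identical, logical(1), dims[[1]])))
    msgs <- c(msgs, "all layers must share identical grid dimensions")
  for (i in seq_along(object@layers)) {
    v <- object@layers[[i]]
    if (!is.matrix(v) || !is.numeric(v))
      msgs <- c(msgs, sprintf("layer '%s' is not a numeric matrix", nm[i]))
    else if (any(!is.finite(v[!is.na(v)])))
      msgs <- c(msgs, sprintf("layer '%s' has non-finite unmasked values", nm[i]))
  }
  if (length(msgs)) msgs else TRUE
})

#' OccurrenceSet: status-tagged occurrence records
#'
#' Thinned point records for one species, each tagged with a biogeographical
#' status (`native`, `alien`, or `discarded`) and, for alien records, the
#' checklist region they fall in.
#'
#' @slot species character(1) species name.
#' @slot data data.frame with columns `lon`, `lat`, `status`, `region_id`.
#' @slot thinned logical(1), whether the set has been thinned to one record
#'   per thinning-grid cell.
#' @export
setClass("OccurrenceSet",
  representation(species = "character", data = "data.frame", thinned = "logical")
)

setValidity("OccurrenceSet", function(object) {
  msgs <- character()
  need <- c("lon", "lat", "status", "region_id")
  if (!all(need %in% names(object@data)))
    msgs <- c(msgs, paste("data must have columns", paste(need, collapse = ", ")))
  else {
    ok <- object@data$status %in% c("native", "alien", "discarded", "unclassified")
    if (!all(ok)) msgs <- c(msgs, "invalid status values")
    al <- object@data$status == "alien"
    if (any(al & is.na(object@data$region_id)))
      msgs <- c(msgs, "alien records must carry a region_id")
  }
  if (length(msgs)) msgs else TRUE
})

#' NicheBreadth: multiplicative range-product niche breadth
#'
#' Carries the per-variable minima and maxima of standardised environmental
#' values over a point set. The amplitude of variable j is `max_j - min_j`;
#' the breadth is the product of the amplitudes, an estimate of the
#' multidimensional volume of occupied environmental space. Extrema are
#' stored exactly so incremental updates are order-invariant.
#'
#' @slot variables character, ordered variable names.
#' @slot mins,maxs numeric, per-variable extrema.
#' @slot nPoints integer(1), number of points accumulated.
#' @seealso [breadthFromPoints()], [updateBreadth()], [breadthRatio()]
#' @export
setClass("NicheBreadth",
  representation(variables = "character", mins = "numeric", maxs = "numeric",
                 nPoints = "integer")
)

setValidity("NicheBreadth", function(object) {
  msgs <- character()
  k <- length(object@variables)
  if (length(object@mins) != k || length(object@maxs) != k)
    msgs <- c(msgs, "mins/maxs must match variables in length")
  if (k == 0L) msgs <- c(msgs, "variable set must be non-empty")
  if (any(object@maxs < object@mins)) msgs <- c(msgs, "maxs must be >= mins")
  if (length(msgs)) msgs else TRUE
})

#' FoldPlan: partition of native occurrences into accumulation folds
#'
#' @slot sizes integer vector of fold sizes (sums to the number of records).
#' @slot rule character(1): `"per100"`, `"per10"`, or `"per1"`.
#' @export
setClass("FoldPlan", representation(sizes = "integer", rule = "character"))

setValidity("FoldPlan", function(object) {
  msgs <- character()
  if (any(object@sizes < 1L)) msgs <- c(msgs, "fold sizes must be positive")
  if (!object@rule %in% c("per100", "per10", "per1")) msgs <- c(msgs, "unknown fold rule")
  if (length(msgs)) msgs else TRUE
})

#' CNACurve: repetition-wise niche-breadth accumulation curve
#'
#' One of the three accumulation curves of the framework. `reps` holds one
#' row per repetition and one column per accumulation step (fold for the
#' native curve, region for the alien and background curves); the mean curve
#' is the pointwise average across repetitions.
#'
#' @slot kind character(1): `"native"`, `"alien"`, or `"background"`.
#' @slot reps numeric matrix, repetitions x steps.
#' @slot stepLabels character, one label per step (fold index or region id
#'   order is repetition-specific for region curves, so labels are generic).
#' @slot regionOrder `NULL`, or a character matrix (repetitions x regions)
#'   giving the region inclusion order per repetition.
#' @slot flags list of diagnostic flags (e.g. empty regions).
#' @seealso [nativeCurve()], [alienCurve()], [backgroundCurve()]
#' @export
setClass("CNACurve",
  representation(kind = "character", reps = "matrix", stepLabels = "character",
                 regionOrder = "ANY", flags = "list")
)

setValidity("CNACurve", function(object) {
  msgs <- character()
  if (!object@kind %in% c("native", "alien", "background", "reference"))
    msgs <- c(msgs, "unknown curve kind")
  if (!is.numeric(object@reps) || nrow(object@reps) < 1L || ncol(object@reps) < 1L)
    msgs <- c(msgs, "reps must be a non-empty numeric matrix")
  if (length(object@stepLabels) != ncol(object@reps))
    msgs <- c(msgs, "stepLabels must have one entry per step")
  if (length(msgs)) msgs else TRUE
})

#' AsymptoteVerdict: operational saturation judgement on a mean curve
#'
#' @slot reached logical(1); `NA` when the curve is too short to judge.
#' @slot fractionAt95 numeric(1), fraction of steps needed for the mean curve
#'   to first reach 95% of its total rise above the curve-kind baseline.
#' @slot tailSlope numeric(1), mean per-step increase over the final 20% of
#'   steps, relative to the total rise.
#' @slot undetermined logical(1), `TRUE` when the curve had fewer than 3 steps.
#' @export
setClass("AsymptoteVerdict",
  representation(reached = "logical", fractionAt95 = "numeric",
                 tailSlope = "numeric", undetermined = "logical")
)

#' CNAOutcome: four-scenario classification of a full run
#'
#' @slot scenario character(1) in `a`--`d`.
#' @slot nicheComparisonConfidence,projectionConfidence character(1),
#'   `"high"` or `"low"`.
#' @slot backgroundHeadroom logical(1), whether the background curve ends
#'   above the alien curve by more than the headroom margin.
#' @slot nestednessFlag logical(1), raised when the alien curve saturates but
#'   the invaded regions offer no conditions beyond those already realised
#'   (environmental nestedness), which flattens curves for reasons unrelated
#'   to species tolerance.
#' @slot expansionRatio numeric(1), final mean value of the alien curve.
#' @slot verdicts list of the native and alien [AsymptoteVerdict-class] objects.
#' @slot thresholds list of the thresholds used.
#' @export
setClass("CNAOutcome",
  representation(scenario = "character",
                 nicheComparisonConfidence = "character",
                 projectionConfidence = "character",
                 backgroundHeadroom = "logical",
                 nestednessFlag = "logical",
                 expansionRatio = "numeric",
                 verdicts = "list",
                 thresholds = "list")
)

#' VirtualSpecies: simulated species with a known environmental niche
#'
#' The species is suitable wherever every (standardised) environmental value
#' falls inside its axis-aligned niche box; an optional logistic softening
#' width turns the hard box edge into a smooth suitability decline.
#'
#' @slot niche matrix 2 x k (`rows low, high`) in standardised units.
#' @slot softening numeric(1), logistic softening width (0 = hard box).
#' @export
setClass("VirtualSpecies", representation(niche = "matrix", softening = "numeric"))

setValidity("VirtualSpecies", function(object) {
  msgs <- character()
  if (nrow(object@niche) != 2L) msgs <- c(msgs, "niche must have rows low, high")
  if (any(object@niche[2, ] <= object@niche[1, ])) msgs <- c(msgs, "niche low must be < high")
  if (length(msgs)) msgs else TRUE
})
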