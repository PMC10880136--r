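#' Accessor generics
#'
#' Small accessor generics for the package's S4 containers.
#'
#' @param x an object.
#' @param ... further arguments for methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("layerNames", function(x) standardGeneric("layerNames"))

#' @rdname accessors
#' @export
setGeneric("nLayers", function(x) standardGeneric("nLayers"))

#' @rdname accessors
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))

#' @rdname accessors
#' @export
setGeneric("extentOf", function(x) standardGeneric("extentOf"))

#' @rdname accessors
#' @export
setGeneric("standardization", function(x) standardGeneric("standardization"))

#' @rdname accessors
#' @export
setGeneric("amplitudes", function(x) standardGeneric("amplitudes"))

#' @rdname accessors
#' @export
setGeneric("breadth", function(x) standardGeneric("breadth"))

#' @rdname accessors
#' @export
setGeneric("nPoints", function(x) standardGeneric("nPoints"))

#' @rdname accessors
#' @export
setGeneric("curveMean", function(x) standardGeneric("curveMean"))

#' @rdname accessors
#' @export
setGeneric("curveReps", function(x) standardGeneric("curveReps"))

#' @rdname accessors
#' @export
setGeneric("curveKind", function(x) standardGeneric("curveKind"))

#' @rdname accessors
#' @export
setGeneric("regionOrder", function(x) standardGeneric("regionOrder"))

#' @rdname accessors
#' @export
setGeneric("occurrenceData", function(x) standardGeneric("occurrenceData"))

#' @rdname accessors
#' @export
setGeneric("scenarioLabel", function(x) standardGeneric("scenarioLabel"))


# -- EnvStack accessors -------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("layerNames", "EnvStack", function(x) names(x@layers))

#' @rdname accessors
#' @export
setMethod("nLayers", "EnvStack", function(x) length(x@layers))

#' @rdname accessors
#' @export
setMethod("gridDim", "EnvStack", function(x) {
  d <- dim(x@layers[[1L]])
  c(nrow = d[1L], ncol = d[2L])
})

#' @rdname accessors
#' @export
setMethod("extentOf", "EnvStack", function(x) {
  d <- gridDim(x)
  c(xmin = x@origin[1L], xmax = x@origin[1L] + d[["ncol"]] * x@cellSize,
    ymin = x@origin[2L], ymax = x@origin[2L] + d[["nrow"]] * x@cellSize)
})

#' @rdname accessors
#' @export
setMethod("standardization", "EnvStack", function(x) x@standardization)

setMethod("show", "EnvStack", function(object) {
  d <- gridDim(object)
  e <- extentOf(object)
  cat(sprintf("EnvStack: %d layer(s), %d x %d cells @ %g deg\n",
              nLayers(object), d[["nrow"]], d[["ncol"]], object@cellSize))
  cat(sprintf("  extent: lon [%g, %g], lat [%g, %g]\n",
              e[["xmin"]], e[["xmax"]], e[["ymin"]], e[["ymax"]]))
  cat("  layers:", paste(layerNames(object), collapse = ", "), "\n")
  cat("  standardised:", if (is.null(object@standardization)) "no" else "yes", "\n")
})

# -- OccurrenceSet ------------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("occurrenceData", "OccurrenceSet", function(x) x@data)

setMethod("show", "OccurrenceSet", function(object) {
  tab <- table(factor(object@data$status,
                      levels = c("native", "alien", "discarded", "unclassified")))
  cat(sprintf("OccurrenceSet: '%s', %d record(s)%s\n", object@species,
              nrow(object@data), if (object@thinned) " (thinned)" else ""))
  cat(sprintf("  native %d | alien %d | discarded %d | unclassified %d\n",
              tab[["native"]], tab[["alien"]], tab[["discarded"]],
              tab[["unclassified"]]))
})

# -- NicheBreadth -------------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("amplitudes", "NicheBreadth", function(x) {
  a <- x@maxs - x@mins
  names(a) <- x@variables
  a
})

#' @rdname accessors
#' @export
setMethod("breadth", "NicheBreadth", function(x) prod(x@maxs - x@mins))

#' @rdname accessors
#' @export
setMethod("nPoints", "NicheBreadth", function(x) x@nPoints)

setMethod("show", "NicheBreadth", function(object) {
  cat(sprintf("NicheBreadth over %d point(s), %d variable(s)\n",
              object@nPoints, length(object@variables)))
  cat("  amplitudes:",
      paste(sprintf("%s=%.4g", object@variables, amplitudes(object)),
            collapse = ", "), "\n")
  cat(sprintf("  breadth B = %.6g\n", breadth(object)))
})

# -- CNACurve -----------------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("curveMean", "CNACurve", function(x) colMeans(x@reps))

#' @rdname accessors
#' @export
setMethod("curveReps", "CNACurve", function(x) x@reps)

#' @rdname accessors
#' @export
setMethod("curveKind", "CNACurve", function(x) x@kind)

#' @rdname accessors
#' @export
setMethod("regionOrder", "CNACurve", function(x) x@regionOrder)

setMethod("show", "CNACurve", function(object) {
  m <- curveMean(object)
  cat(sprintf("CNACurve [%s]: %d repetition(s) x %d step(s)\n",
              object@kind, nrow(object@reps), ncol(object@reps)))
  cat(sprintf("  mean curve: start %.4g -> end %.4g\n", m[1L], m[length(m)]))
  if (length(object@flags)) cat("  flags:", paste(names(object@flags), collapse = ", "), "\n")
})

# -- AsymptoteVerdict / CNAOutcome -------------------------------------------

setMethod("show", "AsymptoteVerdict", function(object) {
  if (object@undetermined) {
    cat("AsymptoteVerdict: undetermined (curve too short)\n")
  } else {
    cat(sprintf("AsymptoteVerdict: %s (fraction to 95%% rise = %.3g, tail slope = %.3g)\n",
                if (isTRUE(object@reached)) "reached" else "not reached",
                object@fractionAt95, object@tailSlope))
  }
})

#' @rdname accessors
#' @export
setMethod("scenarioLabel", "CNAOutcome", function(x) x@scenario)

setMethod("show", "CNAOutcome", function(object) {
  cat(sprintf("CNAOutcome: scenario (%s)\n", object@scenario))
  cat(sprintf("  niche comparison confidence: %s\n", object@nicheComparisonConfidence))
  cat(sprintf("  projection confidence:       %s\n", object@projectionConfidence))
  cat(sprintf("  expansion ratio (alien curve final mean): %.4g\n", object@expansionRatio))
  cat(sprintf("  background headroom: %s%s\n", object@backgroundHeadroom,
              if (object@nestednessFlag) "  [environmental nestedness flagged]" else ""))
})
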