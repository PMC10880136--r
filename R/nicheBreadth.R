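# The range-product niche-breadth statistic: per-variable amplitudes
# (max - min of standardised values) multiplied into a volume estimate of
# occupied environmental space. Extrema are carried exactly so incremental
# accumulation is order-invariant.

#' Niche breadth from a point-value matrix
#'
#' @param values numeric matrix, points x variables, of standardised
#'   environmental values; column names are the variable names.
#' @return a [NicheBreadth-class] object.
#' @examples
#' b <- breadthFromPoints(cbind(t = c(0, 2), p = c(0, 3)))
#' breadth(b)   # 2 * 3 = 6
#' @export
breadthFromPoints <- function(values) {
  values <- as.matrix(values)
  if (nrow(values) < 1L || ncol(values) < 1L) stop("empty value matrix")
  if (any(!is.finite(values))) stop("values must be finite")
  nm <- colnames(values) %||% paste0("v", seq_len(ncol(values)))
  new("NicheBreadth", variables = nm,
      mins = apply(values, 2L, min), maxs = apply(values, 2L, max),
      nPoints = nrow(values))
}

#' Incrementally extend a niche breadth with new points
#'
#' Yields exactly the extrema that [breadthFromPoints()] would give on the
#' concatenated point set, whatever the update order or batching.
#'
#' @param state a [NicheBreadth-class].
#' @param newValues numeric matrix whose columns match `state`'s variables
#'   (an empty matrix leaves the state unchanged).
#' @return the updated [NicheBreadth-class].
#' @export
updateBreadth <- function(state, newValues) {
  stopifnot(is(state, "NicheBreadth"))
  newValues <- as.matrix(newValues)
  if (nrow(newValues) == 0L) return(state)
  nm <- colnames(newValues)
  if (!is.null(nm) && !identical(nm, state@variables))
    stop("column mismatch between update and accumulated state")
  if (ncol(newValues) != length(state@variables))
    stop("column mismatch between update and accumulated state")
  if (any(!is.finite(newValues))) stop("values must be finite")
  initialize(state,
             mins = pmin(state@mins, apply(newValues, 2L, min)),
             maxs = pmax(state@maxs, apply(newValues, 2L, max)),
             nPoints = state@nPoints + nrow(newValues))
}

#' Ratio of an accumulated breadth to a reference breadth
#'
#' The accumulation curves are built from these ratios: partial over total
#' breadth for the native curve, combined over native for the alien and
#' background curves.
#'
#' @param accumulated,reference [NicheBreadth-class] objects.
#' @return numeric(1), `breadth(accumulated) / breadth(reference)`.
#' @export
breadthRatio <- function(accumulated, reference) {
  stopifnot(is(accumulated, "NicheBreadth"), is(reference, "NicheBreadth"))
  ref <- breadth(reference)
  if (ref <= 0) {
    amp <- amplitudes(reference)
    bad <- names(amp)[amp == 0]
    stop(sprintf(paste("reference niche breadth is zero; species has < 2",
                       "environmentally distinct records on variable(s): %s"),
                 paste(bad, collapse = ", ")))
  }
  breadth(accumulated) / ref
}
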