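# Asymptote detection on mean curves, the four-scenario outcome
# classification, and the sampling-bias screening diagnostic.

#' Detect an asymptote on a mean accumulation curve
#'
#' The judgement is a dual criterion on the repetition-mean curve: the curve
#' must reach `riseThreshold` (default 95%) of its total rise above the
#' curve-kind baseline within `maxFraction` (default half) of the steps, and
#' the mean per-step increase over the final 20% of steps, relative to the
#' total rise, must not exceed `tailSlopeMax`. Native-style curves rise from
#' a baseline of 0; alien and background curves from 1 (their value with no
#' regions included). A flat curve (zero rise, e.g. an alien curve stuck at
#' 1) counts as reached. Curves with fewer than 3 steps give an undetermined
#' verdict, treated as not reached, with a warning.
#'
#' @param curve a [CNACurve-class], or a numeric mean-curve vector.
#' @param riseThreshold fraction of the total rise, default 0.95.
#' @param maxFraction largest acceptable fraction of steps, default 0.5.
#' @param tailSlopeMax largest acceptable relative tail slope, default 0.01.
#' @param baseline override for the curve baseline (default: 0 for native
#'   and bare numeric curves, 1 for alien/background).
#' @return an [AsymptoteVerdict-class].
#' @export
detectAsymptote <- function(curve, riseThreshold = 0.95, maxFraction = 0.5,
                            tailSlopeMax = 0.01, baseline = NULL) {
  if (is(curve, "CNACurve")) {
    y <- curveMean(curve)
    if (is.null(baseline))
      baseline <- if (curveKind(curve) %in% c("alien", "background")) 1 else 0
  } else {
    y <- as.numeric(curve)
    if (is.null(baseline)) baseline <- 0
  }
  n <- length(y)
  if (n < 3L) {
    warning("curve has fewer than 3 steps; asymptote verdict is undetermined")
    return(new("AsymptoteVerdict", reached = FALSE, fractionAt95 = NA_real_,
               tailSlope = NA_real_, undetermined = TRUE))
  }
  rise <- y[n] - baseline
  if (rise < 0) stop("curve ends below its baseline; total rise must be >= 0")
  if (rise <= 1e-12) {
    return(new("AsymptoteVerdict", reached = TRUE, fractionAt95 = 1 / n,
               tailSlope = 0, undetermined = FALSE))
  }
  k <- which(y >= baseline + riseThreshold * rise)[1L]
  fraction <- k / n
  m <- max(1L, floor(0.2 * n))
  tailSlope <- max(0, (y[n] - y[n - m]) / m / rise)
  new("AsymptoteVerdict",
      reached = (fraction <= maxFraction) && (tailSlope <= tailSlopeMax),
      fractionAt95 = fraction, tailSlope = tailSlope, undetermined = FALSE)
}

#' Classify a run into the four outcome scenarios
#'
#' Scenario labels follow the asymptote verdicts: (a) native and alien
#' both saturate; (b) only the alien curve saturates; (c) only the native
#' curve saturates; (d) neither does. Niche-comparison confidence is high
#' exactly when the native curve saturates; projection confidence is high
#' when the alien curve saturates *and* the background curve shows headroom
#' -- an alien asymptote without headroom is demoted as uninformative, since
#' the invaded regions' conditions are environmentally nested in what the
#' species already realises, flattening the curve for reasons unrelated to
#' its tolerances. That demotion is surfaced as the nestedness flag.
#'
#' @param native,alien [AsymptoteVerdict-class] objects for the native and
#'   alien curves (undetermined verdicts count as not reached).
#' @param background,alienCurve the [CNACurve-class] objects of the same run
#'   (sharing a region order).
#' @param headroomMargin relative margin by which the background curve's
#'   final mean must exceed the alien curve's, default 0.05.
#' @return a [CNAOutcome-class].
#' @export
classifyOutcome <- function(native, alien, background, alienCurve,
                            headroomMargin = 0.05) {
  stopifnot(is(native, "AsymptoteVerdict"), is(alien, "AsymptoteVerdict"),
            is(background, "CNACurve"), is(alienCurve, "CNACurve"))
  aMean <- curveMean(alienCurve); bMean <- curveMean(background)
  alienFinal <- aMean[length(aMean)]
  bgFinal <- bMean[length(bMean)]
  headroom <- (bgFinal - alienFinal) / alienFinal > headroomMargin
  nat <- isTRUE(native@reached)
  ali <- isTRUE(alien@reached)
  scenario <- if (nat && ali) "a" else if (!nat && ali) "b"
              else if (nat) "c" else "d"
  nested <- ali && !headroom
  new("CNAOutcome",
      scenario = scenario,
      nicheComparisonConfidence = if (nat) "high" else "low",
      projectionConfidence = if (ali && headroom) "high" else "low",
      backgroundHeadroom = headroom,
      nestednessFlag = nested,
      expansionRatio = unname(alienFinal),
      verdicts = list(native = native, alien = alien),
      thresholds = list(headroomMargin = headroomMargin))
}

#' Write an outcome report as JSON
#'
#' @param outcome a [CNAOutcome-class].
#' @param path output file.
#' @export
writeOutcomeReport <- function(outcome, path) {
  v <- function(x) list(reached = x@reached, fraction_at_95 = x@fractionAt95,
                        tail_slope = x@tailSlope, undetermined = x@undetermined)
  jsonlite::write_json(list(
    scenario = outcome@scenario,
    niche_comparison_confidence = outcome@nicheComparisonConfidence,
    projection_confidence = outcome@projectionConfidence,
    background_headroom = outcome@backgroundHeadroom,
    nestedness_flag = outcome@nestednessFlag,
    expansion_ratio = outcome@expansionRatio,
    verdicts = list(native = v(outcome@verdicts$native),
                    alien = v(outcome@verdicts$alien)),
    thresholds = outcome@thresholds
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Sampling-bias screening
#'
#' Compares the environmental space accumulated by the focal records against
#' a reference point set -- stratified-randomly sampled locations, or the
#' pooled records of a larger species group plausibly collected by similar
#' sampling processes. A focal breadth substantially narrower than the
#' reference breadth (ratio below `flagFraction`) flags possible sampling
#' bias: the asymptote of the focal curve may only reflect the well-sampled
#' portion of the species' realised niche.
#'
#' @param focalValues matrix of standardised values at the focal records.
#' @param referenceValues matrix over the same variables at the reference
#'   locations.
#' @param mode `"stratified_random"` or `"reference_group"` (annotation only).
#' @param flagFraction flag when focal/reference breadth falls below this,
#'   default 0.5.
#' @param nReps repetitions for the two accumulation curves.
#' @param seed integer seed.
#' @return list with `ratio`, `flagged`, breadths, and the focal and
#'   reference accumulation curves.
#' @export
biasScreen <- function(focalValues, referenceValues,
                       mode = c("stratified_random", "reference_group"),
                       flagFraction = 0.5, nReps = 10, seed = 1) {
  mode <- match.arg(mode)
  focalValues <- as.matrix(focalValues)
  referenceValues <- as.matrix(referenceValues)
  if (nrow(referenceValues) == 0L) stop("empty reference point set")
  if (!identical(colnames(focalValues), colnames(referenceValues)))
    stop("focal and reference matrices must share variables")
  bf <- breadthFromPoints(focalValues)
  br <- breadthFromPoints(referenceValues)
  ratio <- breadthRatio(bf, br)
  list(mode = mode,
       ratio = ratio,
       flagged = ratio < flagFraction,
       focalBreadth = breadth(bf),
       referenceBreadth = breadth(br),
       focalCurve = nativeCurve(focalValues, nReps = nReps, seed = stageSeed(seed, "bias-focal")),
       referenceCurve = nativeCurve(referenceValues, nReps = nReps,
                                    seed = stageSeed(seed, "bias-ref")))
}
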