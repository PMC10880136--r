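# Construction of the three accumulation curves: native (fold-wise), alien
# (region-wise), and background (region-wise over grid-sampled points),
# each over n_reps repetitions with the pointwise mean as the headline curve.

#' Fold plan for the native accumulation curve
#'
#' The fold size depends on the occurrence regime: more than 1000 records
#' gives folds of 100; between 31 and 1000 records, folds of 10; 30 records
#' or fewer, folds of 1. When the count does not divide evenly the last fold
#' is smaller, so the reference breadth always uses every record.
#'
#' @param n number of native occurrences (>= 1).
#' @return a [FoldPlan-class].
#' @examples
#' makeFoldPlan(45)   # folds 10,10,10,10,5
#' @export
makeFoldPlan <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("need at least one occurrence")
  if (n > 1000L)      { per <- 100L; rule <- "per100" }
  else if (n > 30L)   { per <- 10L;  rule <- "per10" }
  else                { per <- 1L;   rule <- "per1" }
  sizes <- rep(per, n %/% per)
  if (n %% per) sizes <- c(sizes, n %% per)
  new("FoldPlan", sizes = sizes, rule = rule)
}

newCurve <- function(kind, reps, stepLabels, regionOrder = NULL, flags = list()) {
  new("CNACurve", kind = kind, reps = reps, stepLabels = as.character(stepLabels),
      regionOrder = regionOrder, flags = flags)
}

#' Native niche accumulation curve
#'
#' Per repetition, the native records are shuffled and partitioned into folds
#' (see [makeFoldPlan()]); the value at step k is the breadth of the first k
#' folds divided by the breadth of all records. Every repetition row is
#' non-decreasing and ends at exactly 1; the mean curve is the average over
#' repetitions.
#'
#' @param nativeValues numeric matrix of standardised values at native
#'   records (points x selected variables).
#' @param nReps repetitions, default 10.
#' @param seed integer seed (required).
#' @return a [CNACurve-class] of kind `"native"`.
#' @export
nativeCurve <- function(nativeValues, nReps = 10, seed) {
  nativeValues <- as.matrix(nativeValues)
  n <- nrow(nativeValues)
  reference <- breadthFromPoints(nativeValues)
  breadthRatio(reference, reference)   # errors when the reference breadth is zero
  plan <- makeFoldPlan(n)
  nf <- length(plan@sizes)
  ends <- cumsum(plan@sizes)
  reps <- matrix(NA_real_, nReps, nf)
  withSeed(stageSeed(seed, "native-curve"), {
    for (r in seq_len(nReps)) {
      perm <- sample.int(n)
      state <- NULL
      for (k in seq_len(nf)) {
        rows <- perm[(c(0L, ends)[k] + 1L):ends[k]]
        chunk <- nativeValues[rows, , drop = FALSE]
        state <- if (is.null(state)) breadthFromPoints(chunk)
                 else updateBreadth(state, chunk)
        reps[r, k] <- breadthRatio(state, reference)
      }
    }
  })
  newCurve("native", reps, stepLabels = paste0("fold", seq_len(nf)),
           flags = list(foldRule = plan@rule))
}

#' Alien niche accumulation curve
#'
#' Per repetition, a fresh uniform random permutation of the alien regions is
#' drawn; at step k the occurrences of the first k regions are combined with
#' the native occurrences and the breadth is divided by the native reference
#' breadth, so every value is >= 1 and rows are non-decreasing. Regions with
#' no surviving records remain as steps (adding nothing) and are flagged.
#'
#' @param nativeValues matrix of standardised values at native records.
#' @param alienValuesByRegion named list of matrices, one per alien region
#'   (possibly 0-row), sharing columns with `nativeValues`.
#' @param nReps repetitions, default 10.
#' @param seed integer seed.
#' @return a [CNACurve-class] of kind `"alien"`; the per-repetition region
#'   inclusion order is in `regionOrder()` for reuse by [backgroundCurve()].
#' @export
alienCurve <- function(nativeValues, alienValuesByRegion, nReps = 10, seed) {
  nativeValues <- as.matrix(nativeValues)
  m <- length(alienValuesByRegion)
  if (m < 1L) stop("no alien regions supplied")
  rows <- vapply(alienValuesByRegion, nrow, integer(1))
  if (sum(rows) == 0L) stop("no alien records in any region")
  reference <- breadthFromPoints(nativeValues)
  breadthRatio(reference, reference)
  ids <- names(alienValuesByRegion)
  reps <- matrix(NA_real_, nReps, m)
  order <- matrix(NA_character_, nReps, m)
  withSeed(stageSeed(seed, "alien-curve"), {
    for (r in seq_len(nReps)) {
      perm <- sample(ids)
      order[r, ] <- perm
      state <- reference
      for (k in seq_len(m)) {
        state <- updateBreadth(state, alienValuesByRegion[[perm[k]]])
        reps[r, k] <- breadthRatio(state, reference)
      }
    }
  })
  flags <- list()
  if (any(rows == 0L)) flags$emptyRegions <- ids[rows == 0L]
  newCurve("alien", reps, stepLabels = paste0("step", seq_len(m)),
           regionOrder = order, flags = flags)
}

#' Sample one background point per grid cell inside a region
#'
#' Enumerates the cells of the background grid (default 0.25 degrees,
#' anchored at (-180, -90)) that intersect the region polygon -- by default a
#' cell counts when its centre is inside the polygon; `cellMode = "overlap"`
#' accepts any cell whose rectangle touches the polygon -- and draws one
#' uniformly random point within each such cell. Points landing on nodata
#' are redrawn up to `maxRedraw` times, after which the cell is skipped.
#'
#' @param region a polygon.
#' @param stack a standardised [EnvStack-class].
#' @param grid background [gridSpec()], default 0.25 degrees.
#' @param seed integer seed.
#' @param maxRedraw redraw attempts per nodata cell.
#' @param cellMode `"center"` or `"overlap"`.
#' @return list with `points` (lon/lat matrix) and `values` (points x layers
#'   matrix of extracted values).
#' @export
sampleBackgroundPoints <- function(region, stack, grid = gridSpec(0.25), seed,
                                   maxRedraw = 10L, cellMode = c("center", "overlap")) {
  cellMode <- match.arg(cellMode)
  poly <- asPolygon(region)
  bb <- polygonBBox(poly)
  cs <- grid$cellSize
  c0 <- floor((bb[1L] - grid$origin[1L]) / cs)
  c1 <- floor((bb[2L] - grid$origin[1L]) / cs)
  r0 <- floor((bb[3L] - grid$origin[2L]) / cs)
  r1 <- floor((bb[4L] - grid$origin[2L]) / cs)
  cells <- expand.grid(col = c0:c1, row = r0:r1)
  x0 <- grid$origin[1L] + cells$col * cs
  y0 <- grid$origin[2L] + cells$row * cs
  keep <- if (cellMode == "center") {
    pointInPolygon(x0 + cs / 2, y0 + cs / 2, poly)
  } else {
    vapply(seq_len(nrow(cells)), function(i)
      polygonsIntersect(rectPolygon(x0[i], x0[i] + cs, y0[i], y0[i] + cs), poly),
      logical(1))
  }
  x0 <- x0[keep]; y0 <- y0[keep]
  nc <- length(x0)
  if (nc == 0L)
    return(list(points = matrix(numeric(0), 0, 2, dimnames = list(NULL, c("lon", "lat"))),
                values = matrix(numeric(0), 0, nLayers(stack),
                                dimnames = list(NULL, layerNames(stack)))))
  withSeed(seed, {
    pts <- cbind(lon = x0 + stats::runif(nc) * cs, lat = y0 + stats::runif(nc) * cs)
    vals <- suppressWarnings(extractValues(stack, pts))
    kept <- attr(vals, "kept")
    for (attempt in seq_len(maxRedraw)) {
      missing <- setdiff(seq_len(nc), kept)
      if (length(missing) == 0L) break
      pts[missing, ] <- cbind(x0[missing] + stats::runif(length(missing)) * cs,
                              y0[missing] + stats::runif(length(missing)) * cs)
      vv <- suppressWarnings(extractValues(stack, pts[missing, , drop = FALSE]))
      if (nrow(vv) > 0L) {
        ok <- missing[attr(vv, "kept")]
        vals <- rbind(vals, vv)
        kept <- c(kept, ok)
      }
    }
    ord <- order(kept)
    list(points = pts[kept[ord], , drop = FALSE],
         values = vals[ord, , drop = FALSE])
  })
}

#' Background niche accumulation curve
#'
#' Mirrors the alien curve, but each region contributes one random point per
#' background-grid cell instead of the species' records, quantifying the
#' maximum niche expansion the regions' available conditions would allow.
#' Background points are drawn once and reused across repetitions; only the
#' region order (shared with the alien curve of the same run) varies.
#'
#' @param nativeValues matrix of standardised values at native records
#'   (columns = selected variables).
#' @param regions named list of region polygons.
#' @param stack standardised [EnvStack-class] (must contain the selected
#'   variables as layers).
#' @param order character matrix of per-repetition region orders, as returned
#'   in `regionOrder()` of the [alienCurve()] of the same run.
#' @param grid background [gridSpec()], default 0.25 degrees.
#' @param seed integer seed.
#' @param includeAlienOccurrences when `TRUE`, each step also pools the alien
#'   records of the included regions (guaranteeing the background curve
#'   dominates the alien curve pointwise).
#' @param alienValuesByRegion needed when `includeAlienOccurrences = TRUE`.
#' @param cellMode passed to [sampleBackgroundPoints()].
#' @return a [CNACurve-class] of kind `"background"`.
#' @export
backgroundCurve <- function(nativeValues, regions, stack, order,
                            grid = gridSpec(0.25), seed,
                            includeAlienOccurrences = FALSE,
                            alienValuesByRegion = NULL,
                            cellMode = c("center", "overlap")) {
  cellMode <- match.arg(cellMode)
  nativeValues <- as.matrix(nativeValues)
  vars <- colnames(nativeValues)
  if (is.null(vars)) stop("nativeValues needs column names naming the selected variables")
  stopifnot(is.matrix(order), all(vars %in% layerNames(stack)))
  ids <- sort(unique(as.vector(order)))
  if (!all(ids %in% names(regions))) stop("region order names regions not supplied")
  if (includeAlienOccurrences && is.null(alienValuesByRegion))
    stop("alienValuesByRegion needed when includeAlienOccurrences is TRUE")
  reference <- breadthFromPoints(nativeValues)
  breadthRatio(reference, reference)
  bg <- list()
  for (rid in ids) {
    s <- sampleBackgroundPoints(regions[[rid]], stack, grid = grid,
                                seed = stageSeed(seed, paste0("bg-", rid)),
                                cellMode = cellMode)
    v <- s$values
    if (!is.null(vars)) v <- v[, vars, drop = FALSE]
    bg[[rid]] <- v
  }
  nEmpty <- vapply(bg, nrow, integer(1)) == 0L
  nReps <- nrow(order); m <- ncol(order)
  reps <- matrix(NA_real_, nReps, m)
  for (r in seq_len(nReps)) {
    state <- reference
    for (k in seq_len(m)) {
      rid <- order[r, k]
      state <- updateBreadth(state, bg[[rid]])
      if (includeAlienOccurrences)
        state <- updateBreadth(state, as.matrix(alienValuesByRegion[[rid]])[, vars, drop = FALSE])
      reps[r, k] <- breadthRatio(state, reference)
    }
  }
  flags <- list()
  if (any(nEmpty)) flags$emptyRegions <- ids[nEmpty]
  newCurve("background", reps, stepLabels = paste0("step", seq_len(m)),
           regionOrder = order, flags = flags)
}

#' Write a curve as long-form CSV
#'
#' Columns: `curve_kind`, `repetition`, `step`, `label`, `ratio`.
#'
#' @param curve a [CNACurve-class].
#' @param path output file.
#' @export
writeCurveCSV <- function(curve, path) {
  reps <- curveReps(curve)
  d <- expand.grid(repetition = seq_len(nrow(reps)), step = seq_len(ncol(reps)))
  d <- data.frame(curve_kind = curveKind(curve), repetition = d$repetition,
                  step = d$step, label = curve@stepLabels[d$step],
                  ratio = reps[cbind(d$repetition, d$step)])
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Plot the accumulation-curve panels
#'
#' Draws the per-repetition traces in grey with the mean curves on top:
#' native in green, alien in red, background in blue.
#'
#' @param native,alien,background [CNACurve-class] objects (any may be NULL).
#' @param path optional file to write (PNG/SVG/PDF by extension).
#' @return a ggplot object, invisibly when `path` is given.
#' @export
plotCurves <- function(native = NULL, alien = NULL, background = NULL, path = NULL) {
  longRep <- function(curve, panel) {
    if (is.null(curve)) return(NULL)
    reps <- curveReps(curve)
    d <- expand.grid(repetition = seq_len(nrow(reps)), step = seq_len(ncol(reps)))
    data.frame(panel = panel, kind = curveKind(curve), repetition = d$repetition,
               step = d$step, ratio = reps[cbind(d$repetition, d$step)])
  }
  dd <- rbind(longRep(native, "native folds"),
              longRep(alien, "alien regions"), longRep(background, "alien regions"))
  if (is.null(dd)) stop("no curves to plot")
  means <- do.call(rbind, lapply(split(dd, list(dd$panel, dd$kind), drop = TRUE),
    function(g) data.frame(panel = g$panel[1], kind = g$kind[1],
                           step = sort(unique(g$step)),
                           ratio = tapply(g$ratio, g$step, mean))))
  cols <- c(native = "#2e7d32", alien = "#c62828", background = "#1565c0")
  p <- ggplot2::ggplot(dd, ggplot2::aes(x = .data$step, y = .data$ratio)) +
    ggplot2::geom_line(ggplot2::aes(group = interaction(.data$kind, .data$repetition)),
                       colour = "grey70", linewidth = 0.3) +
    ggplot2::geom_line(data = means, ggplot2::aes(colour = .data$kind), linewidth = 1) +
    ggplot2::scale_colour_manual(values = cols, name = NULL) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = "accumulation step", y = "niche breadth ratio") +
    ggplot2::theme_minimal()
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = 9, height = 4, dpi = 150)
    return(invisible(p))
  }
  p
}
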