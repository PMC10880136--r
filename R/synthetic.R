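# Virtual-species and landscape generators: seeded, download-free inputs
# with known ground truth (true niche box, true outcome scenario) for every
# other module.

#' Generate a synthetic environmental stack
#'
#' Each base field is a linear spatial gradient in a random direction plus
#' smoothed Gaussian noise. Base fields are Gram-Schmidt orthogonalised (so
#' an identity mixing matrix yields mutually uncorrelated layers) and then
#' combined by the `mixing` matrix, which imposes a controllable correlation
#' structure to exercise the collinearity filter. The result is standardised.
#'
#' @param nCols,nRows grid dimensions (>= 8).
#' @param kVars number of layers.
#' @param smoothness number of 3x3 smoothing passes applied to the noise
#'   component; 0 suppresses noise entirely (pure gradients).
#' @param seed integer seed; identical seeds give bitwise-identical stacks.
#' @param mixing kVars x kVars matrix combining the orthogonal base fields
#'   (rows = output layers); default identity.
#' @param noiseWeight relative weight of the noise component, default 0.5.
#' @param origin,cellSize grid georeferencing.
#' @param orthogonalize orthogonalise base fields before mixing (default TRUE).
#' @return a standardised [EnvStack-class] with layers `env1..envk`.
#' @export
generateStack <- function(nCols = 64, nRows = 64, kVars = 3, smoothness = 2,
                          seed, mixing = NULL, noiseWeight = 0.5,
                          origin = c(0, 0), cellSize = 0.25,
                          orthogonalize = TRUE) {
  stopifnot(nCols >= 8, nRows >= 8, kVars >= 1)
  if (is.null(mixing)) mixing <- diag(kVars)
  stopifnot(is.matrix(mixing), nrow(mixing) == kVars, ncol(mixing) == kVars)
  withSeed(stageSeed(seed, "stack"), {
    X <- matrix(rep((seq_len(nCols) - 0.5) / nCols, each = nRows), nRows, nCols)
    Y <- matrix(rep((seq_len(nRows) - 0.5) / nRows, nCols), nRows, nCols)
    base <- matrix(NA_real_, nRows * nCols, kVars)
    for (i in seq_len(kVars)) {
      theta <- stats::runif(1, 0, 2 * pi)
      g <- cos(theta) * X + sin(theta) * Y
      f <- scale(as.vector(g))[, 1L]
      if (smoothness > 0) {
        n <- matrix(stats::rnorm(nRows * nCols), nRows, nCols)
        for (p in seq_len(smoothness)) n <- boxBlur(n)
        f <- f + noiseWeight * scale(as.vector(n))[, 1L]
      }
      base[, i] <- f
    }
    if (orthogonalize && kVars > 1L) {
      base <- scale(base, center = TRUE, scale = FALSE)
      base <- qr.Q(qr(base)) * sqrt(nRows * nCols)
    }
    mixed <- base %*% t(mixing)
    layers <- setNames(lapply(seq_len(kVars), function(i)
      matrix(mixed[, i], nRows, nCols)), paste0("env", seq_len(kVars)))
    standardizeStack(envStack(layers, origin = origin, cellSize = cellSize))
  })
}

# one 3x3 box-smoothing pass with replicated edges
boxBlur <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- m[c(1L, seq_len(nr), nr), c(1L, seq_len(nc), nc)]
  acc <- matrix(0, nr, nc)
  for (di in 0:2) for (dj in 0:2)
    acc <- acc + p[di + seq_len(nr), dj + seq_len(nc)]
  acc / 9
}

#' Generate the fold-symmetric scenario landscape
#'
#' A deterministic landscape purpose-built for the outcome-scenario presets:
#' `bio1 = sin(4 pi x) + noise`, `bio2 = sin(4 pi y) + noise`, and `bio3 =
#' 0.8 bio1 + 0.6 bio2 + noise` (a collinear decoy: `|r(bio1, bio3)|` is
#' about 0.79 and `bio3` carries the largest variance inflation, so the
#' collinearity filter removes exactly it),
#' where x, y are map-relative coordinates. The two-period sine makes
#' environmental conditions repeat in geographically disjoint blocks, so
#' alien regions can be environmentally nested in -- or controllably novel
#' relative to -- a native range they never touch. The stack is standardised.
#'
#' @param seed integer seed.
#' @param nBgCells number of 0.25-degree background cells per side (default
#'   64, a 16 x 16 degree map).
#' @param subdivision stack cells per background cell per side (default 3,
#'   i.e. 5-arc-minute environmental cells).
#' @param noiseSd standard deviation of the additive noise on `bio1`/`bio2`
#'   (`bio3` uses 10x this).
#' @param origin lower-left corner, default `c(0, 0)`.
#' @return a standardised [EnvStack-class] with layers `bio1`, `bio2`, `bio3`.
#' @export
generateScenarioStack <- function(seed, nBgCells = 64L, subdivision = 3L,
                                  noiseSd = 0.01, origin = c(0, 0)) {
  n <- nBgCells * subdivision
  cellSize <- 0.25 / subdivision
  withSeed(stageSeed(seed, "scenario-stack"), {
    relx <- (seq_len(n) - 0.5) / n
    v1 <- matrix(rep(sin(4 * pi * relx), each = n), n, n) +
      stats::rnorm(n * n, sd = noiseSd)
    v2 <- matrix(rep(sin(4 * pi * relx), n), n, n) +
      stats::rnorm(n * n, sd = noiseSd)
    v3 <- 0.8 * v1 + 0.6 * v2 + stats::rnorm(n * n, sd = 10 * noiseSd)
    standardizeStack(envStack(list(bio1 = v1, bio2 = v2, bio3 = v3),
                              origin = origin, cellSize = cellSize))
  })
}

# map-relative [0,1] coords -> lon/lat on a stack
relRect <- function(stack, x0, x1, y0, y1) {
  e <- extentOf(stack)
  w <- e[["xmax"]] - e[["xmin"]]; h <- e[["ymax"]] - e[["ymin"]]
  rectPolygon(e[["xmin"]] + x0 * w, e[["xmin"]] + x1 * w,
              e[["ymin"]] + y0 * h, e[["ymin"]] + y1 * h)
}

# stack cell centers falling inside a polygon, with their layer values
cellsInPolygon <- function(stack, polygon) {
  bb <- polygonBBox(polygon)
  d <- gridDim(stack); cs <- stack@cellSize
  cx <- stack@origin[1L] + (seq_len(d[["ncol"]]) - 0.5) * cs
  cy <- stack@origin[2L] + (seq_len(d[["nrow"]]) - 0.5) * cs
  ix <- which(cx >= bb[1L] - cs & cx <= bb[2L] + cs)
  iy <- which(cy >= bb[3L] - cs & cy <= bb[4L] + cs)
  if (!length(ix) || !length(iy))
    return(data.frame(lon = numeric(0), lat = numeric(0), col = integer(0), row = integer(0)))
  g <- expand.grid(col = ix, row = iy)
  lon <- cx[g$col]; lat <- cy[g$row]
  keep <- pointInPolygon(lon, lat, polygon)
  data.frame(lon = lon[keep], lat = lat[keep], col = g$col[keep], row = g$row[keep])
}

# per-layer min/max of stack cell values over cells whose centers fall in
# the polygon
regionEnvBox <- function(stack, polygon) {
  cells <- cellsInPolygon(stack, polygon)
  if (nrow(cells) == 0L) return(NULL)
  vals <- vapply(stack@layers, function(m) m[cbind(cells$row, cells$col)],
                 numeric(nrow(cells)))
  vals <- matrix(vals, nrow = nrow(cells), dimnames = list(NULL, layerNames(stack)))
  rbind(low = apply(vals, 2L, min), high = apply(vals, 2L, max))
}

#' Place native and alien regions with controlled environmental novelty
#'
#' Requires the fold-symmetric landscape of [generateScenarioStack()]. The
#' native range is a fixed block in the lower-left fold; alien regions are
#' rectangles (snapped to the background grid for the nested layout) whose
#' environmental envelopes realise the requested layout:
#' \describe{
#'   \item{nested}{regions in the diagonally mirrored fold, whose conditions
#'     repeat the native block's interior; every region's environmental box
#'     must verify as a subset of the native box.}
#'   \item{novel}{a convex "staircase" of regions reaching progressively
#'     deeper into conditions absent from the native range, so pooled
#'     novelty keeps growing as regions accumulate.}
#'   \item{novel_uniform}{regions with identical environmental novelty, so
#'     the first region already offers everything the rest do.}
#' }
#' Placements are verified post hoc against the stack's actual cell values
#' (nested: box containment; novel: pooled alien amplitude at least
#' `noveltyTarget` times the native amplitude on some variable) and
#' re-jittered up to `maxAttempts` times before erroring.
#'
#' @param stack stack from [generateScenarioStack()].
#' @param layout `"nested"`, `"novel"`, or `"novel_uniform"`.
#' @param seed integer seed.
#' @param nAlien number of alien regions (default 10; 0 gives an empty set).
#' @param noveltyTarget required pooled-amplitude multiple for novel
#'   layouts, default 2.
#' @param maxAttempts placement attempts per verification failure.
#' @return list with `native` (polygon), `regions` (named list of polygons),
#'   `layout`.
#' @export
generateRegions <- function(stack, layout = c("nested", "novel", "novel_uniform"),
                            seed, nAlien = 10L, noveltyTarget = 2,
                            maxAttempts = 50L) {
  layout <- match.arg(layout)
  native <- relRect(stack, 1 / 64, 12 / 64, 1 / 64, 12 / 64)
  nativeBox <- regionEnvBox(stack, native)
  if (nAlien == 0L)
    return(list(native = native, regions = setNames(list(), character(0)), layout = layout))
  ids <- sprintf("reg%02d", seq_len(nAlien))
  regions <- withSeed(stageSeed(seed, "regions"), {
    if (layout == "nested") {
      # two columns x ten rows of sub-blocks in the mirrored fold, clear of
      # the fold's environmental peak
      stopifnot(nAlien <= 10L)
      slots <- expand.grid(xcell = c(34L, 36L), yrow = 34L:38L)
      out <- list()
      for (j in seq_len(nAlien)) {
        ok <- FALSE
        for (att in seq_len(maxAttempts)) {
          s <- slots[(j - 1L + att - 1L) %% nrow(slots) + 1L, ]
          cand <- relRect(stack, s$xcell / 64, (s$xcell + 2L) / 64,
                          s$yrow / 64, (s$yrow + 1L) / 64)
          box <- regionEnvBox(stack, cand)
          if (!is.null(box) && all(box["low", ] >= nativeBox["low", ]) &&
              all(box["high", ] <= nativeBox["high", ])) { ok <- TRUE; break }
        }
        if (!ok) stop(sprintf(
          "could not place nested region %d: candidate envelope exceeds the native box", j))
        out[[j]] <- cand
      }
      out
    } else {
      nativeAmp <- nativeBox["high", ] - nativeBox["low", ]
      # uniform regions span the whole novelty corridor so every region
      # contains both tolerable and intolerable conditions; staircase
      # regions are narrow bands at their target depth
      w <- if (layout == "novel_uniform") 6 / 64 else 1.5 / 64
      rightEdges <- if (layout == "novel_uniform") {
        rep(23 / 64, nAlien)
      } else {
        # convex novelty staircase: solve sin(4 pi x) for raw bio1 minima
        # giving combined/native amplitude ratios 1 + span*(j/n)^6
        span <- max(0.5, noveltyTarget - 0.4)
        targets <- 1 + span * (seq_len(nAlien) / nAlien)^6
        # raw native bio1 amplitude of the fold landscape is ~ 1 - sin(4*pi/64);
        # combined amplitude rawAmp * target gives the target raw minimum s
        rawAmp <- 1 - 0.23
        s <- pmax(-0.995, 1 - rawAmp * targets)
        (pi + ifelse(s >= 0, -asin(s), asin(-s))) / (4 * pi)
      }
      if (layout == "novel_uniform") {
        # latitude bands where sin(4 pi y) stays in ~[0.57, 0.95]: deep
        # inside the native bio2 range even under sparse native sampling,
        # so no region expands bio2; the second sine fold (y + 0.5) offers
        # identical conditions and doubles the available bands
        yBase <- c(0.048, 0.065, 0.082, 0.151, 0.168, 0.185)
        yBase <- c(yBase, yBase + 0.5)
        if (nAlien > length(yBase))
          stop(sprintf("novel_uniform layout supports at most %d regions", length(yBase)))
        yb <- yBase[seq_len(nAlien)]
        yh <- 1 / 64
      } else {
        yb <- 1 / 64 + (seq_len(nAlien) - 1L) * (11 / 64) / nAlien
        yh <- 0.9 * (11 / 64) / nAlien
      }
      out <- list()
      for (j in seq_len(nAlien))
        out[[j]] <- relRect(stack, rightEdges[j] - w, rightEdges[j],
                            yb[j], yb[j] + yh)
      # verify pooled novelty, deepening the last region if needed
      for (att in seq_len(maxAttempts)) {
        pooled <- do.call(rbind, lapply(out, function(p) {
          b <- regionEnvBox(stack, p); if (is.null(b)) NULL else b
        }))
        if (is.null(pooled)) stop("novel layout produced regions with no cells")
        lows <- apply(pooled[rownames(pooled) == "low", , drop = FALSE], 2L, min)
        highs <- apply(pooled[rownames(pooled) == "high", , drop = FALSE], 2L, max)
        combinedAmp <- pmax(highs, nativeBox["high", ]) - pmin(lows, nativeBox["low", ])
        if (any(combinedAmp >= noveltyTarget * nativeAmp)) break
        if (att == maxAttempts)
          stop(sprintf(
            "novelty target %.2fx unattainable: best pooled amplitude %.2fx",
            noveltyTarget, max(combinedAmp / nativeAmp)))
        deepest <- min(rightEdges[nAlien] + 0.005, 0.37)
        rightEdges[nAlien] <- deepest
        out[[nAlien]] <- relRect(stack, deepest - w, deepest,
                                 yb[nAlien], yb[nAlien] + yh)
      }
      out
    }
  })
  list(native = native, regions = setNames(regions, ids), layout = layout)
}

#' Define a virtual species by its niche box
#'
#' @param niche 2 x k matrix (rows `low`, `high`, columns named by variable)
#'   in standardised environmental units.
#' @param softening logistic softening width in standardised units; 0 (the
#'   default) gives a hard box.
#' @return a [VirtualSpecies-class].
#' @export
virtualSpecies <- function(niche, softening = 0) {
  rownames(niche) <- c("low", "high")
  new("VirtualSpecies", niche = niche, softening = softening)
}

#' @rdname virtualSpecies
#' @param species a [VirtualSpecies-class].
#' @return `trueBreadth`: the product of the niche-box widths.
#' @export
trueBreadth <- function(species) prod(species@niche["high", ] - species@niche["low", ])

# suitability of standardised value rows for a species; logical for a hard
# box, probability in (0,1) with logistic softening
suitabilityOf <- function(species, values) {
  vars <- colnames(species@niche)
  stopifnot(all(vars %in% colnames(values)))
  v <- values[, vars, drop = FALSE]
  lo <- matrix(species@niche["low", ], nrow(v), length(vars), byrow = TRUE)
  hi <- matrix(species@niche["high", ], nrow(v), length(vars), byrow = TRUE)
  if (species@softening <= 0) {
    apply(v >= lo & v <= hi, 1L, all)
  } else {
    s <- species@softening
    apply(stats::plogis((v - lo) / s) * stats::plogis((hi - v) / s), 1L, prod)
  }
}

#' Sample virtual-species occurrences inside a polygon
#'
#' Draws a uniform sample of environmentally suitable stack cells inside the
#' polygon and places one point uniformly at random within each chosen cell.
#' `completeness < 1` truncates the species' niche box to that fraction of
#' each axis (keeping the lower portion) before sampling, emulating an
#' unsampled portion of the niche. Bias modes: `"spatial-cluster"` weights
#' cells by a Gaussian kernel around a random focus; `"env-truncation"`
#' halves the first niche axis.
#'
#' @param species a [VirtualSpecies-class] (box in standardised units).
#' @param stack standardised [EnvStack-class].
#' @param polygon sampling region.
#' @param n number of records wanted (capped at the number of suitable cells).
#' @param completeness fraction of each niche axis sampled, default 1.
#' @param bias `"none"`, `"spatial-cluster"`, or `"env-truncation"`.
#' @param seed integer seed.
#' @return data.frame with columns `lon`, `lat`.
#' @export
sampleOccurrences <- function(species, stack, polygon, n, completeness = 1,
                              bias = c("none", "spatial-cluster", "env-truncation"),
                              seed) {
  bias <- match.arg(bias)
  stopifnot(completeness > 0, completeness <= 1)
  niche <- species@niche
  if (completeness < 1)
    niche["high", ] <- niche["low", ] + completeness * (niche["high", ] - niche["low", ])
  if (bias == "env-truncation")
    niche["high", 1L] <- niche["low", 1L] + 0.5 * (niche["high", 1L] - niche["low", 1L])
  eff <- virtualSpecies(niche, species@softening)
  cells <- cellsInPolygon(stack, polygon)
  if (nrow(cells) == 0L) stop("polygon contains no stack cells")
  vals <- vapply(stack@layers, function(m) m[cbind(cells$row, cells$col)],
                 numeric(nrow(cells)))
  vals <- matrix(vals, nrow = nrow(cells), dimnames = list(NULL, layerNames(stack)))
  suit <- suitabilityOf(eff, vals)
  withSeed(stageSeed(seed, "occ"), {
    if (eff@softening > 0) suit <- stats::runif(length(suit)) < suit
    ok <- which(as.logical(suit))
    if (length(ok) == 0L) stop("no suitable cells inside the polygon")
    m <- min(n, length(ok))
    wts <- NULL
    if (bias == "spatial-cluster") {
      ctr <- cells[ok[sample.int(length(ok), 1L)], ]
      sig <- 0.1 * (extentOf(stack)[["xmax"]] - extentOf(stack)[["xmin"]])
      dd <- (cells$lon[ok] - ctr$lon)^2 + (cells$lat[ok] - ctr$lat)^2
      wts <- exp(-dd / (2 * sig^2))
    }
    pick <- if (is.null(wts)) ok[sample.int(length(ok), m)]
            else ok[sample.int(length(ok), m, prob = wts)]
    cs <- stack@cellSize
    data.frame(
      lon = stack@origin[1L] + (cells$col[pick] - 1L) * cs + stats::runif(m) * cs,
      lat = stack@origin[2L] + (cells$row[pick] - 1L) * cs + stats::runif(m) * cs)
  })
}

scenarioPresets <- function() {
  list(
    a = list(layout = "novel_uniform", nativeN = 300L, species = "capped",
             completeness = 1),
    b = list(layout = "novel_uniform", nativeN = 24L, species = "capped",
             completeness = 1),
    c = list(layout = "novel", nativeN = 300L, species = "wide", completeness = 1),
    d = list(layout = "novel", nativeN = 24L, species = "wide", completeness = 1),
    nested = list(layout = "nested", nativeN = 300L, species = "wide",
                  completeness = 1)
  )
}

# species boxes are designed in the raw units of the fold landscape and
# converted to standardised units with the stack's parameters
presetSpecies <- function(stack, which) {
  std <- standardization(stack)
  raw <- if (which == "capped") {
    cbind(bio1 = c(-0.45, 1.3), bio2 = c(-1.3, 1.3), bio3 = c(-1.2, 2.0))
  } else {
    cbind(bio1 = c(-1.3, 1.3), bio2 = c(-1.3, 1.3), bio3 = c(-2.2, 2.2))
  }
  vars <- colnames(raw)
  box <- rbind((raw[1L, ] - std$mean[vars]) / std$sd[vars],
               (raw[2L, ] - std$mean[vars]) / std$sd[vars])
  colnames(box) <- vars
  virtualSpecies(box)
}

#' Build a complete synthetic study system for an outcome scenario
#'
#' Assembles a full analysis input bundle -- standardised stack, native range
#' polygon, alien regions, checklist, and occurrence records -- whose designed
#' outcome is known. Presets `a`--`d` reproduce the four outcome scenarios:
#' \describe{
#'   \item{a}{well-sampled native range (300 records); alien regions of
#'     identical novelty, fully occupied up to the species' tolerance limit,
#'     with conditions beyond it (native and alien curves saturate;
#'     background headroom).}
#'   \item{b}{as `a` with only 24 native records (native curve unsaturated).}
#'   \item{c}{well-sampled native range; a convex staircase of increasingly
#'     novel regions that an unconstrained species keeps expanding into
#'     (alien curve unsaturated).}
#'   \item{d}{as `c` with 24 native records.}
#'   \item{nested}{alien regions environmentally nested in the native
#'     envelope: alien and background curves stay flat at 1 and the
#'     nestedness diagnostic fires.}
#' }
#'
#' @param preset `"a"`, `"b"`, `"c"`, `"d"`, or `"nested"`.
#' @param seed integer seed; same seed, byte-identical bundle.
#' @param nAlien number of alien regions, default 10.
#' @param nativeN,completeness optional overrides of the preset's knobs.
#' @return list (class `CNABundle`) with `stack`, `native`, `regions`,
#'   `checklist`, `occurrences` (data.frame species/lon/lat), `species`,
#'   `preset`, `trueLabel`.
#' @export
makeScenario <- function(preset = c("a", "b", "c", "d", "nested"), seed,
                         nAlien = 10L, nativeN = NULL, completeness = NULL) {
  preset <- match.arg(preset)
  p <- scenarioPresets()[[preset]]
  if (!is.null(nativeN)) p$nativeN <- nativeN
  if (!is.null(completeness)) p$completeness <- completeness
  stack <- generateScenarioStack(seed)
  geo <- generateRegions(stack, layout = p$layout, seed = seed, nAlien = nAlien)
  species <- presetSpecies(stack, p$species)
  natOcc <- sampleOccurrences(species, stack, geo$native, n = p$nativeN,
                              completeness = p$completeness,
                              seed = stageSeed(seed, "native-occ"))
  alienOcc <- list()
  for (rid in names(geo$regions)) {
    alienOcc[[rid]] <- tryCatch(
      sampleOccurrences(species, stack, geo$regions[[rid]], n = 10000L,
                        seed = stageSeed(seed, paste0("occ-", rid))),
      error = function(e) data.frame(lon = numeric(0), lat = numeric(0)))
  }
  occ <- rbind(natOcc, do.call(rbind, alienOcc))
  structure(list(
    stack = stack,
    native = geo$native,
    regions = geo$regions,
    checklist = names(geo$regions),
    occurrences = data.frame(species = "virtual_species", lon = occ$lon,
                             lat = occ$lat, row.names = NULL),
    species = species,
    preset = preset,
    trueLabel = if (preset == "nested") "a" else preset
  ), class = "CNABundle")
}

#' Write a scenario bundle to disk in the pipeline's input formats
#'
#' Writes the stack directory, `native.geojson` (status attribute
#' `"Native"`), `regions.geojson` (with `region_id` properties),
#' `occurrences.csv`, `checklist.csv`, and a ready-to-run `config.yaml`.
#'
#' @param bundle result of [makeScenario()].
#' @param dir output directory (created).
#' @param seed seed recorded in the config.
#' @return `dir`, invisibly.
#' @export
writeScenarioBundle <- function(bundle, dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeEnvStack(bundle$stack, file.path(dir, "stack"))
  writeFeaturesGeoJSON(list(list(polygon = bundle$native, status = "Native")),
                       file.path(dir, "native.geojson"))
  writeFeaturesGeoJSON(bundle$regions, file.path(dir, "regions.geojson"))
  utils::write.csv(bundle$occurrences, file.path(dir, "occurrences.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(species = "virtual_species",
                              region_id = bundle$checklist),
                   file.path(dir, "checklist.csv"), row.names = FALSE)
  yaml::write_yaml(list(
    stack_dir = file.path(dir, "stack"),
    native_geojson = file.path(dir, "native.geojson"),
    regions_geojson = file.path(dir, "regions.geojson"),
    occurrences_csv = file.path(dir, "occurrences.csv"),
    checklist_csv = file.path(dir, "checklist.csv"),
    species = "virtual_species",
    output_dir = file.path(dir, "output"),
    seed = as.integer(seed)
  ), file.path(dir, "config.yaml"))
  invisible(dir)
}
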