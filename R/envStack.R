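#' Create an EnvStack from matrices
#'
#' @param layers named list of numeric matrices (row 1 = southern edge,
#'   column 1 = western edge); `NA` marks nodata.
#' @param origin numeric(2) lon/lat of the lower-left corner.
#' @param cellSize cell size in degrees (square cells).
#' @param standardization optional list with `mean` and `sd` vectors.
#' @return an [EnvStack-class] object.
#' @examples
#' s <- envStack(list(t1 = matrix(1:9, 3)), origin = c(0, 0), cellSize = 1)
#' s
#' @export
envStack <- function(layers, origin = c(-180, -90), cellSize, standardization = NULL) {
  new("EnvStack", layers = layers, origin = as.numeric(origin),
      cellSize = as.numeric(cellSize), standardization = standardization)
}

#' Standardise every layer of a stack
#'
#' Centres and scales each layer to zero mean and unit standard deviation over
#' its unmasked cells: `(val - mu) / sigma`, with the sample standard deviation
#' (n - 1 denominator). The parameters are attached to the returned stack so
#' the transformation can be replayed exactly with [applyStandardization()].
#'
#' @param stack an [EnvStack-class].
#' @return the standardised stack; retrieve the parameters with
#'   [standardization()].
#' @examples
#' s <- envStack(list(a = matrix(c(2, 4, 6), 1)), origin = c(0, 0), cellSize = 1)
#' standardization(standardizeStack(s))
#' @export
standardizeStack <- function(stack) {
  stopifnot(is(stack, "EnvStack"))
  nm <- layerNames(stack)
  mu <- sdv <- setNames(numeric(length(nm)), nm)
  for (i in seq_along(nm)) {
    v <- stack@layers[[i]]
    vv <- v[!is.na(v)]
    if (length(vv) == 0L) stop(sprintf("layer '%s' is entirely masked", nm[i]))
    if (length(unique(vv)) < 2L)
      stop(sprintf("constant layer '%s': standard deviation is zero", nm[i]))
    mu[i] <- mean(vv)
    sdv[i] <- stats::sd(vv)
  }
  params <- list(mean = mu, sd = sdv)
  applyStandardization(stack, params)
}

#' Apply stored standardisation parameters to a stack
#'
#' @param stack an [EnvStack-class] holding raw values.
#' @param params list with named numeric vectors `mean` and `sd` (one entry
#'   per layer).
#' @return an [EnvStack-class] with standardised values and the params attached.
#' @export
applyStandardization <- function(stack, params) {
  stopifnot(is(stack, "EnvStack"), is.list(params),
            all(c("mean", "sd") %in% names(params)))
  nm <- layerNames(stack)
  if (!all(nm %in% names(params$mean)) || !all(nm %in% names(params$sd)))
    stop("standardisation params must cover every layer")
  if (any(params$sd[nm] <= 0)) stop("standardisation sd must be > 0")
  out <- stack@layers
  for (i in seq_along(nm))
    out[[i]] <- (stack@layers[[i]] - params$mean[[nm[i]]]) / params$sd[[nm[i]]]
  envStack(out, origin = stack@origin, cellSize = stack@cellSize,
           standardization = list(mean = params$mean[nm], sd = params$sd[nm]))
}

#' Extract layer values at points
#'
#' Looks up the grid cell containing each point (half-open cell intervals,
#' lower-left closed; points exactly on the top/right raster edge fall in the
#' last cell) and returns one row per point whose cell is unmasked in every
#' layer. Points outside the raster extent are dropped with a warning; points
#' on nodata are dropped silently. The attribute `kept` gives the indices of
#' the surviving input points, in input order.
#'
#' @param stack an [EnvStack-class].
#' @param lon,lat numeric point coordinates (or `lon` a 2-column matrix).
#' @return numeric matrix (points x layers) with attribute `kept`.
#' @export
extractValues <- function(stack, lon, lat = NULL) {
  stopifnot(is(stack, "EnvStack"))
  if (is.null(lat)) { lat <- lon[, 2L]; lon <- lon[, 1L] }
  stopifnot(length(lon) == length(lat))
  d <- gridDim(stack)
  e <- extentOf(stack)
  col <- floor((lon - stack@origin[1L]) / stack@cellSize) + 1
  row <- floor((lat - stack@origin[2L]) / stack@cellSize) + 1
  # points exactly on the top/right edge belong to the last cell
  col[lon == e[["xmax"]]] <- d[["ncol"]]
  row[lat == e[["ymax"]]] <- d[["nrow"]]
  inb <- col >= 1 & col <= d[["ncol"]] & row >= 1 & row <= d[["nrow"]] &
    is.finite(lon) & is.finite(lat)
  if (any(!inb))
    warning(sprintf("%d point(s) outside raster extent dropped", sum(!inb)))
  k <- length(stack@layers)
  vals <- matrix(NA_real_, length(lon), k, dimnames = list(NULL, layerNames(stack)))
  idx <- cbind(row[inb], col[inb])
  for (j in seq_len(k)) vals[inb, j] <- stack@layers[[j]][idx]
  keep <- inb & !apply(is.na(vals), 1L, any)
  out <- vals[keep, , drop = FALSE]
  attr(out, "kept") <- which(keep)
  out
}

#' Grid specification for thinning and background sampling
#'
#' @param cellSize cell size in degrees.
#' @param origin numeric(2) anchor, default the (-180, -90) corner.
#' @return a list of class `GridSpec`.
#' @export
gridSpec <- function(cellSize, origin = c(-180, -90)) {
  stopifnot(cellSize > 0)
  structure(list(cellSize = cellSize, origin = as.numeric(origin)),
            class = "GridSpec")
}

#' Integer cell index of points on a grid
#'
#' Zero-based `(col, row)` indices: `col = floor((lon - origin_lon)/cellSize)`,
#' likewise for `row`. Cells are half-open, closed at the lower-left edge.
#'
#' @param lon,lat numeric coordinates.
#' @param grid a [gridSpec()].
#' @return integer matrix with columns `col`, `row`.
#' @examples
#' cellId(-179.875, -90, gridSpec(0.25))
#' @export
cellId <- function(lon, lat, grid) {
  stopifnot(inherits(grid, "GridSpec"), all(is.finite(lon)), all(is.finite(lat)))
  cbind(col = as.integer(floor((lon - grid$origin[1L]) / grid$cellSize)),
        row = as.integer(floor((lat - grid$origin[2L]) / grid$cellSize)))
}

# -- plain-text raster I/O ----------------------------------------------------

#' Read / write a single layer as an ESRI ASCII grid
#'
#' The ASCII grid format is a 6-line header (`NCOLS`, `NROWS`, `XLLCORNER`,
#' `YLLCORNER`, `CELLSIZE`, `NODATA_VALUE`) followed by rows of values from
#' the northern edge downward.
#'
#' @param path file path.
#' @return for the reader, a list with `values` (matrix, row 1 = south),
#'   `origin`, `cellSize`.
#' @name asciiGrid
NULL

#' @rdname asciiGrid
#' @export
readAsciiGrid <- function(path) {
  con <- file(path, "r"); on.exit(close(con))
  hdr <- list()
  for (i in 1:6) {
    ln <- strsplit(trimws(readLines(con, 1L)), "\\s+")[[1L]]
    hdr[[tolower(ln[1L])]] <- as.numeric(ln[2L])
  }
  vals <- scan(con, what = numeric(), quiet = TRUE)
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  if (length(vals) != nc * nr) stop("ASCII grid payload does not match header dimensions")
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA_real_
  m <- m[rev(seq_len(nr)), , drop = FALSE]   # file rows run north -> south
  list(values = m, origin = c(hdr$xllcorner, hdr$yllcorner), cellSize = hdr$cellsize)
}

#' @rdname asciiGrid
#' @param values numeric matrix (row 1 = southern edge).
#' @param origin numeric(2) lower-left corner.
#' @param cellSize degrees per cell.
#' @param nodata value written for `NA` cells.
#' @export
writeAsciiGrid <- function(values, path, origin, cellSize, nodata = -9999) {
  nr <- nrow(values); nc <- ncol(values)
  m <- values[rev(seq_len(nr)), , drop = FALSE]
  m[is.na(m)] <- nodata
  hdr <- c(sprintf("NCOLS %d", nc), sprintf("NROWS %d", nr),
           sprintf("XLLCORNER %.10g", origin[1L]), sprintf("YLLCORNER %.10g", origin[2L]),
           sprintf("CELLSIZE %.10g", cellSize), sprintf("NODATA_VALUE %g", nodata))
  body <- apply(m, 1L, function(r) paste(format(r, trim = TRUE, digits = 12), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read / write an environmental stack directory
#'
#' A stack on disk is a directory of per-layer ASCII grids plus a
#' `stack.json` sidecar listing the layer order and, when present, the
#' standardisation parameters.
#'
#' @param dir directory path.
#' @return for the reader, an [EnvStack-class].
#' @name stackIO
NULL

#' @rdname stackIO
#' @export
readEnvStack <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "stack.json"), simplifyVector = TRUE)
  layers <- list()
  for (nm in meta$layers) {
    g <- readAsciiGrid(file.path(dir, paste0(nm, ".asc")))
    layers[[nm]] <- g$values
  }
  std <- NULL
  if (!is.null(meta$standardization))
    std <- list(mean = unlist(meta$standardization$mean),
                sd = unlist(meta$standardization$sd))
  envStack(layers, origin = c(meta$origin[[1]], meta$origin[[2]]),
           cellSize = meta$cellSize, standardization = std)
}

#' @rdname stackIO
#' @param stack an [EnvStack-class].
#' @export
writeEnvStack <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in layerNames(stack))
    writeAsciiGrid(stack@layers[[nm]], file.path(dir, paste0(nm, ".asc")),
                   origin = stack@origin, cellSize = stack@cellSize)
  meta <- list(layers = layerNames(stack), origin = stack@origin,
               cellSize = stack@cellSize)
  if (!is.null(stack@standardization))
    meta$standardization <- list(mean = as.list(stack@standardization$mean),
                                 sd = as.list(stack@standardization$sd))
  jsonlite::write_json(meta, file.path(dir, "stack.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
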