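# Planar polygon primitives on lon/lat coordinates.
#
# A polygon is a list of rings; a ring is a 2-column numeric matrix of
# vertices (closing edge implicit). Multiple rings are treated as disjoint
# parts (even-odd containment); holes are not modelled. Coordinates must be
# in [-180, 180] x [-90, 90]; the antimeridian is not wrapped.

#' Construct an axis-aligned rectangular polygon
#'
#' @param xmin,xmax,ymin,ymax rectangle bounds in degrees.
#' @return a polygon (list of one ring).
#' @export
rectPolygon <- function(xmin, xmax, ymin, ymax) {
  stopifnot(xmax > xmin, ymax > ymin)
  list(cbind(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax)))
}

asPolygon <- function(x) {
  if (is.matrix(x)) list(x)
  else if (is.list(x) && all(vapply(x, is.matrix, logical(1)))) x
  else stop("cannot interpret object as a polygon (need a ring matrix or list of rings)")
}

ringClean <- function(ring) {
  # drop an explicit closing vertex
  n <- nrow(ring)
  if (n > 1L && all(ring[1L, ] == ring[n, ])) ring <- ring[-n, , drop = FALSE]
  if (nrow(ring) < 3L) stop("ring must have at least 3 distinct vertices")
  ring
}

#' Polygon area (planar, squared degrees)
#'
#' Shoelace area summed over rings; rings are treated as disjoint parts.
#'
#' @param polygon a polygon (list of ring matrices, or a single ring matrix).
#' @return numeric(1) area in squared degrees.
#' @export
polygonArea <- function(polygon) {
  rings <- asPolygon(polygon)
  sum(vapply(rings, function(r) {
    r <- ringClean(r)
    x <- r[, 1L]; y <- r[, 2L]
    xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
    abs(sum(x * yn - xn * y)) / 2
  }, numeric(1)))
}

# TRUE where point i lies on the boundary of the ring (within eps).
onRingBoundary <- function(px, py, ring, eps = 1e-12) {
  ring <- ringClean(ring)
  n <- nrow(ring)
  res <- rep(FALSE, length(px))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    x1 <- ring[i, 1L]; y1 <- ring[i, 2L]; x2 <- ring[j, 1L]; y2 <- ring[j, 2L]
    cross <- (px - x1) * (y2 - y1) - (py - y1) * (x2 - x1)
    seglen2 <- (x2 - x1)^2 + (y2 - y1)^2
    within <- (px >= pmin(x1, x2) - eps) & (px <= pmax(x1, x2) + eps) &
              (py >= pmin(y1, y2) - eps) & (py <= pmax(y1, y2) + eps)
    res <- res | (abs(cross) <= eps * (1 + sqrt(seglen2)) & within)
  }
  res
}

#' Point-in-polygon test (boundary inclusive)
#'
#' Even-odd ray casting over all rings; points exactly on a polygon boundary
#' count as inside.
#'
#' @param lon,lat numeric vectors of point coordinates.
#' @param polygon a polygon.
#' @return logical vector.
#' @export
pointInPolygon <- function(lon, lat, polygon) {
  stopifnot(length(lon) == length(lat))
  rings <- lapply(asPolygon(polygon), ringClean)
  inside <- rep(FALSE, length(lon))
  boundary <- rep(FALSE, length(lon))
  for (ring in rings) {
    n <- nrow(ring)
    boundary <- boundary | onRingBoundary(lon, lat, ring)
    xi <- ring[, 1L]; yi <- ring[, 2L]
    xj <- c(xi[n], xi[-n]); yj <- c(yi[n], yi[-n])
    for (k in seq_len(n)) {
      crosses <- (yi[k] > lat) != (yj[k] > lat)
      if (any(crosses)) {
        xint <- xi[k] + (lat - yi[k]) * (xj[k] - xi[k]) / (yj[k] - yi[k])
        flip <- crosses & (lon < xint)
        inside <- xor(inside, flip)
      }
    }
  }
  inside | boundary
}

segmentsIntersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2); d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  on <- function(a, b, c) {
    d(a, b, c) == 0 && min(a[1], b[1]) <= c[1] && c[1] <= max(a[1], b[1]) &&
      min(a[2], b[2]) <= c[2] && c[2] <= max(a[2], b[2])
  }
  on(p3, p4, p1) || on(p3, p4, p2) || on(p1, p2, p3) || on(p1, p2, p4)
}

#' Do two polygons intersect?
#'
#' True when any vertex of one polygon lies inside the other, or any pair of
#' edges crosses (boundary contact counts).
#'
#' @param a,b polygons.
#' @return logical(1)
#' @export
polygonsIntersect <- function(a, b) {
  a <- lapply(asPolygon(a), ringClean); b <- lapply(asPolygon(b), ringClean)
  va <- do.call(rbind, a); vb <- do.call(rbind, b)
  if (any(pointInPolygon(va[, 1L], va[, 2L], b))) return(TRUE)
  if (any(pointInPolygon(vb[, 1L], vb[, 2L], a))) return(TRUE)
  for (ra in a) {
    na <- nrow(ra)
    for (i in seq_len(na)) {
      p1 <- ra[i, ]; p2 <- ra[if (i == na) 1L else i + 1L, ]
      for (rb in b) {
        nb <- nrow(rb)
        for (j in seq_len(nb)) {
          p3 <- rb[j, ]; p4 <- rb[if (j == nb) 1L else j + 1L, ]
          if (segmentsIntersect(p1, p2, p3, p4)) return(TRUE)
        }
      }
    }
  }
  FALSE
}

isConvexRing <- function(ring) {
  ring <- ringClean(ring)
  n <- nrow(ring)
  sgn <- 0
  for (i in seq_len(n)) {
    p1 <- ring[i, ]; p2 <- ring[(i %% n) + 1L, ]; p3 <- ring[((i + 1L) %% n) + 1L, ]
    cr <- (p2[1] - p1[1]) * (p3[2] - p2[2]) - (p2[2] - p1[2]) * (p3[1] - p2[1])
    if (cr != 0) {
      s <- sign(cr)
      if (sgn == 0) sgn <- s else if (s != sgn) return(FALSE)
    }
  }
  TRUE
}

# Sutherland-Hodgman clip of a subject ring against a convex clip ring.
convexClipRing <- function(subject, clip) {
  subject <- ringClean(subject); clip <- ringClean(clip)
  # ensure counter-clockwise clip ring
  x <- clip[, 1L]; y <- clip[, 2L]
  if (sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y) < 0) clip <- clip[rev(seq_len(nrow(clip))), ]
  out <- subject
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (nrow(out) == 0L) break
    a <- clip[i, ]; b <- clip[(i %% nc) + 1L, ]
    inp <- out; out <- matrix(numeric(0), 0, 2)
    np <- nrow(inp)
    insideHalf <- function(p) (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1]) >= 0
    for (j in seq_len(np)) {
      cur <- inp[j, ]; prv <- inp[if (j == 1L) np else j - 1L, ]
      ci <- insideHalf(cur); pi <- insideHalf(prv)
      if (ci != pi) {
        # intersection of segment prv-cur with line a-b
        dx1 <- cur[1] - prv[1]; dy1 <- cur[2] - prv[2]
        dx2 <- b[1] - a[1]; dy2 <- b[2] - a[2]
        den <- dx1 * dy2 - dy1 * dx2
        t <- ((a[1] - prv[1]) * dy2 - (a[2] - prv[2]) * dx2) / den
        out <- rbind(out, prv + t * c(dx1, dy1))
      }
      if (ci) out <- rbind(out, cur)
    }
  }
  out
}

#' Area of intersection of two polygons
#'
#' Exact Sutherland-Hodgman clipping when the second polygon's (single) ring
#' is convex; otherwise a deterministic grid-sampling estimate over the
#' intersection of the bounding boxes.
#'
#' @param a,b polygons; `b` is the clip polygon.
#' @param gridN grid resolution per axis for the sampling fallback.
#' @return numeric(1) area in squared degrees.
#' @export
polygonIntersectionArea <- function(a, b, gridN = 256L) {
  a <- asPolygon(a); b <- asPolygon(b)
  if (length(b) == 1L && isConvexRing(b[[1L]])) {
    return(sum(vapply(a, function(r) {
      cl <- convexClipRing(r, b[[1L]])
      if (nrow(cl) < 3L) 0 else polygonArea(list(cl))
    }, numeric(1))))
  }
  bba <- polygonBBox(a); bbb <- polygonBBox(b)
  xmin <- max(bba[1L], bbb[1L]); xmax <- min(bba[2L], bbb[2L])
  ymin <- max(bba[3L], bbb[3L]); ymax <- min(bba[4L], bbb[4L])
  if (xmin >= xmax || ymin >= ymax) return(0)
  xs <- seq(xmin, xmax, length.out = gridN + 1L); xs <- (xs[-1L] + xs[-length(xs)]) / 2
  ys <- seq(ymin, ymax, length.out = gridN + 1L); ys <- (ys[-1L] + ys[-length(ys)]) / 2
  g <- expand.grid(x = xs, y = ys)
  inA <- pointInPolygon(g$x, g$y, a)
  hit <- inA
  hit[inA] <- pointInPolygon(g$x[inA], g$y[inA], b)
  cellArea <- (xmax - xmin) * (ymax - ymin) / (gridN^2)
  sum(hit) * cellArea
}

polygonBBox <- function(polygon) {
  v <- do.call(rbind, asPolygon(polygon))
  c(min(v[, 1L]), max(v[, 1L]), min(v[, 2L]), max(v[, 2L]))
}

# Repair degenerate rings: drop consecutive duplicate vertices. Returns the
# polygon or errors when a ring is unrepairable.
repairPolygon <- function(polygon) {
  rings <- asPolygon(polygon)
  lapply(rings, function(r) {
    r <- ringClean(r)
    keep <- c(TRUE, rowSums(abs(diff(r))) > 0)
    r <- r[keep, , drop = FALSE]
    if (nrow(r) < 3L) stop("unrepairable geometry: ring collapses to < 3 vertices")
    r
  })
}
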