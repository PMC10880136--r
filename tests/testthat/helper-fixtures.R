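# Shared fixtures: a tiny deterministic stack and polygon helpers.

# 8 x 8 two-layer stack on [0,2] x [0,2] (cellSize 0.25) with linear fields;
# optionally poke NA holes
tinyStack <- function(nodata = FALSE) {
  xs <- matrix(rep(seq_len(8), each = 8), 8, 8)   # varies by column (lon)
  ys <- matrix(rep(seq_len(8), 8), 8, 8)          # varies by row (lat)
  a <- xs + 0.1 * ys
  b <- ys - 0.05 * xs
  if (nodata) { a[3, 4] <- NA; b[3, 4] <- NA }
  envStack(list(alpha = a, beta = b), origin = c(0, 0), cellSize = 0.25)
}

# a random simple (possibly concave) polygon around a center: sorted random
# angles with random radii
randomPolygon <- function(nVertices = 8, center = c(0, 0), scale = 1) {
  ang <- sort(stats::runif(nVertices, 0, 2 * pi))
  r <- stats::runif(nVertices, 0.3, 1) * scale
  cbind(center[1] + r * cos(ang), center[2] + r * sin(ang))
}
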