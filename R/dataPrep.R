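# Occurrence thinning, native-range filtering, range-map -> checklist
# conversion, and biogeographical classification of records.

#' Thin occurrence records to one per grid cell
#'
#' Keeps exactly one record per occupied thinning-grid cell (default grid:
#' 2.5 arc-minutes anchored at (-180, -90), matching the environmental
#' layers' resolution). The retained record is chosen uniformly at random
#' within each cell under `seed`, so upstream sort order cannot leak into
#' the result.
#'
#' @param records data.frame with numeric columns `lon` and `lat`.
#' @param grid a [gridSpec()]; default 2.5 arc-minutes.
#' @param seed integer seed (required).
#' @param species species name carried into the result.
#' @return an [OccurrenceSet-class] with status `"unclassified"`.
#' @export
thinRecords <- function(records, grid = gridSpec(2.5 / 60), seed, species = "species") {
  if (is.null(records) || nrow(records) == 0L) stop("no records to thin")
  stopifnot(all(c("lon", "lat") %in% names(records)))
  ids <- cellId(records$lon, records$lat, grid)
  key <- cellKey(ids[, "col"], ids[, "row"])
  groups <- split(seq_len(nrow(records)), key)
  keep <- withSeed(stageSeed(seed, "thin"), {
    vapply(groups, function(ix) if (length(ix) == 1L) ix else ix[sample.int(length(ix), 1L)],
           integer(1))
  })
  keep <- sort(keep)
  new("OccurrenceSet", species = species,
      data = data.frame(lon = records$lon[keep], lat = records$lat[keep],
                        status = "unclassified", region_id = NA_character_,
                        stringsAsFactors = FALSE),
      thinned = TRUE)
}

#' Filter a range map down to its native features
#'
#' Drops features whose biogeographical status is `Introduced` or `Unknown`,
#' returning the polygons of the remaining (native) features. An empty result
#' signals that the species has no usable native range.
#'
#' @param rangeMap list of features, each a list with elements `polygon` and
#'   `status` (see [readFeaturesGeoJSON()]).
#' @return list of polygons (possibly empty).
#' @export
filterNativeRange <- function(rangeMap) {
  if (length(rangeMap) == 0L) stop("range map has no features")
  keep <- vapply(rangeMap, function(f) !(f$status %in% c("Introduced", "Unknown")),
                 logical(1))
  lapply(rangeMap[keep], `[[`, "polygon")
}

#' Convert an alien range map into a checklist of regions
#'
#' Overlays alien range polygons with administrative regions and returns the
#' ids of regions that overlap the range. With `minOverlapFraction = 0`
#' (default) any intersection counts; otherwise the intersection area divided
#' by the region area must reach the fraction.
#'
#' @param alienPolygons a polygon or list of polygons.
#' @param regions named list of region polygons (names are region ids).
#' @param minOverlapFraction minimum intersection-area / region-area.
#' @return character vector of region ids, sorted.
#' @export
rangemapToChecklist <- function(alienPolygons, regions, minOverlapFraction = 0) {
  if (length(regions) == 0L) stop("no regions supplied")
  if (is.matrix(alienPolygons) || (is.list(alienPolygons) && is.matrix(alienPolygons[[1L]])))
    alienPolygons <- list(asPolygon(alienPolygons))
  if (length(alienPolygons) == 0L) stop("no alien polygons supplied")
  alienPolygons <- lapply(alienPolygons, function(p) repairPolygon(asPolygon(p)))
  out <- character()
  for (rid in sort(names(regions))) {
    reg <- repairPolygon(asPolygon(regions[[rid]]))
    hit <- any(vapply(alienPolygons, function(a) polygonsIntersect(a, reg), logical(1)))
    if (!hit) next
    if (minOverlapFraction > 0) {
      inter <- sum(vapply(alienPolygons, function(a) polygonIntersectionArea(a, reg),
                          numeric(1)))
      if (inter / polygonArea(reg) < minOverlapFraction) next
    }
    out <- c(out, rid)
  }
  sort(out)
}

#' Classify thinned records as native, alien, or discarded
#'
#' A record inside the native range polygons is `native`; a record inside a
#' checklist region (and not in the native range — native takes precedence
#' when geometries overlap) is `alien`, tagged with that region's id; all
#' other records are `discarded`. Containment is boundary-inclusive; a record
#' on the shared boundary of two alien regions goes to the lexicographically
#' smaller region id.
#'
#' @param occ a thinned [OccurrenceSet-class].
#' @param nativePolygons list of polygons (may be empty).
#' @param alienRegions named list of region polygons restricted to the
#'   species' checklist.
#' @return the [OccurrenceSet-class] with statuses and region ids filled in.
#' @export
classifyRecords <- function(occ, nativePolygons, alienRegions) {
  stopifnot(is(occ, "OccurrenceSet"))
  if (!occ@thinned) warning("classifying an unthinned occurrence set")
  d <- occ@data
  n <- nrow(d)
  status <- rep("discarded", n)
  region <- rep(NA_character_, n)
  if (length(nativePolygons)) {
    inNative <- rep(FALSE, n)
    for (p in nativePolygons)
      inNative <- inNative | pointInPolygon(d$lon, d$lat, p)
    status[inNative] <- "native"
  }
  for (rid in sort(names(alienRegions))) {
    cand <- status == "discarded"
    if (!any(cand)) break
    hit <- cand
    hit[cand] <- pointInPolygon(d$lon[cand], d$lat[cand], alienRegions[[rid]])
    status[hit] <- "alien"
    region[hit] <- rid
  }
  d$status <- status
  d$region_id <- region
  initialize(occ, data = d)
}
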