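# Tabular and GeoJSON ingestion. Occurrence CSVs accept the Darwin-Core
# column names used by GBIF exports as aliases.

#' Read occurrence records from CSV
#'
#' Expects columns `species`, `decimalLongitude`, `decimalLatitude`
#' (Darwin-Core) or the aliases `lon`/`longitude`, `lat`/`latitude`.
#'
#' @param path CSV file path.
#' @param species optional species name to filter on.
#' @return data.frame with columns `species`, `lon`, `lat`.
#' @export
readOccurrences <- function(path, species = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  pick <- function(cands) {
    hit <- intersect(cands, names(d))
    if (length(hit) == 0L)
      stop(sprintf("occurrence file lacks any of: %s", paste(cands, collapse = ", ")))
    d[[hit[1L]]]
  }
  out <- data.frame(
    species = if ("species" %in% names(d)) d$species else "species",
    lon = as.numeric(pick(c("lon", "decimalLongitude", "longitude", "x"))),
    lat = as.numeric(pick(c("lat", "decimalLatitude", "latitude", "y"))),
    stringsAsFactors = FALSE)
  if (!is.null(species)) out <- out[out$species == species, , drop = FALSE]
  out
}

#' Read an alien checklist from CSV
#'
#' @param path CSV with columns `species` and `region_id`.
#' @param species optional species filter.
#' @return character vector of region ids.
#' @export
readChecklist <- function(path, species = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("species", "region_id") %in% names(d)))
  if (!is.null(species)) d <- d[d$species == species, , drop = FALSE]
  sort(unique(as.character(d$region_id)))
}

# Convert GeoJSON Polygon/MultiPolygon coordinate arrays into the package's
# ring-list representation.
geojsonGeomToPolygon <- function(geom) {
  ringsOf <- function(coords) lapply(coords, function(ring) {
    m <- do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
    m
  })
  if (geom$type == "Polygon") ringsOf(geom$coordinates)
  else if (geom$type == "MultiPolygon")
    do.call(c, lapply(geom$coordinates, ringsOf))
  else stop(sprintf("unsupported geometry type '%s'", geom$type))
}

#' Read polygon features from GeoJSON
#'
#' Reads a FeatureCollection of Polygon/MultiPolygon features. Each feature
#' becomes a list with `polygon` (list of rings), `status` (taken from
#' `statusField`, default `"legend"`, `NA` when absent), and `region_id`
#' (from the `region_id` or `id` property when present).
#'
#' @param path GeoJSON file.
#' @param statusField property holding the biogeographical status.
#' @return list of features.
#' @export
readFeaturesGeoJSON <- function(path, statusField = "legend") {
  g <- jsonlite::read_json(path)
  feats <- if (identical(g$type, "FeatureCollection")) g$features else list(g)
  lapply(feats, function(f) {
    props <- f$properties %||% list()
    list(polygon = geojsonGeomToPolygon(f$geometry),
         status = as.character(props[[statusField]] %||% NA_character_),
         region_id = as.character(props[["region_id"]] %||% props[["id"]] %||% NA_character_))
  })
}

#' Read a region set from GeoJSON
#'
#' @param path GeoJSON FeatureCollection whose features carry a `region_id`
#'   (or `id`) property.
#' @return named list of polygons.
#' @export
readRegionsGeoJSON <- function(path) {
  feats <- readFeaturesGeoJSON(path)
  ids <- vapply(feats, `[[`, character(1), "region_id")
  if (any(is.na(ids))) stop("every region feature needs a region_id property")
  if (anyDuplicated(ids)) stop("region ids must be unique")
  setNames(lapply(feats, `[[`, "polygon"), ids)
}

#' Write polygon features to GeoJSON
#'
#' @param features list of lists with `polygon` plus optional `status` and
#'   `region_id` entries, or a named list of polygons (names become region ids).
#' @param path output file.
#' @export
writeFeaturesGeoJSON <- function(features, path) {
  if (!is.null(names(features)) && all(nzchar(names(features))) &&
      all(vapply(features, function(f) is.null(f$polygon), logical(1))))
    features <- mapply(function(p, id) list(polygon = asPolygon(p), region_id = id),
                       features, names(features), SIMPLIFY = FALSE)
  toCoords <- function(polygon) lapply(polygon, function(ring) {
    ring <- rbind(ring, ring[1L, ])    # GeoJSON rings are closed
    lapply(seq_len(nrow(ring)), function(i) c(ring[i, 1L], ring[i, 2L]))
  })
  fl <- lapply(features, function(f) {
    props <- list()
    if (!is.null(f$status) && !is.na(f$status)) props$legend <- f$status
    if (!is.null(f$region_id) && !is.na(f$region_id)) props$region_id <- f$region_id
    list(type = "Feature",
         properties = props,
         geometry = list(type = "Polygon", coordinates = toCoords(asPolygon(f$polygon))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = unname(fl)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
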