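# End-to-end orchestration: configuration handling, the prepare and run
# stages over on-disk inputs, an in-memory variant for simulated bundles,
# and the simulate convenience wrapper.

cnaDefaults <- function() {
  list(
    seed = 1L,
    n_reps = 10L,
    thinning_cell = 2.5 / 60,
    background_cell = 0.25,
    background_origin = c(-180, -90),
    selection_background_n = 10000L,
    correlation_threshold = 0.7,
    contribution_threshold = 5,
    rise_threshold = 0.95,
    max_fraction = 0.5,
    tail_slope_max = 0.01,
    headroom_margin = 0.05,
    status_field = "legend",
    include_alien_occurrences = FALSE,
    write_plots = TRUE
  )
}

#' Load and complete a run configuration
#'
#' @param config a YAML file path or a named list. Required fields for file
#'   based runs: `stack_dir`, `native_geojson`, `regions_geojson`,
#'   `occurrences_csv`, `checklist_csv`, `species`, `output_dir`. All
#'   analysis parameters (seed, thresholds, repetition count, grid sizes)
#'   have package defaults that the file can override.
#' @return the completed configuration list.
#' @export
cnaConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  out <- utils::modifyList(cnaDefaults(), config)
  out$seed <- as.integer(out$seed)
  out
}

# uniform-with-replacement sample of stack cells inside the native range,
# used as the background for the importance estimator
selectionBackground <- function(stack, polygons, n, seed) {
  cells <- do.call(rbind, lapply(polygons, function(p) cellsInPolygon(stack, p)))
  cells <- unique(cells)
  if (is.null(cells) || nrow(cells) == 0L)
    stop("native range contains no stack cells")
  withSeed(seed, {
    pick <- sample.int(nrow(cells), n, replace = TRUE)
    vals <- vapply(stack@layers, function(m) m[cbind(cells$row[pick], cells$col[pick])],
                   numeric(n))
    matrix(vals, nrow = n, dimnames = list(NULL, layerNames(stack)))
  })
}

#' Prepare stage: load, standardise, thin, and classify
#'
#' Reads the stack (standardising it if its sidecar carries no
#' standardisation parameters), the native range features (keeping
#' native-status polygons only), the region polygons restricted to the
#' species' checklist, and the occurrence records, which are thinned on the
#' thinning grid and classified as native / alien / discarded.
#'
#' @param config see [cnaConfig()].
#' @return list (class `CNAPrepared`) with `stack`, `nativePolygons`,
#'   `regions`, `occ` (classified [OccurrenceSet-class]), `config`.
#' @export
cnaPrepare <- function(config) {
  config <- cnaConfig(config)
  for (f in c("stack_dir", "native_geojson", "regions_geojson",
              "occurrences_csv", "checklist_csv", "species"))
    if (is.null(config[[f]])) stop(sprintf("config field missing: %s", f))
  stack <- readEnvStack(config$stack_dir)
  if (is.null(standardization(stack))) stack <- standardizeStack(stack)
  nativePolygons <- filterNativeRange(
    readFeaturesGeoJSON(config$native_geojson, statusField = config$status_field))
  allRegions <- readRegionsGeoJSON(config$regions_geojson)
  ids <- readChecklist(config$checklist_csv, species = config$species)
  missing <- setdiff(ids, names(allRegions))
  if (length(missing))
    stop(sprintf("checklist names unknown regions: %s", paste(missing, collapse = ", ")))
  regions <- allRegions[ids]
  records <- readOccurrences(config$occurrences_csv, species = config$species)
  occ <- thinRecords(records, grid = gridSpec(config$thinning_cell,
                                              config$background_origin),
                     seed = config$seed, species = config$species)
  occ <- classifyRecords(occ, nativePolygons, regions)
  structure(list(stack = stack, nativePolygons = nativePolygons,
                 regions = regions, occ = occ, config = config),
            class = "CNAPrepared")
}

#' Core analysis on prepared inputs
#'
#' Variable selection on the native records against a within-native-range
#' background sample, then the three accumulation curves (sharing one region
#' order per repetition), asymptote verdicts, and the outcome
#' classification.
#'
#' @param prepared result of [cnaPrepare()] or an equivalently shaped list.
#' @return list (class `CNAResults`) with `selection`, `curves` (native /
#'   alien / background), `verdicts`, `outcome`, `counts`, `foldPlan`,
#'   `config`.
#' @export
cnaAnalyze <- function(prepared) {
  config <- cnaConfig(prepared$config %||% list())
  stack <- prepared$stack
  occ <- prepared$occ
  regions <- prepared$regions
  d <- occurrenceData(occ)
  nat <- d[d$status == "native", , drop = FALSE]
  if (nrow(nat) == 0L) stop("no records classified as native")
  presence <- extractValues(stack, nat$lon, nat$lat)
  background <- selectionBackground(stack, prepared$nativePolygons,
                                    n = config$selection_background_n,
                                    seed = stageSeed(config$seed, "sel-bg"))
  selection <- selectVariables(presence, background,
                               correlationThreshold = config$correlation_threshold,
                               contributionThreshold = config$contribution_threshold)
  vars <- selection$kept
  nativeValues <- presence[, vars, drop = FALSE]
  alienByRegion <- list()
  for (rid in names(regions)) {
    rows <- d[d$status == "alien" & !is.na(d$region_id) & d$region_id == rid, ,
              drop = FALSE]
    alienByRegion[[rid]] <- if (nrow(rows) == 0L) {
      matrix(numeric(0), 0L, length(vars), dimnames = list(NULL, vars))
    } else {
      extractValues(stack, rows$lon, rows$lat)[, vars, drop = FALSE]
    }
  }
  natC <- nativeCurve(nativeValues, nReps = config$n_reps, seed = config$seed)
  aliC <- alienCurve(nativeValues, alienByRegion, nReps = config$n_reps,
                     seed = config$seed)
  bgC <- backgroundCurve(nativeValues, regions, stack, order = regionOrder(aliC),
                         grid = gridSpec(config$background_cell,
                                         config$background_origin),
                         seed = config$seed,
                         includeAlienOccurrences = config$include_alien_occurrences,
                         alienValuesByRegion = alienByRegion)
  verdicts <- list(
    native = detectAsymptote(natC, riseThreshold = config$rise_threshold,
                             maxFraction = config$max_fraction,
                             tailSlopeMax = config$tail_slope_max),
    alien = detectAsymptote(aliC, riseThreshold = config$rise_threshold,
                            maxFraction = config$max_fraction,
                            tailSlopeMax = config$tail_slope_max),
    background = detectAsymptote(bgC, riseThreshold = config$rise_threshold,
                                 maxFraction = config$max_fraction,
                                 tailSlopeMax = config$tail_slope_max))
  outcome <- classifyOutcome(verdicts$native, verdicts$alien, bgC, aliC,
                             headroomMargin = config$headroom_margin)
  structure(list(
    selection = selection,
    curves = list(native = natC, alien = aliC, background = bgC),
    verdicts = verdicts,
    outcome = outcome,
    counts = list(native = nrow(nativeValues),
                  alien = vapply(alienByRegion, nrow, integer(1)),
                  discarded = sum(d$status == "discarded")),
    foldPlan = makeFoldPlan(nrow(nativeValues)),
    config = config
  ), class = "CNAResults")
}

#' Run stage: prepare, analyse, and write all outputs
#'
#' Writes, under `output_dir`: `selection.json`, `curve_native.csv`,
#' `curve_alien.csv`, `curve_background.csv`, `outcome.json`, `curves.png`
#' (unless `write_plots: false`), and `manifest.json` (configuration hash,
#' record counts, fold plan, kept variables, per-repetition region orders).
#' Identical configuration and seed give identical outputs.
#'
#' @param config see [cnaConfig()].
#' @return the [cnaAnalyze()] results, invisibly.
#' @export
cnaRun <- function(config) {
  prepared <- cnaPrepare(config)
  config <- prepared$config
  if (is.null(config$output_dir)) stop("config field missing: output_dir")
  res <- cnaAnalyze(prepared)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$output_dir, f)
  writeSelectionReport(res$selection, out("selection.json"))
  writeCurveCSV(res$curves$native, out("curve_native.csv"))
  writeCurveCSV(res$curves$alien, out("curve_alien.csv"))
  writeCurveCSV(res$curves$background, out("curve_background.csv"))
  writeOutcomeReport(res$outcome, out("outcome.json"))
  if (isTRUE(config$write_plots))
    plotCurves(res$curves$native, res$curves$alien, res$curves$background,
               path = out("curves.png"))
  writeManifest(res, out("manifest.json"))
  invisible(res)
}

writeManifest <- function(res, path) {
  cfg <- res$config
  jsonlite::write_json(list(
    package = "cumniche",
    version = as.character(utils::packageVersion("cumniche")),
    config = cfg,
    config_hash = rlang::hash(cfg),
    seed = cfg$seed,
    counts = res$counts,
    fold_plan = list(rule = res$foldPlan@rule, sizes = res$foldPlan@sizes),
    variables_kept = res$selection$kept,
    region_order = res$curves$alien@regionOrder,
    scenario = res$outcome@scenario
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the analysis on an in-memory scenario bundle
#'
#' Thins and classifies the bundle's occurrences and runs [cnaAnalyze()]
#' without touching the filesystem. Convenience for simulation studies.
#'
#' @param bundle result of [makeScenario()].
#' @param ... configuration overrides (see [cnaConfig()]); the bundle itself
#'   carries no seed, so pass `seed` here to vary the analysis seed.
#' @return [cnaAnalyze()] results.
#' @export
runBundle <- function(bundle, ...) {
  config <- utils::modifyList(cnaDefaults(), list(...))
  occ <- thinRecords(bundle$occurrences,
                     grid = gridSpec(config$thinning_cell, config$background_origin),
                     seed = config$seed, species = bundle$occurrences$species[1L])
  occ <- classifyRecords(occ, list(bundle$native), bundle$regions)
  cnaAnalyze(structure(list(stack = bundle$stack,
                            nativePolygons = list(bundle$native),
                            regions = bundle$regions[bundle$checklist],
                            occ = occ, config = config),
                       class = "CNAPrepared"))
}

#' Simulate stage: write a ready-to-run synthetic study system
#'
#' Builds a [makeScenario()] bundle and writes it with
#' [writeScenarioBundle()], including a `config.yaml` that [cnaRun()] (or
#' the command line interface) can execute directly.
#'
#' @param preset scenario preset, see [makeScenario()].
#' @param seed integer seed.
#' @param dir output directory.
#' @return the config file path, invisibly.
#' @export
cnaSimulate <- function(preset, seed, dir) {
  bundle <- makeScenario(preset, seed = seed)
  writeScenarioBundle(bundle, dir, seed = seed)
  invisible(file.path(dir, "config.yaml"))
}
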