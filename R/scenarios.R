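#' @include AllClasses.R engine.R
NULL

#' Apply top-up irrigation to a weekly rain series
#'
#' Weeks whose rainfall is strictly below `threshold` receive `7 * rate` mm
#' (the daily top-up applied across the week); weeks at or above the
#' threshold are untouched. With `mode = "target"` the week is instead
#' topped *up to* `threshold` mm (an alternative reading of top-up rules;
#' the additive rule is the default).
#'
#' @param rain weekly rain, mm: vector of 52, or matrix `cells x 52`.
#' @param rate irrigation rate, mm/day (default 2.5).
#' @param threshold weekly rainfall threshold, mm (default 25); comparison is
#'   strict (`<`), so a 25 mm week receives nothing.
#' @param mode `"additive"` (default) or `"target"`.
#' @return Adjusted rain, same shape.
#' @examples
#' applyIrrigation(c(0, 20, 25, 40), rate = 2.5, threshold = 25)
#' # 17.5 37.5 25.0 40.0 (recycled over a 52-week series in real use)
#' @export
applyIrrigation <- function(rain, rate = 2.5, threshold = 25,
                            mode = c("additive", "target")) {
  mode <- match.arg(mode)
  if (rate < 0) stop("irrigation rate must be >= 0")
  if (any(rain < 0, na.rm = TRUE)) stop("negative weekly rain")
  dry <- !is.na(rain) & rain < threshold
  out <- rain
  if (mode == "additive") out[dry] <- rain[dry] + 7 * rate
  else out[dry] <- threshold
  out
}

#' Irrigate a weekly climate grid
#'
#' Returns a copy of `w` whose land-cell rain series have the top-up rule of
#' [applyIrrigation()] applied week by week.
#'
#' @param w a [WeeklyClimateGrid-class].
#' @param p a [ClimexParams-class]; supplies the irrigation rate/threshold.
#' @param mode passed to [applyIrrigation()].
#' @return A [WeeklyClimateGrid-class].
#' @export
irrigateWeekly <- function(w, p = climexParams(), mode = "additive") {
  rain <- w@rain
  land <- rep(w@mask, 52L)
  rain[land] <- applyIrrigation(rain[land], p@irrigationRate,
                                p@irrigationThreshold, mode)
  initialize(w, rain = rain)
}

#' Run irrigation scenario I
#'
#' The engine run after applying year-round top-up irrigation to every cell:
#' the risk surface where cropping is sustained by irrigation.
#'
#' @inheritParams runGrid
#' @param mode irrigation mode, see [applyIrrigation()].
#' @return A [ClimexRun-class].
#' @export
runScenarioI <- function(w, p = climexParams(), sp = soilParams(),
                         mode = "additive") {
  runGrid(irrigateWeekly(w, p, mode), p, sp)
}

#' Composite irrigation scenario II
#'
#' Cell-wise selection: the irrigated-run EI inside mapped irrigation areas
#' (mask = 1) and the rainfed EI elsewhere (mask = 0 or nodata).
#'
#' @param eiRain rainfed EI [GridLayer-class].
#' @param eiIrr irrigation-scenario-I EI [GridLayer-class].
#' @param mask 0/1 irrigation-area [GridLayer-class].
#' @return An EI [GridLayer-class].
#' @export
compositeScenarioII <- function(eiRain, eiIrr, mask) {
  .checkSameSpec(eiIrr@spec, eiRain@spec, "irrigated EI raster")
  .checkSameSpec(mask@spec, eiRain@spec, "irrigation mask")
  m <- mask@values
  irr <- !is.na(m) & m == 1
  v <- eiRain@values
  v[irr] <- eiIrr@values[irr]
  gridLayer(eiRain@spec, v)
}

#' Run a named suite of climate scenarios
#'
#' For each named climate input, runs the engine rainfed, under irrigation
#' scenario I, and (when an irrigation mask is supplied) composes the
#' scenario II EI surface. Future-climate projections enter simply as
#' additional named climate inputs. When `outDir` is given, the EI rasters
#' are written as ESRI ASCII grids together with a JSON manifest recording
#' the parameter values, scenario names and files, so any output can be
#' reproduced from the manifest alone.
#'
#' @param climates a named list of [MonthlyClimateGrid-class] (or
#'   [WeeklyClimateGrid-class]) objects, e.g.
#'   `list(current = ..., csiro2030 = ...)`.
#' @param p a [ClimexParams-class].
#' @param sp a [SoilParams-class].
#' @param mask optional 0/1 irrigation [GridLayer-class]; required if
#'   `scenarios` includes `"irrigationII"`.
#' @param scenarios subset of `c("rainfed", "irrigationI", "irrigationII")`.
#' @param outDir optional output directory.
#' @return A named list (one element per climate) of lists with elements
#'   `rainfed`, `irrigationI` ([ClimexRun-class]) and `irrigationII`
#'   (EI [GridLayer-class]), as requested.
#' @export
runSuite <- function(climates, p = climexParams(), sp = soilParams(),
                     mask = NULL,
                     scenarios = c("rainfed", "irrigationI", "irrigationII"),
                     outDir = NULL) {
  scenarios <- match.arg(scenarios, several.ok = TRUE)
  if (is.null(names(climates)) || any(!nzchar(names(climates))))
    stop("climates must be a named list")
  if ("irrigationII" %in% scenarios && is.null(mask))
    stop("irrigation scenario II requires an irrigation mask")
  out <- list()
  files <- character()
  for (nm in names(climates)) {
    cl <- climates[[nm]]
    w <- if (is(cl, "MonthlyClimateGrid")) monthlyToWeekly(cl) else cl
    res <- list()
    if (any(c("rainfed", "irrigationII") %in% scenarios))
      res$rainfed <- runGrid(w, p, sp)
    if (any(c("irrigationI", "irrigationII") %in% scenarios))
      res$irrigationI <- runScenarioI(w, p, sp)
    if ("irrigationII" %in% scenarios)
      res$irrigationII <- compositeScenarioII(
        res$rainfed@ei, res$irrigationI@ei, mask)
    if (!is.null(outDir)) {
      dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
      for (sc in intersect(scenarios, names(res))) {
        ei <- if (sc == "irrigationII") res[[sc]] else res[[sc]]@ei
        f <- file.path(outDir, sprintf("%s_%s_ei.asc", nm, sc))
        writeAsciiGrid(ei, f)
        files <- c(files, f)
      }
    }
    out[[nm]] <- res
  }
  if (!is.null(outDir)) {
    manifest <- list(
      package = "ecoclimex",
      version = as.character(utils::packageVersion("ecoclimex")),
      params = paramsAsList(p),
      soil = list(capacity = sp@capacity, evapCoeff = sp@evapCoeff,
                  smCap = sp@smCap, smInit = sp@smInit,
                  spinupYears = sp@spinupYears),
      climates = names(climates),
      scenarios = scenarios,
      files = files
    )
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}

#' Species parameters as a named list
#'
#' @param p a [ClimexParams-class].
#' @return Named list of the parameter values (rates as magnitudes).
#' @export
paramsAsList <- function(p) {
  nms <- .paramSlotNames()
  stats::setNames(lapply(nms, function(nm) slot(p, nm)), nms)
}
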