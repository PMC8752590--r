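#' @include AllClasses.R
NULL

.categoryLevels <- c("unsuitable", "marginal", "suitable", "optimal")

#' Suitability category labels
#'
#' The four EI classes, in increasing suitability: unsuitable (EI = 0),
#' marginal (0 < EI <= 10), suitable (10 < EI <= 30), optimal
#' (30 < EI <= 100).
#'
#' @return Character vector of the four labels.
#' @export
categoryLevels <- function() .categoryLevels

#' Classify an EI surface into suitability categories
#'
#' Classification uses the unrounded EI and half-open intervals: EI = 0 is
#' unsuitable, (0, 10] marginal, (10, 30] suitable, (30, 100] optimal.
#' Nodata cells stay `NA`.
#'
#' @param ei an EI [GridLayer-class] (values in [0, 100]), or a numeric
#'   vector/matrix of EI values.
#' @return For a [GridLayer-class] input: a [GridLayer-class] of integer
#'   codes 1-4 (see [categoryLevels()]); otherwise a factor with those
#'   levels.
#' @examples
#' classifyEI(c(0, 5, 10, 10.0001, 30.5))
#' @export
classifyEI <- function(ei) {
  codes <- function(v) {
    out <- rep(NA_real_, length(v))
    ok <- !is.na(v)
    if (any(ok & (v < 0 | v > 100)))
      stop("EI values must lie in [0, 100]")
    out[ok & v == 0] <- 1
    out[ok & v > 0 & v <= 10] <- 2
    out[ok & v > 10 & v <= 30] <- 3
    out[ok & v > 30] <- 4
    out
  }
  if (is(ei, "GridLayer"))
    return(gridLayer(ei@spec, matrix(codes(ei@values),
                                     ei@spec@nRows, ei@spec@nCols)))
  factor(.categoryLevels[codes(as.numeric(ei))], levels = .categoryLevels)
}

#' Area of a latitude-longitude grid cell
#'
#' Spherical-segment area of a `res x res` degree cell centred at latitude
#' `lat`: `R^2 * dlon * (sin(lat + res/2) - sin(lat - res/2))` with
#' `R = 6371` km. About 343 km2 for a 10-arc-minute cell at the equator,
#' shrinking with `cos(lat)` towards the poles.
#'
#' @param lat cell-centre latitude(s), degrees.
#' @param res cell size, degrees (default 1/6).
#' @return Cell area(s), km2.
#' @export
cellAreaKm2 <- function(lat, res = 1 / 6) {
  R <- 6371
  toRad <- pi / 180
  R^2 * (res * toRad) *
    (sin(pmin(90, lat + res / 2) * toRad) -
       sin(pmax(-90, lat - res / 2) * toRad))
}

#' Per-cell areas for a grid
#'
#' @param spec a [GridSpec-class].
#' @return Numeric matrix of cell areas (km2), constant along rows.
#' @export
gridCellAreas <- function(spec) {
  matrix(cellAreaKm2(cellLatitudes(spec), spec@resolution),
         spec@nRows, spec@nCols)
}

.resolveRegion <- function(layer, regionMask) {
  keep <- !is.na(layer@values)
  if (!is.null(regionMask)) {
    .checkSameSpec(regionMask@spec, layer@spec, "region mask")
    keep <- keep & !is.na(regionMask@values) & regionMask@values == 1
  }
  if (!any(keep)) stop("empty region: no cells selected")
  keep
}

#' Latitude-weighted area accounting by suitability category
#'
#' Sums spherical cell areas per category over the region (all valid cells,
#' or a 0/1 region mask), and the share of the region's total area in each
#' category. Shares sum to 100 over the region.
#'
#' @param cat a category [GridLayer-class] from [classifyEI()].
#' @param regionMask optional 0/1 [GridLayer-class].
#' @return A data.frame with columns `category`, `areaKm2`, `areaMkm2`
#'   (10^6 km2) and `sharePct`.
#' @export
areaByCategory <- function(cat, regionMask = NULL) {
  keep <- .resolveRegion(cat, regionMask)
  areas <- gridCellAreas(cat@spec)
  code <- factor(.categoryLevels[cat@values[keep]], levels = .categoryLevels)
  a <- as.numeric(tapply(areas[keep], code, sum, default = 0))
  data.frame(
    category = .categoryLevels,
    areaKm2 = a,
    areaMkm2 = a / 1e6,
    sharePct = 100 * a / sum(a)
  )
}

#' Scenario change table
#'
#' Per-category percent change in area between a baseline and a scenario
#' classification over one region: `100 * (A_scen - A_base) / A_base`. A
#' category absent from the baseline but present in the scenario has no
#' defined percent change and is reported as `NA`; absent from both, the
#' change is 0.
#'
#' @param baseline,scenario category [GridLayer-class] objects on one grid.
#' @param regionMask optional 0/1 [GridLayer-class].
#' @return A data.frame with columns `category`, `baselineKm2`,
#'   `scenarioKm2`, `changePct`.
#' @export
changeTable <- function(baseline, scenario, regionMask = NULL) {
  .checkSameSpec(scenario@spec, baseline@spec, "scenario grid")
  ab <- areaByCategory(baseline, regionMask)
  as_ <- areaByCategory(scenario, regionMask)
  chg <- ifelse(ab$areaKm2 > 0,
                100 * (as_$areaKm2 - ab$areaKm2) / ab$areaKm2,
                ifelse(as_$areaKm2 > 0, NA_real_, 0))
  data.frame(
    category = ab$category,
    baselineKm2 = ab$areaKm2,
    scenarioKm2 = as_$areaKm2,
    changePct = chg
  )
}

#' Potential co-occurrence area of two EI surfaces
#'
#' Total spherical area of cells where both surfaces exceed the EI
#' threshold (default 10, i.e. both in the suitable-to-optimal classes) —
#' the pest-host overlap statistic.
#'
#' @param eiA,eiB EI [GridLayer-class] objects on one grid.
#' @param threshold EI threshold, strict (`>`), default 10.
#' @param regionMask optional 0/1 [GridLayer-class].
#' @return Overlap area, km2.
#' @export
overlapArea <- function(eiA, eiB, threshold = 10, regionMask = NULL) {
  .checkSameSpec(eiB@spec, eiA@spec, "second EI grid")
  keep <- .resolveRegion(eiA, regionMask)
  both <- keep & !is.na(eiB@values) &
    eiA@values > threshold & eiB@values > threshold
  sum(gridCellAreas(eiA@spec)[both])
}

#' Occurrence-based model performance statistics
#'
#' Extracts the EI of the cell containing each occurrence record
#' (nearest-cell extraction), reports descriptive statistics, a 10-bin
#' histogram over [0, 100] with the fitted normal curve parameters, and the
#' proportion of records in suitable-to-optimal cells (EI > 10). Records on
#' nodata cells or off-grid are counted and excluded with a warning.
#'
#' @param ei an EI [GridLayer-class].
#' @param occ occurrence data.frame (`lon`, `lat`, `source`).
#' @return A list: `values` (per-record EI), `n`, `nExcluded`, `mean`,
#'   `median`, `sd`, `propAbove10`, `histogram` (data.frame `binStart`,
#'   `binEnd`, `count`), `normalCurve` (list `mean`, `sd`).
#' @export
performanceStats <- function(ei, occ) {
  occ <- validateOccurrences(occ)
  if (!nrow(occ)) stop("no occurrence records supplied")
  cells <- cellFromCoords(occ$lon, occ$lat, ei@spec)
  v <- rep(NA_real_, nrow(occ))
  on <- !is.na(cells$cell)
  v[on] <- ei@values[cells$cell[on]]
  excl <- sum(is.na(v))
  if (excl == nrow(occ)) stop("no occurrence record lies on a valid cell")
  if (excl > 0)
    warning(excl, " record(s) off-grid or on nodata cells excluded")
  v <- v[!is.na(v)]
  breaks <- seq(0, 100, by = 10)
  h <- hist(v, breaks = breaks, include.lowest = TRUE, right = TRUE,
            plot = FALSE)
  list(
    values = v, n = length(v), nExcluded = excl,
    mean = mean(v), median = stats::median(v), sd = stats::sd(v),
    propAbove10 = mean(v > 10),
    histogram = data.frame(binStart = breaks[-11], binEnd = breaks[-1],
                           count = h$counts),
    normalCurve = list(mean = mean(v), sd = stats::sd(v))
  )
}
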