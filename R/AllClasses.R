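#' @import methods
NULL

#' Grid geometry of a gridded climatology
#'
#' A `GridSpec` describes the geometry every layer of a run must share:
#' cell-centre registered, WGS84 longitude/latitude, row 1 at the northern
#' edge. `latOrigin`/`lonOrigin` are the *centre* of the top-left cell and
#' `resolution` the cell size in decimal degrees (default 10 arc-minutes,
#' 1/6 degree, the resolution of common global climatologies).
#'
#' @slot nRows,nCols integer, grid dimensions.
#' @slot latOrigin,lonOrigin numeric, centre of the top-left cell (degrees).
#' @slot resolution numeric, cell size in degrees.
#' @aliases GridSpec
#' @exportClass GridSpec
setClass("GridSpec",
  representation(
    nRows = "integer", nCols = "integer",
    latOrigin = "numeric", lonOrigin = "numeric",
    resolution = "numeric"
  ),
  prototype(
    nRows = 1L, nCols = 1L, latOrigin = 0, lonOrigin = 0, resolution = 1 / 6
  )
)

setValidity("GridSpec", function(object) {
  msg <- character()
  if (length(object@nRows) != 1L || is.na(object@nRows) || object@nRows < 1L)
    msg <- c(msg, "nRows must be a single integer >= 1")
  if (length(object@nCols) != 1L || is.na(object@nCols) || object@nCols < 1L)
    msg <- c(msg, "nCols must be a single integer >= 1")
  if (length(object@resolution) != 1L || !is.finite(object@resolution) ||
      object@resolution <= 0)
    msg <- c(msg, "resolution must be a single positive number")
  if (!is.finite(object@latOrigin) || abs(object@latOrigin) > 90)
    msg <- c(msg, "latOrigin must be a latitude in [-90, 90]")
  if (!is.finite(object@lonOrigin) || abs(object@lonOrigin) > 180)
    msg <- c(msg, "lonOrigin must be a longitude in [-180, 180]")
  if (length(msg)) msg else TRUE
})

#' Construct a GridSpec
#'
#' @param nRows,nCols grid dimensions.
#' @param latOrigin,lonOrigin centre of the top-left cell (degrees); row 1 is
#'   the northernmost row.
#' @param resolution cell size in degrees (default 1/6 degree = 10 arc-min).
#' @return A [GridSpec-class] object.
#' @examples
#' GridSpec(10, 10, latOrigin = 5, lonOrigin = 30)
#' @export
GridSpec <- function(nRows, nCols, latOrigin = 0, lonOrigin = 0,
                     resolution = 1 / 6) {
  new("GridSpec",
    nRows = as.integer(nRows), nCols = as.integer(nCols),
    latOrigin = as.numeric(latOrigin), lonOrigin = as.numeric(lonOrigin),
    resolution = as.numeric(resolution)
  )
}

#' A single gridded layer
#'
#' Carries one matrix of cell values (EI, a stress index, a mask, ...) on a
#' [GridSpec-class]. `NA` encodes nodata / sea.
#'
#' @slot spec the [GridSpec-class].
#' @slot values numeric matrix, `nRows x nCols`.
#' @aliases GridLayer
#' @exportClass GridLayer
setClass("GridLayer",
  representation(spec = "GridSpec", values = "matrix")
)

setValidity("GridLayer", function(object) {
  d <- dim(object@values)
  if (d[1] != object@spec@nRows || d[2] != object@spec@nCols)
    return("values matrix does not match the GridSpec dimensions")
  if (!is.numeric(object@values))
    return("values must be numeric")
  TRUE
})

#' Construct a GridLayer
#'
#' @param spec a [GridSpec-class].
#' @param values numeric matrix (`nRows x nCols`) or a single value recycled.
#' @return A [GridLayer-class].
#' @export
gridLayer <- function(spec, values) {
  if (!is.matrix(values))
    values <- matrix(as.numeric(values), spec@nRows, spec@nCols)
  storage.mode(values) <- "double"
  new("GridLayer", spec = spec, values = values)
}

#' Monthly gridded climatology
#'
#' Twelve monthly layers per variable: minimum and maximum temperature
#' (degrees C), precipitation (mm per month) and, optionally, relative
#' humidity at 09:00 and 15:00 (%, carried through but unused by the default
#' engine). `mask` flags land cells; sea/nodata cells hold `NA`.
#'
#' @slot spec the [GridSpec-class].
#' @slot tmin,tmax,prec numeric arrays `nRows x nCols x 12`.
#' @slot rh09,rh15 numeric arrays `nRows x nCols x 12`, or zero-length when
#'   humidity is absent.
#' @slot mask logical matrix, `TRUE` = land.
#' @aliases MonthlyClimateGrid
#' @exportClass MonthlyClimateGrid
setClass("MonthlyClimateGrid",
  representation(
    spec = "GridSpec",
    tmin = "array", tmax = "array", prec = "array",
    rh09 = "array", rh15 = "array",
    mask = "matrix"
  )
)

setValidity("MonthlyClimateGrid", function(object) {
  s <- object@spec
  want <- c(s@nRows, s@nCols, 12L)
  msg <- character()
  for (nm in c("tmin", "tmax", "prec")) {
    a <- slot(object, nm)
    if (!identical(dim(a), as.integer(want)))
      msg <- c(msg, sprintf("%s must be a %d x %d x 12 array", nm,
                            s@nRows, s@nCols))
  }
  for (nm in c("rh09", "rh15")) {
    a <- slot(object, nm)
    if (length(a) && !identical(dim(a), as.integer(want)))
      msg <- c(msg, sprintf("%s, when present, must be %d x %d x 12", nm,
                            s@nRows, s@nCols))
  }
  if (!identical(dim(object@mask), c(s@nRows, s@nCols)))
    msg <- c(msg, "mask must match the grid dimensions")
  if (length(msg)) return(msg)
  land <- which(object@mask)
  if (length(land)) {
    idx <- rep(land, times = 12L) +
      rep(0:11, each = length(land)) * (s@nRows * s@nCols)
    for (nm in c("tmin", "tmax", "prec")) {
      v <- slot(object, nm)[idx]
      if (any(!is.finite(v)))
        msg <- c(msg, sprintf("non-finite %s values on land cells", nm))
    }
    bad <- which(object@tmax < object@tmin, arr.ind = TRUE)
    if (nrow(bad)) {
      bad <- bad[object@mask[bad[, 1:2, drop = FALSE]], , drop = FALSE]
      if (nrow(bad))
        msg <- c(msg, sprintf(
          "tmax < tmin at land cell (row %d, col %d, month %d)",
          bad[1, 1], bad[1, 2], bad[1, 3]))
    }
    pr <- object@prec
    pr[!is.finite(pr)] <- 0
    if (any(pr < 0))
      msg <- c(msg, "negative precipitation")
  }
  if (length(msg)) msg else TRUE
})

#' Weekly gridded climate series
#'
#' The engine's native time step: 52 weeks of exactly 7 days (days 365-366
#' ignored). Temperatures in degrees C, rain in mm per week; `tavg` is
#' `(tmin + tmax) / 2` cell-wise by construction.
#'
#' @slot spec the [GridSpec-class].
#' @slot tmin,tmax,tavg,rain numeric arrays `nRows x nCols x 52`.
#' @slot mask logical matrix, `TRUE` = land.
#' @aliases WeeklyClimateGrid
#' @exportClass WeeklyClimateGrid
setClass("WeeklyClimateGrid",
  representation(
    spec = "GridSpec",
    tmin = "array", tmax = "array", tavg = "array", rain = "array",
    mask = "matrix"
  )
)

setValidity("WeeklyClimateGrid", function(object) {
  s <- object@spec
  want <- as.integer(c(s@nRows, s@nCols, 52L))
  msg <- character()
  for (nm in c("tmin", "tmax", "tavg", "rain"))
    if (!identical(dim(slot(object, nm)), want))
      msg <- c(msg, sprintf("%s must be %d x %d x 52", nm, s@nRows, s@nCols))
  if (!identical(dim(object@mask), c(s@nRows, s@nCols)))
    msg <- c(msg, "mask must match the grid dimensions")
  if (length(msg)) return(msg)
  dev <- abs(object@tavg - (object@tmin + object@tmax) / 2)
  if (any(dev > 1e-8, na.rm = TRUE))
    msg <- c(msg, "tavg must equal (tmin + tmax)/2 cell-wise")
  if (any(object@rain < 0, na.rm = TRUE))
    msg <- c(msg, "negative weekly rain")
  if (length(msg)) msg else TRUE
})

#' Species response parameters for the ecoclimatic engine
#'
#' The full species parameterisation: the temperature trapezoid DV0-DV3
#' (degrees C), the soil-moisture trapezoid SM0-SM3 (soil-moisture index
#' units, i.e. fractions of soil water holding capacity), the four stress
#' threshold/rate pairs, the annual degree-day requirement PDD, and the
#' irrigation top-up rule. Stress rates are stored as magnitudes (per week);
#' the direction of each stress (below or above its threshold) is encoded in
#' the engine, which avoids the sign conventions some parameter tables use
#' for cold and dry rates.
#'
#' Defaults are the fall armyworm profile: DV0=12, DV1=25, DV2=30, DV3=36;
#' SM0=0.15, SM1=0.8, SM2=1.5, SM3=2.0; cold stress below TTCS=8 degC at
#' 0.005/week on weekly tmin; heat stress above TTHS=39 degC at 0.0025/week
#' on weekly tmax; dry stress below SMDS=0.1 at 0.005/week; wet stress above
#' SMWS=2.0 at 0.01/week; PDD=400 degree-days above DV0; top-up irrigation of
#' 2.5 mm/day applied to weeks with rainfall below 25 mm.
#'
#' @slot DV0,DV1,DV2,DV3 temperature thresholds (degrees C).
#' @slot SM0,SM1,SM2,SM3 soil-moisture thresholds (index units).
#' @slot TTCS,TTHS cold/heat stress temperature thresholds (degrees C).
#' @slot THCS,THHS cold/heat stress accumulation rates (per week, magnitude).
#' @slot SMDS,SMWS dry/wet stress soil-moisture thresholds (index units).
#' @slot HDS,HWS dry/wet stress accumulation rates (per week, magnitude).
#' @slot PDD minimum annual degree-day sum above DV0 (degree-days).
#' @slot irrigationRate top-up irrigation (mm per day).
#' @slot irrigationThreshold weekly rainfall below which top-up applies (mm).
#' @aliases ClimexParams
#' @exportClass ClimexParams
setClass("ClimexParams",
  representation(
    DV0 = "numeric", DV1 = "numeric", DV2 = "numeric", DV3 = "numeric",
    SM0 = "numeric", SM1 = "numeric", SM2 = "numeric", SM3 = "numeric",
    TTCS = "numeric", THCS = "numeric",
    TTHS = "numeric", THHS = "numeric",
    SMDS = "numeric", HDS = "numeric",
    SMWS = "numeric", HWS = "numeric",
    PDD = "numeric",
    irrigationRate = "numeric", irrigationThreshold = "numeric"
  ),
  prototype(
    DV0 = 12, DV1 = 25, DV2 = 30, DV3 = 36,
    SM0 = 0.15, SM1 = 0.8, SM2 = 1.5, SM3 = 2.0,
    TTCS = 8, THCS = 0.005,
    TTHS = 39, THHS = 0.0025,
    SMDS = 0.1, HDS = 0.005,
    SMWS = 2.0, HWS = 0.01,
    PDD = 400,
    irrigationRate = 2.5, irrigationThreshold = 25
  )
)

setValidity("ClimexParams", function(object) {
  msg <- character()
  tv <- c(object@DV0, object@DV1, object@DV2, object@DV3)
  sv <- c(object@SM0, object@SM1, object@SM2, object@SM3)
  if (any(!is.finite(tv)) || is.unsorted(tv))
    msg <- c(msg, "temperature thresholds must satisfy DV0 <= DV1 <= DV2 <= DV3")
  if (any(!is.finite(sv)) || any(sv < 0) || is.unsorted(sv))
    msg <- c(msg, "soil-moisture thresholds must satisfy 0 <= SM0 <= SM1 <= SM2 <= SM3")
  rates <- c(object@THCS, object@THHS, object@HDS, object@HWS,
             object@irrigationRate)
  if (any(!is.finite(rates)) || any(rates < 0))
    msg <- c(msg, "stress and irrigation rates must be finite magnitudes >= 0")
  if (!is.finite(object@PDD) || object@PDD < 0)
    msg <- c(msg, "PDD must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Soil-moisture bucket parameters
#'
#' A single-bucket weekly water balance: the bucket holds `capacity` mm at a
#' soil-moisture index of 1; weekly evaporative demand is
#' `evapCoeff * max(0, tavg) * min(1, SM)` mm, i.e. proportional to
#' temperature and damped by moisture availability; the index is capped at
#' `smCap` (above the wet-stress threshold so run-off conditions can bind).
#' The annual cycle is spun up from `smInit` for `spinupYears` years before
#' the reported year.
#'
#' @slot capacity soil water holding capacity (mm), default 100.
#' @slot evapCoeff evaporation coefficient (mm per degC per week), default 1.
#' @slot smCap upper cap on the soil-moisture index, default 2.5.
#' @slot smInit initial soil-moisture index, default 0.5.
#' @slot spinupYears number of spin-up years, default 2.
#' @aliases SoilParams
#' @exportClass SoilParams
setClass("SoilParams",
  representation(
    capacity = "numeric", evapCoeff = "numeric",
    smCap = "numeric", smInit = "numeric", spinupYears = "integer"
  ),
  prototype(
    capacity = 100, evapCoeff = 1, smCap = 2.5, smInit = 0.5,
    spinupYears = 2L
  )
)

setValidity("SoilParams", function(object) {
  msg <- character()
  if (!is.finite(object@capacity) || object@capacity <= 0)
    msg <- c(msg, "capacity must be > 0")
  if (!is.finite(object@evapCoeff) || object@evapCoeff < 0)
    msg <- c(msg, "evapCoeff must be >= 0")
  if (!is.finite(object@smCap) || object@smCap <= 0)
    msg <- c(msg, "smCap must be > 0")
  if (!is.finite(object@smInit) || object@smInit < 0 ||
      object@smInit > object@smCap)
    msg <- c(msg, "smInit must lie in [0, smCap]")
  if (is.na(object@spinupYears) || object@spinupYears < 1L)
    msg <- c(msg, "spinupYears must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Per-location engine result
#'
#' Weekly temperature index, moisture index, growth index and soil moisture,
#' plus the annual summaries: growth index GI_A (0-100), the four annual
#' stresses (0-100), the composite stress index SI (0-1), the interaction
#' stress SX (fixed at 1 in this parameterisation), annual degree-days DD
#' above DV0, and the Ecoclimatic Index EI (0-100; forced to 0 when
#' DD < PDD).
#'
#' @slot ti,mi,giW,sm numeric vectors of length 52.
#' @slot giA,cs,hs,ds,ws,si,sx,dd,ei numeric scalars.
#' @aliases CellResult
#' @exportClass CellResult
setClass("CellResult",
  representation(
    ti = "numeric", mi = "numeric", giW = "numeric", sm = "numeric",
    giA = "numeric", cs = "numeric", hs = "numeric", ds = "numeric",
    ws = "numeric", si = "numeric", sx = "numeric", dd = "numeric",
    ei = "numeric"
  )
)

setValidity("CellResult", function(object) {
  msg <- character()
  for (nm in c("ti", "mi", "giW", "sm"))
    if (length(slot(object, nm)) != 52L)
      msg <- c(msg, sprintf("%s must have length 52", nm))
  inRange <- function(x, lo, hi) is.finite(x) && x >= lo && x <= hi
  for (nm in c("giA", "cs", "hs", "ds", "ws", "ei"))
    if (!inRange(slot(object, nm), 0, 100))
      msg <- c(msg, sprintf("%s must lie in [0, 100]", nm))
  for (nm in c("si", "sx"))
    if (!inRange(slot(object, nm), 0, 1))
      msg <- c(msg, sprintf("%s must lie in [0, 1]", nm))
  if (length(msg)) msg else TRUE
})

#' Gridded engine result
#'
#' The cell-wise maps produced by one engine run: Ecoclimatic Index, annual
#' growth index, maximum weekly growth index, and the four annual stresses.
#'
#' @slot ei,giA,giWMax,cs,hs,ds,ws [GridLayer-class] objects on one grid.
#' @aliases ClimexRun
#' @exportClass ClimexRun
setClass("ClimexRun",
  representation(
    ei = "GridLayer", giA = "GridLayer", giWMax = "GridLayer",
    cs = "GridLayer", hs = "GridLayer", ds = "GridLayer", ws = "GridLayer"
  )
)

setValidity("ClimexRun", function(object) {
  s <- object@ei@spec
  for (nm in c("giA", "giWMax", "cs", "hs", "ds", "ws")) {
    g <- slot(object, nm)@spec
    if (g@nRows != s@nRows || g@nCols != s@nCols)
      return("all layers of a ClimexRun must share one grid")
  }
  TRUE
})
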