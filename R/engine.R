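#' @include AllClasses.R params.R
NULL

# Piecewise-linear trapezoid on (a, b, c, d): 0 outside (a, d), 1 on [b, c],
# linear ramps between. The open-source standard for threshold-bounded
# growth responses; continuous everywhere thresholds are distinct.
.trapezoid <- function(x, a, b, c, d) {
  y <- numeric(length(x))
  y[is.na(x)] <- NA_real_
  up <- !is.na(x) & x > a & x < b
  y[up] <- (x[up] - a) / (b - a)
  flat <- !is.na(x) & x >= b & x <= c
  y[flat] <- 1
  down <- !is.na(x) & x > c & x < d
  y[down] <- (d - x[down]) / (d - c)
  y
}

#' Weekly temperature index
#'
#' Trapezoidal response of weekly population growth to mean temperature:
#' 0 at or below DV0 and at or above DV3, 1 on the optimal plateau
#' [DV1, DV2], linear ramps between.
#'
#' @param tavg weekly mean temperature(s), degC; any shape, vectorised.
#' @param p a [ClimexParams-class].
#' @return Values in [0, 1], same shape as `tavg`.
#' @examples
#' p <- climexParams()
#' temperatureIndex(c(12, 18.5, 27, 33, 36), p)  # 0, 0.5, 1, 0.5, 0
#' @export
temperatureIndex <- function(tavg, p) {
  out <- .trapezoid(as.numeric(tavg), p@DV0, p@DV1, p@DV2, p@DV3)
  if (!is.null(dim(tavg))) dim(out) <- dim(tavg)
  out
}

#' Weekly moisture index
#'
#' Trapezoidal response to the weekly soil-moisture index, bounded by
#' SM0..SM3 (analogous to [temperatureIndex()]).
#'
#' @param sm weekly soil-moisture index value(s); vectorised.
#' @param p a [ClimexParams-class].
#' @return Values in [0, 1], same shape as `sm`.
#' @export
moistureIndex <- function(sm, p) {
  out <- .trapezoid(as.numeric(sm), p@SM0, p@SM1, p@SM2, p@SM3)
  if (!is.null(dim(sm))) dim(out) <- dim(sm)
  out
}

#' Weekly soil-moisture series from a bucket water balance
#'
#' Iterates the single-bucket balance
#' `SM_w = clamp(SM_{w-1} + (rain_w - E_w) / capacity, 0, smCap)` with
#' evaporative demand `E_w = evapCoeff * max(0, tavg_w) * min(1, SM_{w-1})`
#' (mm/week). The annual cycle is run `spinupYears + 1` times from `smInit`
#' and the final year is returned, so the reported series is (numerically)
#' the periodic attractor of the annual forcing.
#'
#' @param rain weekly rain, mm: vector of 52 or matrix `cells x 52`.
#' @param tavg weekly mean temperature, degC, same shape as `rain`.
#' @param sp a [SoilParams-class].
#' @return Soil-moisture index series, same shape as the input.
#' @export
soilMoistureSeries <- function(rain, tavg, sp = soilParams()) {
  vec <- is.null(dim(rain))
  if (vec) { rain <- matrix(rain, 1L); tavg <- matrix(tavg, 1L) }
  stopifnot(ncol(rain) == 52L, identical(dim(rain), dim(tavg)))
  if (any(rain < 0, na.rm = TRUE)) stop("negative weekly rain")
  sm <- matrix(NA_real_, nrow(rain), 52L)
  state <- rep(sp@smInit, nrow(rain))
  demand <- sp@evapCoeff * pmax(tavg, 0)    # mm/week at full availability
  for (cycle in seq_len(sp@spinupYears + 1L)) {
    for (w in 1:52) {
      e <- demand[, w] * pmin(1, state)
      state <- state + (rain[, w] - e) / sp@capacity
      state <- pmin(pmax(state, 0), sp@smCap)
      sm[, w] <- state
    }
  }
  if (vec) sm[1L, ] else sm
}

#' Annual growth index
#'
#' `GI_A = 100 * mean(ti * mi)` over the 52 weeks: the annual potential for
#' population growth during favourable conditions, on a 0-100 scale.
#'
#' @param ti,mi weekly index series of length 52 (or matrices `cells x 52`).
#' @return GI_A in [0, 100] (vector if matrices supplied).
#' @export
annualGrowthIndex <- function(ti, mi) {
  if (is.null(dim(ti))) {
    if (length(ti) != 52L || length(mi) != 52L)
      stop("weekly index series must have length 52")
    return(100 * mean(ti * mi))
  }
  if (ncol(ti) != 52L || !identical(dim(ti), dim(mi)))
    stop("weekly index series must be cells x 52")
  100 * rowMeans(ti * mi)
}

#' Annual stress accumulation
#'
#' One stress accumulator: each week contributes
#' `rate * max(0, threshold - x)` (direction `"below"`) or
#' `rate * max(0, x - threshold)` (direction `"above"`); the annual stress is
#' `min(100, 100 * sum(increments))`. Applied four times per location: cold
#' stress on weekly tmin below TTCS, heat stress on weekly tmax above TTHS,
#' dry stress on weekly soil moisture below SMDS, wet stress on soil
#' moisture above SMWS.
#'
#' @param x weekly series of length 52 (or matrix `cells x 52`).
#' @param threshold stress threshold, in the units of `x`.
#' @param rate accumulation rate per week (magnitude, >= 0).
#' @param direction `"below"` or `"above"`.
#' @return Annual stress in [0, 100] (vector for matrix input).
#' @examples
#' tmin <- rep(8, 52); tmin[1] <- 6
#' stressAnnual(tmin, 8, 0.005, "below")  # 1.0
#' @export
stressAnnual <- function(x, threshold, rate, direction = c("below", "above")) {
  direction <- match.arg(direction)
  if (rate < 0) stop("rate must be a magnitude >= 0")
  exc <- if (direction == "below") pmax(threshold - x, 0)
         else pmax(x - threshold, 0)
  s <- if (is.null(dim(x))) {
    if (length(x) != 52L) stop("weekly series must have length 52")
    sum(exc)
  } else {
    if (ncol(x) != 52L) stop("weekly series must be cells x 52")
    rowSums(exc)
  }
  pmin(100, 100 * rate * s)
}

#' Composite annual stress index
#'
#' `SI = prod(1 - S_i / 100)` over the four annual stresses, in [0, 1]; any
#' stress reaching 100 forces SI = 0.
#'
#' @param cs,hs,ds,ws annual cold, heat, dry and wet stress, each in
#'   [0, 100]; vectorised.
#' @return SI in [0, 1].
#' @export
stressIndex <- function(cs, hs, ds, ws) {
  pmax(0, (1 - cs / 100) * (1 - hs / 100) * (1 - ds / 100) * (1 - ws / 100))
}

#' Annual degree-day sum above the base temperature
#'
#' `DD = sum(7 * max(0, tavg_w - DV0))` over the 52 weeks.
#'
#' @param tavg weekly mean temperatures (length 52, or matrix `cells x 52`).
#' @param DV0 base temperature, degC.
#' @return Annual degree-days (vector for matrix input).
#' @export
annualDegreeDays <- function(tavg, DV0) {
  dd <- 7 * pmax(tavg - DV0, 0)
  if (is.null(dim(tavg))) sum(dd) else rowSums(dd)
}

#' Ecoclimatic Index
#'
#' `EI = GI_A * SI * SX`, forced to 0 where the annual degree-day sum falls
#' short of the generation requirement (`dd < pdd`), clipped to [0, 100].
#' EI = 0 marks locations unsuitable for long-term persistence; 100 is
#' incubator-grade suitability.
#'
#' @param giA annual growth index in [0, 100]; vectorised.
#' @param si composite stress index in [0, 1].
#' @param sx interaction stress index in [0, 1] (1 = disabled).
#' @param dd annual degree-days above DV0.
#' @param pdd degree-day requirement per generation.
#' @return EI in [0, 100].
#' @export
ecoclimaticIndex <- function(giA, si, sx, dd, pdd) {
  ei <- giA * si * sx
  ei[dd < pdd] <- 0
  pmin(pmax(ei, 0), 100)
}

#' Run the engine for one location
#'
#' Composes the weekly pipeline for a single cell: soil-moisture series,
#' temperature/moisture/growth indices, the four annual stresses, the
#' degree-day sum, and EI. All weekly series are retained in the result for
#' inspection.
#'
#' @param tmin,tmax weekly temperature series of length 52, degC.
#' @param rain weekly rain series of length 52, mm.
#' @param p a [ClimexParams-class].
#' @param sp a [SoilParams-class].
#' @return A [CellResult-class].
#' @examples
#' p <- climexParams(); sp <- soilParams()
#' runLocation(rep(22, 52), rep(32, 52), rep(30, 52), p, sp)
#' @export
runLocation <- function(tmin, tmax, rain, p = climexParams(),
                        sp = soilParams()) {
  stopifnot(length(tmin) == 52L, length(tmax) == 52L, length(rain) == 52L)
  if (any(!is.finite(tmin)) || any(!is.finite(tmax)) || any(!is.finite(rain)))
    stop("non-finite weekly climate values")
  if (any(tmax < tmin)) stop("tmax < tmin in weekly series")
  tavg <- (tmin + tmax) / 2
  sm <- soilMoistureSeries(rain, tavg, sp)
  ti <- temperatureIndex(tavg, p)
  mi <- moistureIndex(sm, p)
  giW <- ti * mi
  giA <- annualGrowthIndex(ti, mi)
  cs <- stressAnnual(tmin, p@TTCS, p@THCS, "below")
  hs <- stressAnnual(tmax, p@TTHS, p@THHS, "above")
  ds <- stressAnnual(sm, p@SMDS, p@HDS, "below")
  ws <- stressAnnual(sm, p@SMWS, p@HWS, "above")
  si <- stressIndex(cs, hs, ds, ws)
  dd <- annualDegreeDays(tavg, p@DV0)
  ei <- ecoclimaticIndex(giA, si, 1, dd, p@PDD)
  new("CellResult",
    ti = ti, mi = mi, giW = giW, sm = sm,
    giA = giA, cs = cs, hs = hs, ds = ds, ws = ws,
    si = si, sx = 1, dd = dd, ei = ei
  )
}

# Vectorised core shared by runGrid/sensitivity: weekly matrices
# (cells x 52) in, annual vectors out.
.runCells <- function(tmin, tmax, rain, p, sp, sm = NULL) {
  tavg <- (tmin + tmax) / 2
  if (is.null(sm)) sm <- soilMoistureSeries(rain, tavg, sp)
  ti <- temperatureIndex(tavg, p)
  mi <- moistureIndex(sm, p)
  giW <- ti * mi
  giA <- 100 * rowMeans(giW)
  cs <- stressAnnual(tmin, p@TTCS, p@THCS, "below")
  hs <- stressAnnual(tmax, p@TTHS, p@THHS, "above")
  ds <- stressAnnual(sm, p@SMDS, p@HDS, "below")
  ws <- stressAnnual(sm, p@SMWS, p@HWS, "above")
  si <- stressIndex(cs, hs, ds, ws)
  dd <- annualDegreeDays(tavg, p@DV0)
  list(
    ei = ecoclimaticIndex(giA, si, 1, dd, p@PDD),
    giA = giA, giWMax = apply(giW, 1L, max),
    cs = cs, hs = hs, ds = ds, ws = ws, sm = sm
  )
}

# Land cells of a WeeklyClimateGrid as cells x 52 matrices.
.weeklyAsMatrices <- function(w) {
  land <- which(w@mask)
  nc <- w@spec@nRows * w@spec@nCols
  pick <- function(a) {
    m <- matrix(a, nrow = nc, ncol = 52L)
    m[land, , drop = FALSE]
  }
  list(land = land,
       tmin = pick(w@tmin), tmax = pick(w@tmax), rain = pick(w@rain))
}

#' Run the engine over a weekly climate grid
#'
#' Cell-wise application of [runLocation()] to every land cell (vectorised
#' internally); masked cells become nodata (`NA`) in every output layer.
#'
#' @param w a [WeeklyClimateGrid-class].
#' @param p a [ClimexParams-class].
#' @param sp a [SoilParams-class].
#' @return A [ClimexRun-class] holding EI, annual growth index, maximum
#'   weekly growth index, and the four annual stress layers.
#' @export
runGrid <- function(w, p = climexParams(), sp = soilParams()) {
  s <- w@spec
  mats <- .weeklyAsMatrices(w)
  res <- .runCells(mats$tmin, mats$tmax, mats$rain, p, sp)
  toLayer <- function(v) {
    m <- matrix(NA_real_, s@nRows, s@nCols)
    m[mats$land] <- v
    gridLayer(s, m)
  }
  new("ClimexRun",
    ei = toLayer(res$ei), giA = toLayer(res$giA),
    giWMax = toLayer(res$giWMax),
    cs = toLayer(res$cs), hs = toLayer(res$hs),
    ds = toLayer(res$ds), ws = toLayer(res$ws)
  )
}
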