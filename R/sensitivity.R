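#' @include AllClasses.R engine.R risk-analysis.R
NULL

.sensParams <- function() {
  c("DV0", "DV1", "DV2", "DV3", "SM0", "SM1", "SM2", "SM3",
    "TTCS", "THCS", "TTHS", "THHS", "SMDS", "HDS", "SMWS", "HWS", "PDD")
}

#' Default one-at-a-time perturbations
#'
#' Temperatures are perturbed by +/- 1 degC, soil-moisture thresholds by
#' +/- 0.05, stress rates by +/- 50% of their value, and PDD by +/- 10%.
#' All steps are overridable.
#'
#' @param p a [ClimexParams-class].
#' @return Named numeric vector of absolute perturbation half-widths.
#' @export
defaultDeltas <- function(p = climexParams()) {
  c(
    DV0 = 1, DV1 = 1, DV2 = 1, DV3 = 1, TTCS = 1, TTHS = 1,
    SM0 = 0.05, SM1 = 0.05, SM2 = 0.05, SM3 = 0.05,
    SMDS = 0.05, SMWS = 0.05,
    THCS = 0.5 * p@THCS, THHS = 0.5 * p@THHS,
    HDS = 0.5 * p@HDS, HWS = 0.5 * p@HWS,
    PDD = 0.1 * p@PDD
  )[.sensParams()]
}

.perturb <- function(p, name, delta) {
  args <- paramsAsList(p)
  args[[name]] <- args[[name]] + delta
  tryCatch(do.call(climexParams, args), error = function(e) NULL)
}

# Area (km2) with EI > 0 and per-category areas, for one parameter set.
.rangeAreas <- function(mats, spec, p, sp, keep, areas) {
  res <- .runCells(mats$tmin, mats$tmax, mats$rain, p, sp)
  ei <- rep(NA_real_, spec@nRows * spec@nCols)
  ei[mats$land] <- res$ei
  ei <- ei[keep]
  a <- areas[keep]
  cat <- classifyEI(ei)
  list(
    range = sum(a[ei > 0], na.rm = TRUE),
    byCat = as.numeric(tapply(a, cat, sum, default = 0))
  )
}

.pctChange <- function(new, base) {
  ifelse(base > 0, 100 * (new - base) / base, ifelse(new > 0, NA_real_, 0))
}

#' One-at-a-time parameter sensitivity
#'
#' Runs the engine with each parameter perturbed by +delta and -delta while
#' all others stay at baseline, and reports the percent change in the
#' potential range (area with EI > 0) relative to the baseline run, plus the
#' signed per-category area changes. Perturbations that violate the
#' parameter ordering invariants are skipped with a warning and reported as
#' `NA`. A baseline range of zero with a perturbed range of zero counts as a
#' 0% change; zero baseline with a nonzero perturbed range is `NA`
#' (undefined relative change).
#'
#' @param p baseline [ClimexParams-class].
#' @param climate a [WeeklyClimateGrid-class].
#' @param deltas named numeric vector of absolute half-widths (default
#'   [defaultDeltas()]); order of names does not affect results.
#' @param sp a [SoilParams-class].
#' @param regionMask optional 0/1 [GridLayer-class].
#' @return A data.frame with one row per parameter: `parameter`, `delta`,
#'   `rangePctPlus`, `rangePctMinus`, `rangePctMax` (max absolute range
#'   change), and signed category changes `unsuitablePct`, `marginalPct`,
#'   `suitablePct`, `optimalPct` for the direction with the larger absolute
#'   range change.
#' @export
oatSensitivity <- function(p, climate, deltas = defaultDeltas(p),
                           sp = soilParams(), regionMask = NULL) {
  mats <- .weeklyAsMatrices(climate)
  spec <- climate@spec
  landLayer <- gridLayer(spec, matrix(NA_real_, spec@nRows, spec@nCols))
  landLayer@values[mats$land] <- 1
  keep <- .resolveRegion(landLayer, regionMask)
  keep <- which(as.vector(keep))
  areas <- as.vector(gridCellAreas(spec))
  base <- .rangeAreas(mats, spec, p, sp, keep, areas)
  params <- intersect(.sensParams(), names(deltas))
  params <- .sensParams()[.sensParams() %in% params]  # canonical order
  rows <- lapply(params, function(nm) {
    d <- deltas[[nm]]
    out <- data.frame(
      parameter = nm, delta = d,
      rangePctPlus = NA_real_, rangePctMinus = NA_real_,
      rangePctMax = NA_real_,
      unsuitablePct = NA_real_, marginalPct = NA_real_,
      suitablePct = NA_real_, optimalPct = NA_real_
    )
    side <- list()
    for (sgn in c(1, -1)) {
      pp <- .perturb(p, nm, sgn * d)
      if (is.null(pp)) {
        warning("perturbation of ", nm, " by ", sgn * d,
                " violates parameter ordering; skipped")
        next
      }
      side[[as.character(sgn)]] <- .rangeAreas(mats, spec, pp, sp, keep, areas)
    }
    if (!is.null(side[["1"]]))
      out$rangePctPlus <- .pctChange(side[["1"]]$range, base$range)
    if (!is.null(side[["-1"]]))
      out$rangePctMinus <- .pctChange(side[["-1"]]$range, base$range)
    mags <- abs(c(out$rangePctPlus, out$rangePctMinus))
    if (any(is.finite(mags))) {
      out$rangePctMax <- max(mags, na.rm = TRUE)
      pickPlus <- isTRUE(mags[1] >= mags[2]) || !is.finite(mags[2])
      chosen <- if (pickPlus) side[["1"]] else side[["-1"]]
      cc <- .pctChange(chosen$byCat, base$byCat)
      out[, c("unsuitablePct", "marginalPct", "suitablePct",
              "optimalPct")] <- as.list(cc)
    }
    out
  })
  do.call(rbind, rows)
}

#' Default parameter uncertainty ranges
#'
#' Each parameter's range is its baseline value +/- the default
#' one-at-a-time half-width (see [defaultDeltas()]).
#'
#' @param p a [ClimexParams-class].
#' @return Named list of `c(lo, hi)` ranges.
#' @export
defaultUncertaintyRanges <- function(p = climexParams()) {
  d <- defaultDeltas(p)
  vals <- paramsAsList(p)
  out <- lapply(names(d), function(nm) vals[[nm]] + c(-1, 1) * d[[nm]])
  stats::setNames(out, names(d))
}

#' Proportional model agreement under sampled parameter uncertainty
#'
#' Draws `n` parameter sets with each listed parameter sampled independently
#' and uniformly from its range (unlisted parameters stay at baseline), runs
#' the engine for each, and reports per cell the percentage of sampled
#' models with EI > 0. With zero-width ranges (or `n = 1`) the map is binary
#' \{0, 100\} and matches the baseline suitability. Draws violating the
#' parameter ordering invariants are rejected and resampled (an error is
#' raised if the range bounds themselves cannot produce valid parameter
#' sets).
#'
#' @param p baseline [ClimexParams-class].
#' @param ranges named list of `c(lo, hi)` per parameter (default
#'   [defaultUncertaintyRanges()]).
#' @param n number of sampled parameter sets (>= 1).
#' @param seed integer seed.
#' @param climate a [WeeklyClimateGrid-class].
#' @param sp a [SoilParams-class].
#' @param regionMask optional 0/1 [GridLayer-class]; cells outside become
#'   nodata.
#' @return An agreement [GridLayer-class] in [0, 100] %.
#' @export
uncertaintyMap <- function(p, ranges = defaultUncertaintyRanges(p), n = 20,
                           seed = 1, climate, sp = soilParams(),
                           regionMask = NULL) {
  if (n < 1) stop("n must be >= 1")
  bad <- setdiff(names(ranges), .sensParams())
  if (length(bad)) stop("unknown parameters in ranges: ",
                        paste(bad, collapse = ", "))
  mats <- .weeklyAsMatrices(climate)
  spec <- climate@spec
  suitable <- matrix(0, length(mats$land), 1L)[, 1L]
  .withSeed(seed, {
    for (i in seq_len(n)) {
      pp <- NULL
      for (try in 1:100) {
        args <- paramsAsList(p)
        for (nm in names(ranges)) {
          r <- ranges[[nm]]
          args[[nm]] <- stats::runif(1, min(r), max(r))
        }
        pp <- tryCatch(do.call(climexParams, args), error = function(e) NULL)
        if (!is.null(pp)) break
      }
      if (is.null(pp))
        stop("uncertainty ranges cannot produce valid parameter orderings")
      res <- .runCells(mats$tmin, mats$tmax, mats$rain, pp, sp)
      suitable <- suitable + (res$ei > 0)
    }
  })
  m <- matrix(NA_real_, spec@nRows, spec@nCols)
  m[mats$land] <- 100 * suitable / n
  out <- gridLayer(spec, m)
  if (!is.null(regionMask)) {
    keep <- .resolveRegion(out, regionMask)
    v <- out@values
    v[!keep] <- NA_real_
    out <- gridLayer(spec, v)
  }
  out
}
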