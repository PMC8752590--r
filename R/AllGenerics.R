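#' @include AllClasses.R
NULL

#' Accessors for gridded objects
#'
#' `gridSpec()` returns the shared grid geometry, `landMask()` the logical
#' land mask, and `layerValues()` the numeric value matrix of a
#' [GridLayer-class].
#'
#' @param x a gridded object.
#' @return `gridSpec()` a [GridSpec-class]; `landMask()` a logical matrix;
#'   `layerValues()` a numeric matrix.
#' @name grid-accessors
NULL

#' @rdname grid-accessors
#' @export
setGeneric("gridSpec", function(x) standardGeneric("gridSpec"))

#' @rdname grid-accessors
#' @export
setGeneric("landMask", function(x) standardGeneric("landMask"))

#' @rdname grid-accessors
#' @export
setGeneric("layerValues", function(x) standardGeneric("layerValues"))

#' @rdname grid-accessors
setMethod("gridSpec", "GridLayer", function(x) x@spec)
#' @rdname grid-accessors
setMethod("gridSpec", "MonthlyClimateGrid", function(x) x@spec)
#' @rdname grid-accessors
setMethod("gridSpec", "WeeklyClimateGrid", function(x) x@spec)
#' @rdname grid-accessors
setMethod("gridSpec", "ClimexRun", function(x) x@ei@spec)

#' @rdname grid-accessors
setMethod("landMask", "MonthlyClimateGrid", function(x) x@mask)
#' @rdname grid-accessors
setMethod("landMask", "WeeklyClimateGrid", function(x) x@mask)
#' @rdname grid-accessors
setMethod("landMask", "GridLayer", function(x) !is.na(x@values))

#' @rdname grid-accessors
setMethod("layerValues", "GridLayer", function(x) x@values)

#' Cell-centre latitudes and longitudes
#'
#' @param spec a [GridSpec-class].
#' @return `cellLatitudes()`: numeric vector of row-centre latitudes (north to
#'   south); `cellLongitudes()`: column-centre longitudes (west to east).
#' @export
cellLatitudes <- function(spec) {
  spec@latOrigin - (seq_len(spec@nRows) - 1L) * spec@resolution
}

#' @rdname cellLatitudes
#' @export
cellLongitudes <- function(spec) {
  spec@lonOrigin + (seq_len(spec@nCols) - 1L) * spec@resolution
}

setMethod("show", "GridSpec", function(object) {
  cat(sprintf(
    "GridSpec: %d x %d cells, %.4f deg resolution, top-left centre (%.4f, %.4f)\n",
    object@nRows, object@nCols, object@resolution,
    object@latOrigin, object@lonOrigin))
})

setMethod("show", "GridLayer", function(object) {
  v <- object@values
  cat(sprintf("GridLayer on %d x %d grid (%d nodata cells)\n",
              object@spec@nRows, object@spec@nCols, sum(is.na(v))))
  if (any(!is.na(v)))
    cat(sprintf("  range: [%.4g, %.4g], mean %.4g\n",
                min(v, na.rm = TRUE), max(v, na.rm = TRUE),
                mean(v, na.rm = TRUE)))
})

setMethod("show", "MonthlyClimateGrid", function(object) {
  cat(sprintf(
    "MonthlyClimateGrid: %d x %d cells x 12 months, %d land cells%s\n",
    object@spec@nRows, object@spec@nCols, sum(object@mask),
    if (length(object@rh09)) ", with humidity" else ""))
})

setMethod("show", "WeeklyClimateGrid", function(object) {
  cat(sprintf("WeeklyClimateGrid: %d x %d cells x 52 weeks, %d land cells\n",
              object@spec@nRows, object@spec@nCols, sum(object@mask)))
})

setMethod("show", "ClimexParams", function(object) {
  cat("ClimexParams\n")
  cat(sprintf("  temperature DV0..DV3 (degC): %g, %g, %g, %g\n",
              object@DV0, object@DV1, object@DV2, object@DV3))
  cat(sprintf("  soil moisture SM0..SM3:      %g, %g, %g, %g\n",
              object@SM0, object@SM1, object@SM2, object@SM3))
  cat(sprintf("  cold stress: below %g degC at %g/week (weekly tmin)\n",
              object@TTCS, object@THCS))
  cat(sprintf("  heat stress: above %g degC at %g/week (weekly tmax)\n",
              object@TTHS, object@THHS))
  cat(sprintf("  dry stress:  below SM %g at %g/week\n",
              object@SMDS, object@HDS))
  cat(sprintf("  wet stress:  above SM %g at %g/week\n",
              object@SMWS, object@HWS))
  cat(sprintf("  degree-day requirement PDD: %g above DV0\n", object@PDD))
  cat(sprintf("  irrigation: %g mm/day when weekly rain < %g mm\n",
              object@irrigationRate, object@irrigationThreshold))
})

setMethod("show", "CellResult", function(object) {
  cat(sprintf(
    "CellResult: EI %.2f (GI_A %.2f, SI %.3f, SX %g, DD %.1f)\n",
    object@ei, object@giA, object@si, object@sx, object@dd))
  cat(sprintf("  stresses: cold %.2f, heat %.2f, dry %.2f, wet %.2f\n",
              object@cs, object@hs, object@ds, object@ws))
})

setMethod("show", "ClimexRun", function(object) {
  s <- gridSpec(object)
  ei <- object@ei@values
  cat(sprintf("ClimexRun on %d x %d grid\n", s@nRows, s@nCols))
  cat(sprintf("  EI: median %.2f, share EI > 0: %.1f%%\n",
              stats::median(ei, na.rm = TRUE),
              100 * mean(ei > 0, na.rm = TRUE)))
})

#' Extract a result layer from a ClimexRun
#'
#' @param x a [ClimexRun-class].
#' @param name one of `"ei"`, `"giA"`, `"giWMax"`, `"cs"`, `"hs"`, `"ds"`,
#'   `"ws"`.
#' @return The corresponding [GridLayer-class].
#' @export
resultLayer <- function(x, name = c("ei", "giA", "giWMax", "cs", "hs",
                                    "ds", "ws")) {
  name <- match.arg(name)
  slot(x, name)
}
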