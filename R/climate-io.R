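#' @include AllClasses.R grid-io.R
NULL

#' Construct a monthly climate grid
#'
#' @param spec a [GridSpec-class].
#' @param tmin,tmax,prec numeric arrays `nRows x nCols x 12` (degC, degC,
#'   mm/month).
#' @param rh09,rh15 optional relative-humidity arrays (%).
#' @param mask optional logical land mask; defaults to cells where all three
#'   mandatory variables are finite in every month.
#' @return A validated [MonthlyClimateGrid-class].
#' @export
monthlyClimateGrid <- function(spec, tmin, tmax, prec,
                               rh09 = NULL, rh15 = NULL, mask = NULL) {
  shape <- function(x) {
    x <- as.array(x)
    if (length(dim(x)) != 3L) stop("climate variables must be 3-d arrays")
    storage.mode(x) <- "double"
    x
  }
  tmin <- shape(tmin); tmax <- shape(tmax); prec <- shape(prec)
  if (is.null(mask))
    mask <- apply(is.finite(tmin) & is.finite(tmax) & is.finite(prec),
                  c(1, 2), all)
  empty <- array(numeric(0), c(0L, 0L, 0L))
  new("MonthlyClimateGrid",
    spec = spec, tmin = tmin, tmax = tmax, prec = prec,
    rh09 = if (is.null(rh09)) empty else shape(rh09),
    rh15 = if (is.null(rh15)) empty else shape(rh15),
    mask = mask
  )
}

#' Read a monthly climatology from raster stacks
#'
#' Each variable is a 12-band stack of ESRI ASCII grids (`prefix_01.asc` ...
#' `prefix_12.asc`, or a vector of 12 explicit paths). All stacks must share
#' one grid; land cells are those where tmin, tmax and prec are all valid,
#' and the result is validated (tmax >= tmin, prec >= 0, finite on land).
#'
#' @param tmin,tmax,prec stack prefix or 12 paths per variable.
#' @param rh09,rh15 optional humidity stacks.
#' @return A [MonthlyClimateGrid-class].
#' @export
readMonthlyClimate <- function(tmin, tmax, prec, rh09 = NULL, rh15 = NULL) {
  a <- .readStack(tmin)
  spec <- a$spec
  b <- .readStack(tmax, spec = spec)
  p <- .readStack(prec, spec = spec)
  r9 <- if (!is.null(rh09)) .readStack(rh09, spec = spec)$values
  r15 <- if (!is.null(rh15)) .readStack(rh15, spec = spec)$values
  monthlyClimateGrid(spec, a$values, b$values, p$values, r9, r15)
}

#' Write a monthly climatology as raster stacks
#'
#' @param m a [MonthlyClimateGrid-class].
#' @param tmin,tmax,prec output stack prefixes (files `prefix_01.asc` ...).
#' @param rh09,rh15 optional output prefixes for humidity.
#' @return Invisibly, the vector of files written.
#' @export
writeMonthlyClimate <- function(m, tmin, tmax, prec,
                                rh09 = NULL, rh15 = NULL) {
  s <- m@spec
  napply <- function(a) { a[rep(!m@mask, 12L)] <- NA_real_; a }
  files <- c(
    .writeStack(s, napply(m@tmin), tmin),
    .writeStack(s, napply(m@tmax), tmax),
    .writeStack(s, napply(m@prec), prec)
  )
  if (!is.null(rh09) && length(m@rh09))
    files <- c(files, .writeStack(s, napply(m@rh09), rh09))
  if (!is.null(rh15) && length(m@rh15))
    files <- c(files, .writeStack(s, napply(m@rh15), rh15))
  invisible(files)
}

.daysInMonth <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)

# Periodic linear interpolation from 12 mid-month anchors to the 52
# week-midpoint days of a 364-day working year. x: matrix (cells x 12).
# Returns cells x 52.
.interpMidMonth <- function(x, daysInMonth = .daysInMonth) {
  stopifnot(length(daysInMonth) == 12L)
  yearLen <- sum(daysInMonth)
  mid <- cumsum(daysInMonth) - daysInMonth / 2
  # wrap one anchor at each end for periodicity
  anchors <- c(mid[12] - yearLen, mid, mid[1] + yearLen)
  wk <- (seq_len(52L) - 1L) * 7 + 3.5
  idx <- findInterval(wk, anchors)          # interval [anchors[i], anchors[i+1])
  w <- (wk - anchors[idx]) / (anchors[idx + 1L] - anchors[idx])
  xe <- cbind(x[, 12L], x, x[, 1L])         # cells x 14
  x0 <- xe[, idx, drop = FALSE]
  x1 <- xe[, idx + 1L, drop = FALSE]
  x0 + sweep(x1 - x0, 2L, w, `*`)
}

#' Convert a monthly climatology to the weekly series the engine consumes
#'
#' Temperatures are linearly interpolated between mid-month anchor values,
#' evaluated at each week's mid-point day; the year is 52 weeks of exactly 7
#' days (days 365-366 are ignored). Monthly precipitation is first converted
#' to a daily rate (month total / days in month), interpolated the same way,
#' then multiplied by 7 to give mm per week. Constant monthly fields are
#' preserved exactly, and for smooth seasonal cycles the annual weekly rain
#' total stays within a few percent of the monthly annual total (the 364-day
#' working year and the interpolation account for the difference).
#'
#' @param m a [MonthlyClimateGrid-class].
#' @param daysInMonth month lengths used for the rate conversion and the
#'   anchor positions; default the standard non-leap calendar.
#' @return A [WeeklyClimateGrid-class].
#' @export
monthlyToWeekly <- function(m, daysInMonth = .daysInMonth) {
  validObject(m)
  s <- m@spec
  nc <- s@nRows * s@nCols
  flat <- function(a) matrix(a, nrow = nc, ncol = 12L)
  tminW <- .interpMidMonth(flat(m@tmin), daysInMonth)
  tmaxW <- .interpMidMonth(flat(m@tmax), daysInMonth)
  rateM <- sweep(flat(m@prec), 2L, daysInMonth, `/`)
  rainW <- pmax(.interpMidMonth(rateM, daysInMonth) * 7, 0)
  dimw <- c(s@nRows, s@nCols, 52L)
  new("WeeklyClimateGrid",
    spec = s,
    tmin = array(tminW, dimw), tmax = array(tmaxW, dimw),
    tavg = array((tminW + tmaxW) / 2, dimw),
    rain = array(rainW, dimw),
    mask = m@mask
  )
}

## ---- occurrences ----------------------------------------------------------

#' Read or write occurrence records
#'
#' Occurrence sets are plain data frames with columns `lon`, `lat`
#' (decimal degrees, WGS84) and `source` (free-text provenance label),
#' serialised as CSV with exactly that header.
#'
#' @param path CSV path.
#' @return `readOccurrences()`: a validated occurrence data.frame.
#' @export
readOccurrences <- function(path) {
  occ <- utils::read.csv(path, stringsAsFactors = FALSE)
  validateOccurrences(occ)
}

#' @rdname readOccurrences
#' @param occ an occurrence data.frame.
#' @export
writeOccurrences <- function(occ, path) {
  occ <- validateOccurrences(occ)
  utils::write.csv(occ, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname readOccurrences
#' @export
validateOccurrences <- function(occ) {
  if (!all(c("lon", "lat", "source") %in% names(occ)))
    stop("occurrences need columns lon, lat, source")
  if (nrow(occ)) {
    if (any(!is.finite(occ$lon)) || any(!is.finite(occ$lat)))
      stop("non-finite occurrence coordinates")
    if (any(occ$lat < -90 | occ$lat > 90))
      stop("latitude outside [-90, 90]")
    if (any(occ$lon < -180 | occ$lon > 180))
      stop("longitude outside [-180, 180]")
  }
  occ[, c("lon", "lat", "source")]
}

#' Map coordinates to grid cells
#'
#' Row/column indices of the cells containing each point, under cell-centre
#' registration with row 1 at the northern edge. Points outside the grid
#' extent get `NA`; points exactly on the southern or eastern outer edge are
#' assigned to the last row/column.
#'
#' @param lon,lat coordinate vectors (degrees).
#' @param spec a [GridSpec-class].
#' @return A data.frame with columns `row`, `col`, `cell` (linear index,
#'   column-major), `NA` where off-grid.
#' @export
cellFromCoords <- function(lon, lat, spec) {
  res <- spec@resolution
  top <- spec@latOrigin + res / 2
  left <- spec@lonOrigin - res / 2
  r <- floor((top - lat) / res) + 1L
  cl <- floor((lon - left) / res) + 1L
  # points exactly on the outer south/east edge fall in the last cell
  r[lat == top - spec@nRows * res] <- spec@nRows
  cl[lon == left + spec@nCols * res] <- spec@nCols
  bad <- r < 1L | r > spec@nRows | cl < 1L | cl > spec@nCols
  r[bad] <- NA_integer_; cl[bad] <- NA_integer_
  data.frame(row = r, col = cl, cell = r + (cl - 1L) * spec@nRows)
}

#' Spatially thin occurrences to one record per grid cell
#'
#' Retains the first record (in input order) falling in each cell of `spec`;
#' records outside the grid extent are dropped with a warning. Thinning is
#' idempotent. An empty input yields an empty output.
#'
#' @param occ occurrence data.frame (`lon`, `lat`, `source`).
#' @param spec the thinning grid, typically the climate [GridSpec-class]
#'   (10 arc-min cells by default, ~18 km at the equator).
#' @return The thinned occurrence data.frame.
#' @export
thinOccurrences <- function(occ, spec) {
  occ <- validateOccurrences(occ)
  if (!nrow(occ)) return(occ)
  cells <- cellFromCoords(occ$lon, occ$lat, spec)$cell
  if (anyNA(cells)) {
    warning(sum(is.na(cells)), " occurrence record(s) outside the grid dropped")
    occ <- occ[!is.na(cells), , drop = FALSE]
    cells <- cells[!is.na(cells)]
  }
  out <- occ[!duplicated(cells), , drop = FALSE]
  rownames(out) <- NULL
  out
}
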