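#' @include AllClasses.R
NULL

# ESRI ASCII grid: 6 header lines then nRows rows of nCols values,
# row 1 = northern edge. Cell-centre registration is recovered from the
# corner coordinates in the header.

.specFromHeader <- function(h) {
  res <- h[["cellsize"]]
  GridSpec(
    nRows = h[["nrows"]], nCols = h[["ncols"]],
    latOrigin = h[["yllcorner"]] + h[["nrows"]] * res - res / 2,
    lonOrigin = h[["xllcorner"]] + res / 2,
    resolution = res
  )
}

#' Read an ESRI ASCII grid
#'
#' Reads a single-band ESRI ASCII raster (`.asc`) into a
#' [GridLayer-class]. Nodata cells (value given by the `NODATA_value`
#' header, conventionally -9999) become `NA`.
#'
#' @param path file path.
#' @param spec optional reference [GridSpec-class]; a mismatch in shape,
#'   origin or resolution is an error.
#' @return A [GridLayer-class].
#' @export
readAsciiGrid <- function(path, spec = NULL) {
  if (!file.exists(path)) stop("raster not found: ", path)
  con <- file(path, "r")
  on.exit(close(con))
  hdr <- character(6)
  for (i in 1:6) hdr[i] <- readLines(con, n = 1L)
  toks <- strsplit(trimws(hdr), "[[:space:]]+")
  keys <- tolower(vapply(toks, `[`, "", 1L))
  vals <- as.numeric(vapply(toks, `[`, "", 2L))
  names(vals) <- keys
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% keys))
    stop("malformed ESRI ASCII header in ", path)
  h <- as.list(vals[need])
  names(h) <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
                "NODATA_value")
  v <- scan(con, what = numeric(), quiet = TRUE)
  n <- h$nrows * h$ncols
  if (length(v) != n)
    stop(sprintf("expected %d values in %s, found %d", n, path, length(v)))
  m <- matrix(v, nrow = h$nrows, ncol = h$ncols, byrow = TRUE)
  m[m == h$NODATA_value] <- NA_real_
  out <- gridLayer(.specFromHeader(h), m)
  if (!is.null(spec)) .checkSameSpec(out@spec, spec, path)
  out
}

.checkSameSpec <- function(got, want, what = "raster") {
  same <- got@nRows == want@nRows && got@nCols == want@nCols &&
    abs(got@resolution - want@resolution) < 1e-9 &&
    abs(got@latOrigin - want@latOrigin) < 1e-6 &&
    abs(got@lonOrigin - want@lonOrigin) < 1e-6
  if (!same)
    stop("grid mismatch with reference GridSpec in ", what)
  invisible(TRUE)
}

#' Write an ESRI ASCII grid
#'
#' Values are written with 17 significant digits, so a write/read round trip
#' reproduces single- and double-precision values exactly. `NA` cells are
#' written as the nodata value.
#'
#' @param layer a [GridLayer-class].
#' @param path output path.
#' @param nodata nodata sentinel, default -9999.
#' @return `path`, invisibly.
#' @export
writeAsciiGrid <- function(layer, path, nodata = -9999) {
  s <- layer@spec
  res <- s@resolution
  hdr <- c(
    sprintf("ncols %d", s@nCols),
    sprintf("nrows %d", s@nRows),
    sprintf("xllcorner %.12f", s@lonOrigin - res / 2),
    sprintf("yllcorner %.12f", s@latOrigin + res / 2 - s@nRows * res),
    sprintf("cellsize %.12f", res),
    sprintf("NODATA_value %g", nodata)
  )
  m <- layer@values
  m[is.na(m)] <- nodata
  body <- apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a 0/1 mask raster
#'
#' @param path ESRI ASCII grid path; values must be 0, 1 or nodata.
#' @param spec optional reference [GridSpec-class] to check against.
#' @return A [GridLayer-class] with values in \{0, 1, NA\}.
#' @export
readMask <- function(path, spec = NULL) {
  g <- readAsciiGrid(path, spec)
  v <- g@values
  if (any(!(v %in% c(0, 1)) & !is.na(v)))
    stop("mask raster contains values other than 0/1: ", path)
  g
}

#' Read an Ecoclimatic Index raster
#'
#' @param path ESRI ASCII grid path; land values must be finite in [0, 100].
#' @param spec optional reference [GridSpec-class] to check against.
#' @return A [GridLayer-class].
#' @export
readEIRaster <- function(path, spec = NULL) {
  g <- readAsciiGrid(path, spec)
  v <- g@values
  bad <- !is.na(v) & (!is.finite(v) | v < 0 | v > 100)
  if (any(bad)) {
    ij <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("EI raster value out of [0,100] at cell (row %d, col %d)",
                 ij[1], ij[2]))
  }
  g
}

# 12-band stacks are stored as one .asc per band with suffix _01.._12.
.stackPaths <- function(prefix, n = 12L) {
  if (length(prefix) == n) return(prefix)
  if (length(prefix) == 1L)
    return(sprintf("%s_%02d.asc", sub("\\.asc$", "", prefix), seq_len(n)))
  stop("expected a single stack prefix or ", n, " band paths")
}

.readStack <- function(prefix, n = 12L, spec = NULL) {
  paths <- .stackPaths(prefix, n)
  layers <- vector("list", n)
  for (i in seq_len(n)) {
    layers[[i]] <- readAsciiGrid(paths[i], spec)
    if (is.null(spec)) spec <- layers[[i]]@spec
    else .checkSameSpec(layers[[i]]@spec, spec, paths[i])
  }
  a <- array(NA_real_, c(spec@nRows, spec@nCols, n))
  for (i in seq_len(n)) a[, , i] <- layers[[i]]@values
  list(spec = spec, values = a)
}

.writeStack <- function(spec, a, prefix, nodata = -9999) {
  n <- dim(a)[3]
  paths <- .stackPaths(prefix, n)
  for (i in seq_len(n))
    writeAsciiGrid(gridLayer(spec, a[, , i]), paths[i], nodata)
  invisible(paths)
}
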