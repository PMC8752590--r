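#' @include AllClasses.R
NULL

#' Construct species parameters
#'
#' Builds a [ClimexParams-class] object. All arguments default to the fall
#' armyworm profile (see the class documentation for values and units);
#' supply any subset to override. Cold and dry stress rates are magnitudes;
#' parameter tables that print them with a negative sign (a storage
#' convention meaning "stress accrues below the threshold") should be entered
#' here as positive numbers.
#'
#' @param DV0,DV1,DV2,DV3 temperature trapezoid (degrees C).
#' @param SM0,SM1,SM2,SM3 soil-moisture trapezoid (index units).
#' @param TTCS,THCS cold stress threshold (degC, on weekly tmin) and rate.
#' @param TTHS,THHS heat stress threshold (degC, on weekly tmax) and rate.
#' @param SMDS,HDS dry stress threshold (SM units) and rate.
#' @param SMWS,HWS wet stress threshold (SM units) and rate.
#' @param PDD annual degree-day requirement above DV0.
#' @param irrigationRate top-up irrigation (mm/day).
#' @param irrigationThreshold weekly rainfall (mm) below which top-up applies.
#' @return A validated [ClimexParams-class].
#' @examples
#' p <- climexParams()            # fall armyworm defaults
#' climexParams(DV3 = 34)         # one override
#' @export
climexParams <- function(DV0 = 12, DV1 = 25, DV2 = 30, DV3 = 36,
                         SM0 = 0.15, SM1 = 0.8, SM2 = 1.5, SM3 = 2.0,
                         TTCS = 8, THCS = 0.005,
                         TTHS = 39, THHS = 0.0025,
                         SMDS = 0.1, HDS = 0.005,
                         SMWS = 2.0, HWS = 0.01,
                         PDD = 400,
                         irrigationRate = 2.5, irrigationThreshold = 25) {
  new("ClimexParams",
    DV0 = DV0, DV1 = DV1, DV2 = DV2, DV3 = DV3,
    SM0 = SM0, SM1 = SM1, SM2 = SM2, SM3 = SM3,
    TTCS = TTCS, THCS = abs(THCS),
    TTHS = TTHS, THHS = abs(THHS),
    SMDS = SMDS, HDS = abs(HDS),
    SMWS = SMWS, HWS = abs(HWS),
    PDD = PDD,
    irrigationRate = irrigationRate,
    irrigationThreshold = irrigationThreshold
  )
}

#' Construct soil-bucket parameters
#'
#' @param capacity soil water holding capacity (mm).
#' @param evapCoeff evaporation coefficient (mm per degC per week).
#' @param smCap upper cap on the soil-moisture index.
#' @param smInit initial soil-moisture index for spin-up.
#' @param spinupYears spin-up years before the reported annual cycle.
#' @return A validated [SoilParams-class].
#' @export
soilParams <- function(capacity = 100, evapCoeff = 1, smCap = 2.5,
                       smInit = 0.5, spinupYears = 2) {
  new("SoilParams",
    capacity = capacity, evapCoeff = evapCoeff, smCap = smCap,
    smInit = smInit, spinupYears = as.integer(spinupYears)
  )
}

.paramSlotNames <- function() {
  c("DV0", "DV1", "DV2", "DV3", "SM0", "SM1", "SM2", "SM3",
    "TTCS", "THCS", "TTHS", "THHS", "SMDS", "HDS", "SMWS", "HWS",
    "PDD", "irrigationRate", "irrigationThreshold")
}

#' Read a flat key=value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment; blank lines
#' ignored. Values are returned as character and coerced by the caller.
#'
#' @param path file path.
#' @return Named character vector.
#' @export
readConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(stats::setNames(character(), character()))
  bad <- !grepl("=", lines, fixed = TRUE)
  if (any(bad))
    stop("malformed config line (expected key = value): ", lines[bad][1])
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  stats::setNames(vals, keys)
}

#' Read species parameters from a key=value file
#'
#' The file carries one key per parameter symbol (`DV0`, ..., `PDD`,
#' `irrigationRate`, `irrigationThreshold`); missing keys keep their profile
#' defaults. Negative printed rates are accepted and stored as magnitudes.
#'
#' @param path parameter file path.
#' @return A [ClimexParams-class].
#' @seealso [fawParams()] for the shipped fall armyworm profile.
#' @export
readParams <- function(path) {
  cfg <- readConfig(path)
  known <- intersect(names(cfg), .paramSlotNames())
  unknown <- setdiff(names(cfg), .paramSlotNames())
  if (length(unknown))
    warning("ignoring unknown parameter keys: ",
            paste(unknown, collapse = ", "))
  args <- lapply(cfg[known], function(v) {
    x <- suppressWarnings(as.numeric(v))
    if (is.na(x)) stop("non-numeric parameter value: ", v)
    x
  })
  do.call(climexParams, args)
}

#' Write species parameters to a key=value file
#'
#' @param p a [ClimexParams-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeParams <- function(p, path) {
  nms <- .paramSlotNames()
  vals <- vapply(nms, function(nm) slot(p, nm), numeric(1))
  writeLines(sprintf("%s = %.15g", nms, vals), path)
  invisible(path)
}

#' Shipped fall armyworm parameter profile
#'
#' Reads `faw.params` from the package's `extdata`; identical to
#' `climexParams()` defaults, shipped as a file so runs can be reproduced
#' from configuration alone.
#'
#' @return A [ClimexParams-class].
#' @export
fawParams <- function() {
  readParams(system.file("extdata", "faw.params", package = "ecoclimex",
                         mustWork = TRUE))
}
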