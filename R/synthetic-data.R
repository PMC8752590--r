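#' @include AllClasses.R climate-io.R
NULL

# Evaluate expr with a temporarily seeded RNG, restoring the caller's state,
# so generators are pure functions of (parameters, seed).
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

.archetypePresets <- list(
  # Defaults are calibrated fixtures: they are chosen so that the engine's
  # qualitative signatures hold (tropical optimal, desert dry-stressed and
  # unsuitable, cold-continental cold-stressed with a positive midsummer
  # growth window), not to reproduce any real climatology.
  tropical_wet_dry = list(
    tavgMean = 26, tavgAmplitude = 2, diurnalRange = 10,
    annualRain = 1200, rainPeakMonth = 7, rainConcentration = 0.8,
    tPeakMonth = 7, noiseSdT = 0.3, noiseSdRainFrac = 0.05
  ),
  desert = list(
    tavgMean = 28, tavgAmplitude = 8, diurnalRange = 12,
    annualRain = 50, rainPeakMonth = 1, rainConcentration = 1,
    tPeakMonth = 7, noiseSdT = 0.3, noiseSdRainFrac = 0.05
  ),
  mediterranean = list(
    tavgMean = 17, tavgAmplitude = 9, diurnalRange = 10,
    annualRain = 600, rainPeakMonth = 1, rainConcentration = 1.5,
    tPeakMonth = 7, noiseSdT = 0.3, noiseSdRainFrac = 0.05
  ),
  cold_continental = list(
    tavgMean = 5, tavgAmplitude = 15, diurnalRange = 10,
    annualRain = 300, rainPeakMonth = 7, rainConcentration = 1.2,
    tPeakMonth = 7, noiseSdT = 0.3, noiseSdRainFrac = 0.05
  ),
  humid_subtropical = list(
    tavgMean = 20, tavgAmplitude = 8, diurnalRange = 9,
    annualRain = 1000, rainPeakMonth = 7, rainConcentration = 1,
    tPeakMonth = 7, noiseSdT = 0.3, noiseSdRainFrac = 0.05
  )
)

#' Climate archetypes
#'
#' `archetypeNames()` lists the built-in archetypes; `climateArchetype()`
#' returns one as a parameter list, with optional overrides. An archetype is
#' a stylised seasonal regime: monthly mean temperature follows
#' `tavgMean + tavgAmplitude * cos(2*pi*(m - tPeakMonth)/12)`, tmin/tmax sit
#' `diurnalRange/2` below/above it, and `annualRain` is apportioned across
#' months by a unimodal von Mises-style weight
#' `exp(rainConcentration * cos(2*pi*(m - rainPeakMonth)/12))`, normalised to
#' sum to one. Independent Gaussian cell noise (`noiseSdT` degC on
#' temperature, `noiseSdRainFrac` multiplicative on rain) makes cells
#' distinct.
#'
#' @param name archetype name.
#' @param ... named overrides of the preset fields.
#' @return A named list of archetype parameters.
#' @examples
#' climateArchetype("desert")
#' climateArchetype("desert", annualRain = 100)
#' @export
climateArchetype <- function(name = archetypeNames(), ...) {
  name <- match.arg(name)
  arch <- .archetypePresets[[name]]
  over <- list(...)
  bad <- setdiff(names(over), names(arch))
  if (length(bad)) stop("unknown archetype fields: ", paste(bad, collapse = ", "))
  arch[names(over)] <- over
  if (arch$annualRain < 0 || arch$tavgAmplitude < 0)
    stop("annualRain and tavgAmplitude must be >= 0")
  c(list(name = name), arch)
}

#' @rdname climateArchetype
#' @export
archetypeNames <- function() names(.archetypePresets)

#' Generate a monthly climate grid from an archetype
#'
#' Deterministic given `(arch, spec, seed)`. All cells are land; geography
#' (sea, regions) is handled by masks downstream.
#'
#' @param arch an archetype from [climateArchetype()], or its name.
#' @param spec a [GridSpec-class].
#' @param seed integer seed.
#' @return A [MonthlyClimateGrid-class].
#' @export
genArchetypeClimate <- function(arch, spec, seed) {
  if (is.character(arch)) arch <- climateArchetype(arch)
  nc <- spec@nRows * spec@nCols
  m <- seq_len(12L)
  tavgM <- arch$tavgMean +
    arch$tavgAmplitude * cos(2 * pi * (m - arch$tPeakMonth) / 12)
  wRain <- exp(arch$rainConcentration *
                 cos(2 * pi * (m - arch$rainPeakMonth) / 12))
  rainM <- arch$annualRain * wRain / sum(wRain)
  .withSeed(seed, {
    tNoise <- matrix(stats::rnorm(nc * 12L, sd = arch$noiseSdT), nc, 12L)
    rNoise <- matrix(
      pmax(0, 1 + stats::rnorm(nc * 12L, sd = arch$noiseSdRainFrac)), nc, 12L)
    tavg <- sweep(tNoise, 2L, tavgM, `+`)
    rain <- sweep(rNoise, 2L, rainM, `*`)
    dimm <- c(spec@nRows, spec@nCols, 12L)
    monthlyClimateGrid(
      spec,
      tmin = array(tavg - arch$diurnalRange / 2, dimm),
      tmax = array(tavg + arch$diurnalRange / 2, dimm),
      prec = array(rain, dimm)
    )
  })
}

#' Generate a random irrigation mask
#'
#' Exactly `round(fraction * nCells)` cells are set to 1, chosen uniformly at
#' random with the given seed.
#'
#' @param spec a [GridSpec-class].
#' @param fraction proportion of cells irrigated, in [0, 1].
#' @param seed integer seed.
#' @return A [GridLayer-class] of 0/1 values.
#' @export
genIrrigationMask <- function(spec, fraction, seed) {
  if (!is.finite(fraction) || fraction < 0 || fraction > 1)
    stop("fraction must lie in [0, 1]")
  nc <- spec@nRows * spec@nCols
  k <- round(fraction * nc)
  v <- numeric(nc)
  if (k > 0)
    .withSeed(seed, v[sample.int(nc, k)] <- 1)
  gridLayer(spec, matrix(v, spec@nRows, spec@nCols))
}

#' Generate occurrence records concentrated in suitable cells
#'
#' `(1 - noiseFrac) * n` points are placed in cells sampled with probability
#' proportional to EI (presence driven by suitability); the remaining
#' `noiseFrac * n` are uniform over land cells (observation noise and
#' transient records). Each point is placed uniformly within its cell.
#'
#' @param ei an EI [GridLayer-class]; `NA` cells are excluded.
#' @param n number of records (>= 1).
#' @param noiseFrac proportion of uniform background points, in [0, 1].
#' @param seed integer seed.
#' @return An occurrence data.frame (`lon`, `lat`, `source`), where `source`
#'   is `"suitability"` or `"background"`.
#' @export
genOccurrences <- function(ei, n, noiseFrac = 0.05, seed = 1) {
  if (n < 1) stop("n must be >= 1")
  if (noiseFrac < 0 || noiseFrac > 1) stop("noiseFrac must lie in [0, 1]")
  spec <- ei@spec
  v <- as.vector(ei@values)
  land <- which(!is.na(v))
  if (!length(land)) stop("no land cells in EI grid")
  nSuit <- round((1 - noiseFrac) * n)
  nBack <- n - nSuit
  w <- v[land]
  if (nSuit > 0 && sum(w) <= 0)
    stop("no cell has EI > 0; cannot place suitability-weighted points")
  .withSeed(seed, {
    cells <- c(
      if (nSuit > 0) sample(land, nSuit, replace = TRUE, prob = w),
      if (nBack > 0) sample(land, nBack, replace = TRUE)
    )
    r <- ((cells - 1L) %% spec@nRows) + 1L
    cl <- ((cells - 1L) %/% spec@nRows) + 1L
    lat <- cellLatitudes(spec)[r] + (stats::runif(n) - 0.5) * spec@resolution
    lon <- cellLongitudes(spec)[cl] + (stats::runif(n) - 0.5) * spec@resolution
    data.frame(
      lon = lon, lat = lat,
      source = rep(c("suitability", "background"), c(nSuit, nBack)),
      stringsAsFactors = FALSE
    )
  })
}
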