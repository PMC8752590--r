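# Shared fixtures, built in code at test time.

smallSpec <- function(nRows = 4, nCols = 5, lat = 10, lon = 20, res = 1 / 6) {
  GridSpec(nRows, nCols, latOrigin = lat, lonOrigin = lon, resolution = res)
}

# A constant monthly climate: every cell, every month identical.
constantMonthly <- function(spec = smallSpec(), tmin = 20, tmax = 30,
                            prec = 80) {
  d <- c(spec@nRows, spec@nCols, 12L)
  monthlyClimateGrid(spec,
    tmin = array(tmin, d), tmax = array(tmax, d), prec = array(prec, d))
}

# Weekly series builders for single-location engine tests.
constWeeks <- function(x) rep(x, 52L)

# Random plausible weekly series (bounded temperatures, nonneg rain).
randomWeekly <- function() {
  tmin <- runif(52, -15, 25)
  list(tmin = tmin,
       tmax = tmin + runif(52, 0, 18),
       rain = rexp(52, rate = 1 / 20))
}
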