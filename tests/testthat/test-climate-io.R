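test_that("ASCII grid write/read round-trips values and geometry exactly", {
  spec <- smallSpec()
  set.seed(11)
  m <- matrix(rnorm(spec@nRows * spec@nCols), spec@nRows, spec@nCols)
  m[2, 3] <- NA
  f <- withr::local_tempfile(fileext = ".asc")
  writeAsciiGrid(gridLayer(spec, m), f)
  g <- readAsciiGrid(f)
  expect_identical(layerValues(g), m)
  expect_equal(g@spec@latOrigin, spec@latOrigin)
  expect_equal(g@spec@lonOrigin, spec@lonOrigin)
  expect_equal(g@spec@resolution, spec@resolution)
})

test_that("monthly climate read validates stacks and round-trips", {
  spec <- smallSpec()
  m <- constantMonthly(spec)
  td <- withr::local_tempdir()
  pre <- function(v) file.path(td, v)
  writeMonthlyClimate(m, pre("tmin"), pre("tmax"), pre("prec"))
  m2 <- readMonthlyClimate(pre("tmin"), pre("tmax"), pre("prec"))
  expect_equal(m2@tmin, m@tmin)
  expect_equal(m2@tmax, m@tmax)
  expect_equal(m2@prec, m@prec)
  expect_true(all(m2@tmin == 20) && all(m2@tmax == 30) && all(m2@prec == 80))

  # mismatched shapes across stacks are rejected
  other <- constantMonthly(smallSpec(nRows = 3))
  writeMonthlyClimate(other, pre("bad_tmax"), pre("t2"), pre("p2"))
  expect_error(readMonthlyClimate(pre("tmin"), pre("bad_tmax"), pre("prec")),
               "mismatch")
})

test_that("readers reject physically invalid land values", {
  spec <- smallSpec()
  d <- c(spec@nRows, spec@nCols, 12L)
  expect_error(
    monthlyClimateGrid(spec, tmin = array(25, d), tmax = array(20, d),
                       prec = array(10, d), mask = matrix(TRUE, 4, 5)),
    "tmax < tmin")
  expect_error(
    monthlyClimateGrid(spec, tmin = array(10, d), tmax = array(20, d),
                       prec = array(-1, d)),
    "precipitation")
  expect_error(
    monthlyClimateGrid(spec, tmin = array(NaN, d), tmax = array(20, d),
                       prec = array(5, d), mask = matrix(TRUE, 4, 5)),
    "non-finite")
})

test_that("weekly conversion preserves constants and converts rain rates", {
  m <- constantMonthly(tmin = 20, tmax = 30, prec = 80)
  w <- monthlyToWeekly(m)
  expect_true(all(w@tmin == 20))
  expect_true(all(w@tmax == 30))
  expect_true(all(w@tavg == 25))

  # constant 31 mm in an all-31-day month calendar -> exactly 7 mm/week
  m31 <- constantMonthly(prec = 31)
  w31 <- monthlyToWeekly(m31, daysInMonth = rep(31, 12))
  expect_equal(as.vector(w31@rain), rep(7, length(w31@rain)))
})

test_that("weekly interpolation tracks a sinusoidal seasonal cycle", {
  spec <- smallSpec(1, 1)
  mths <- 1:12
  tavgM <- 15 + 10 * cos(2 * pi * (mths - 7) / 12)
  d <- c(1, 1, 12)
  m <- monthlyClimateGrid(spec, tmin = array(tavgM - 5, d),
                          tmax = array(tavgM + 5, d),
                          prec = array(50, d))
  w <- monthlyToWeekly(m)
  tavgW <- as.vector(w@tavg)
  # interpolation between mid-month anchors cannot overshoot and must come
  # within half a degree of the monthly extremes
  expect_lte(max(tavgW), max(tavgM) + 1e-9)
  expect_gte(min(tavgW), min(tavgM) - 1e-9)
  expect_lt(abs(max(tavgW) - max(tavgM)), 0.5)
  expect_lt(abs(min(tavgW) - min(tavgM)), 0.5)
})

test_that("annual rain total is approximately conserved for smooth cycles", {
  spec <- smallSpec(1, 1)
  mths <- 1:12
  precM <- 100 + 80 * cos(2 * pi * (mths - 2) / 12)
  m <- monthlyClimateGrid(spec, tmin = array(10, c(1, 1, 12)),
                          tmax = array(20, c(1, 1, 12)),
                          prec = array(precM, c(1, 1, 12)))
  w <- monthlyToWeekly(m)
  expect_lt(abs(sum(w@rain) - sum(precM)) / sum(precM), 0.05)
})

test_that("occurrence thinning keeps one record per cell and is idempotent", {
  spec <- smallSpec(2, 2, lat = 2, lon = 1, res = 1)
  occ <- data.frame(lon = c(1.0, 1.01, 2.0), lat = c(1.0, 1.01, 2.0),
                    source = c("a", "b", "c"))
  th <- thinOccurrences(occ, spec)
  expect_equal(nrow(th), 2L)          # two records share one cell
  expect_equal(th$source[1], "a")     # first-in-input-order tie-break

  # distinct cells are all retained
  occ2 <- data.frame(lon = c(0.8, 1.8), lat = c(0.8, 1.8),
                     source = c("a", "b"))
  expect_equal(nrow(thinOccurrences(occ2, spec)), 2L)

  # pigeonhole: many random points on a 2x2 grid collapse to <= 4
  set.seed(7)
  occ3 <- data.frame(lon = runif(100, 0.5, 2.5), lat = runif(100, 0.5, 2.5),
                     source = "x")
  th3 <- thinOccurrences(occ3, spec)
  expect_lte(nrow(th3), 4L)
  expect_identical(thinOccurrences(th3, spec), th3)

  # empty input is an empty output, not an error
  expect_equal(nrow(thinOccurrences(occ[0, ], spec)), 0L)
})

test_that("occurrence CSV round-trips and coordinates are validated", {
  occ <- data.frame(lon = c(10.5, -3.2), lat = c(1.1, 45.0),
                    source = c("survey", "trap"))
  f <- withr::local_tempfile(fileext = ".csv")
  writeOccurrences(occ, f)
  expect_equal(readOccurrences(f), occ)
  expect_error(validateOccurrences(data.frame(lon = 1, lat = 91,
                                              source = "s")),
               "latitude")
})

test_that("mask and EI raster readers enforce their contracts", {
  spec <- smallSpec()
  f <- withr::local_tempfile(fileext = ".asc")
  writeAsciiGrid(gridLayer(spec, 0), f)
  expect_true(all(layerValues(readMask(f)) == 0))

  writeAsciiGrid(gridLayer(spec, 0.5), f)
  expect_error(readMask(f), "0/1")

  writeAsciiGrid(gridLayer(spec, 101), f)
  expect_error(readEIRaster(f), "\\[0,100\\]")

  writeAsciiGrid(gridLayer(spec, 50), f)
  expect_error(readEIRaster(f, smallSpec(nRows = 7)), "mismatch")
})
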