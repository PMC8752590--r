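p <- climexParams()
sp <- soilParams()

test_that("temperature and moisture indices reproduce the worked ramp values", {
  expect_identical(temperatureIndex(27, p), 1)
  expect_identical(temperatureIndex(12, p), 0)
  expect_equal(temperatureIndex(18.5, p), 0.5)
  expect_equal(temperatureIndex(33, p), 0.5)
  expect_identical(moistureIndex(1.0, p), 1)
  expect_identical(moistureIndex(0.15, p), 0)
  expect_equal(moistureIndex(0.475, p), 0.5)
  expect_equal(moistureIndex(1.75, p), 0.5)
})

test_that("indices equal the closed-form trapezoid at random points", {
  trapOracle <- function(x, a, b, c, d) {
    # closed form, written independently of the implementation
    ifelse(x <= a | x >= d, 0,
           ifelse(x < b, (x - a) / (b - a),
                  ifelse(x <= c, 1, (d - x) / (d - c))))
  }
  set.seed(1)
  xt <- runif(10000, 0, 50)
  expect_lt(max(abs(temperatureIndex(xt, p) -
                      trapOracle(xt, 12, 25, 30, 36))), 1e-12)
  xs <- runif(10000, 0, 3)
  expect_lt(max(abs(moistureIndex(xs, p) -
                      trapOracle(xs, 0.15, 0.8, 1.5, 2.0))), 1e-12)
})

test_that("index curves are monotone on their rising limbs", {
  tt <- seq(5, 25, by = 0.1)          # up to DV1
  expect_true(all(diff(temperatureIndex(tt, p)) >= 0))
  ss <- seq(0, 0.8, by = 0.01)        # up to SM1
  expect_true(all(diff(moistureIndex(ss, p)) >= 0))
})

test_that("soil bucket drains to zero without rain and saturates under flood", {
  dry <- soilMoistureSeries(constWeeks(0), constWeeks(25), sp)
  expect_true(all(diff(dry) <= 1e-12))
  expect_lt(dry[52], 1e-6)

  wet <- soilMoistureSeries(constWeeks(300), constWeeks(25), sp)
  expect_true(all(wet[10:52] == sp@smCap))
})

test_that("soil bucket converges to the analytic interior fixed point", {
  # at equilibrium with SM* <= 1: rain = evapCoeff * tavg * SM*
  rain <- 15; tavg <- 25
  smStar <- rain / (sp@evapCoeff * tavg)
  sm <- soilMoistureSeries(constWeeks(rain), constWeeks(tavg), sp)
  expect_equal(sm[52], smStar, tolerance = 1e-6)
  expect_lt(max(abs(sm - smStar)), 1e-4)
})

test_that("matrix and vector soil-moisture paths agree", {
  set.seed(3)
  w <- randomWeekly()
  tavg <- (w$tmin + w$tmax) / 2
  vec <- soilMoistureSeries(w$rain, tavg, sp)
  mat <- soilMoistureSeries(rbind(w$rain, w$rain), rbind(tavg, tavg), sp)
  expect_equal(mat[1, ], vec)
  expect_equal(mat[2, ], vec)
})

test_that("annual growth index is the scaled mean of weekly products", {
  expect_identical(annualGrowthIndex(constWeeks(1), constWeeks(1)), 100)
  expect_identical(annualGrowthIndex(constWeeks(0), constWeeks(1)), 0)
  half <- c(rep(1, 26), rep(0, 26))
  expect_equal(annualGrowthIndex(half, constWeeks(1)), 50)
  expect_error(annualGrowthIndex(rep(1, 51), rep(1, 51)), "52")
})

test_that("stress accumulation reproduces the worked examples exactly", {
  expect_identical(stressAnnual(constWeeks(8), 8, 0.005, "below"), 0)
  tmin <- constWeeks(8); tmin[17] <- 6
  expect_equal(stressAnnual(tmin, 8, 0.005, "below"), 1.0)
  expect_equal(stressAnnual(constWeeks(45), 39, 0.0025, "above"), 78.0)
  expect_identical(stressAnnual(constWeeks(2.0), 2.0, 0.01, "above"), 0)
  expect_error(stressAnnual(constWeeks(1), 1, 0.1, "sideways"))
})

test_that("each stress is nondecreasing in weekly exceedance and caps at 100", {
  set.seed(5)
  for (i in 1:20) {
    base <- runif(52, 0, 10)
    extra <- base + runif(52, 0, 5)   # pointwise larger exceedance
    sBase <- stressAnnual(20 - base, 20, 0.01, "below")
    sMore <- stressAnnual(20 - extra, 20, 0.01, "below")
    expect_gte(sMore, sBase)
    aBase <- stressAnnual(20 + base, 20, 0.01, "above")
    aMore <- stressAnnual(20 + extra, 20, 0.01, "above")
    expect_gte(aMore, aBase)
  }
  expect_identical(stressAnnual(constWeeks(-100), 8, 1, "below"), 100)
})

test_that("degree-day accumulation matches its closed form", {
  expect_identical(annualDegreeDays(constWeeks(12), 12), 0)
  expect_equal(annualDegreeDays(constWeeks(22), 12), 3640)
  one <- constWeeks(12); one[30] <- 13
  expect_equal(annualDegreeDays(one, 12), 7)
})

test_that("stress index composes multiplicatively", {
  expect_identical(stressIndex(0, 0, 0, 0), 1)
  expect_identical(stressIndex(100, 0, 0, 0), 0)
  expect_equal(stressIndex(50, 50, 0, 0), 0.25)
})

test_that("EI combines growth and stress and is gated by the degree-day sum", {
  expect_equal(ecoclimaticIndex(80, 0.5, 1.0, 3640, 400), 40)
  expect_identical(ecoclimaticIndex(80, 0.5, 1.0, 399, 400), 0)
  expect_identical(ecoclimaticIndex(0, 1, 1, 5000, 400), 0)
})

test_that("EI identities hold over randomized weekly series", {
  set.seed(42)
  for (i in 1:200) {
    w <- randomWeekly()
    r <- runLocation(w$tmin, w$tmax, w$rain, p, sp)
    expect_gte(r@ei, 0); expect_lte(r@ei, 100)
    shouldBeZero <- r@giA == 0 || r@si == 0 || r@dd < p@PDD
    expect_identical(r@ei == 0, shouldBeZero)
    # EI never exceeds its growth component
    expect_lte(r@ei, r@giA + 1e-12)
  }
})

test_that("run_location on canonical climates behaves as composed oracle", {
  # constant optimal climate: tavg 27, rain holding SM on the optimal plateau
  rain <- constWeeks(27)              # equilibrium SM = 27/27 = 1.0
  r <- runLocation(constWeeks(22), constWeeks(32), rain, p, sp)
  expect_gt(r@ei, 90)

  # desert cell: no rain at all
  d <- runLocation(constWeeks(20), constWeeks(32), constWeeks(0), p, sp)
  expect_identical(d@ei, 0)
  expect_gt(d@ds, 0)

  # frozen cell
  f <- runLocation(constWeeks(-5), constWeeks(5), constWeeks(20), p, sp)
  expect_identical(f@ei, 0)
  expect_identical(f@dd, 0)
  expect_identical(f@giA, 0)
})

test_that("runGrid equals runLocation cell-wise on a uniform grid", {
  m <- constantMonthly(smallSpec(), tmin = 22, tmax = 32, prec = 110)
  w <- monthlyToWeekly(m)
  run <- runGrid(w, p, sp)
  one <- runLocation(w@tmin[1, 1, ], w@tmax[1, 1, ], w@rain[1, 1, ], p, sp)
  expect_true(all(abs(layerValues(run@ei) - one@ei) < 1e-12))
  expect_true(all(abs(layerValues(run@giA) - one@giA) < 1e-12))
  expect_true(all(abs(layerValues(run@cs) - one@cs) < 1e-12))
})

test_that("runGrid keeps nodata cells as NA in every layer", {
  spec <- smallSpec()
  m <- constantMonthly(spec, tmin = 22, tmax = 32, prec = 110)
  mask <- m@mask; mask[1, 1] <- FALSE
  m2 <- monthlyClimateGrid(spec, m@tmin, m@tmax, m@prec, mask = mask)
  run <- runGrid(monthlyToWeekly(m2), p, sp)
  expect_true(is.na(layerValues(run@ei)[1, 1]))
  expect_true(is.na(layerValues(run@ws)[1, 1]))
  expect_false(anyNA(layerValues(run@ei)[-1]))
})

test_that("parameter file round-trips and the shipped profile loads", {
  faw <- fawParams()
  expect_equal(faw, climexParams())
  f <- withr::local_tempfile(fileext = ".params")
  writeParams(climexParams(DV3 = 35, PDD = 390), f)
  back <- readParams(f)
  expect_equal(back@DV3, 35)
  expect_equal(back@PDD, 390)
  # negative printed rates are magnitudes
  writeLines(c("THCS = -0.005", "HDS = -0.005"), f)
  expect_equal(readParams(f)@THCS, 0.005)
  expect_error(climexParams(DV1 = 40, DV2 = 30), "DV0 <= DV1")
})
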