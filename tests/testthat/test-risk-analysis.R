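test_that("EI classification uses the printed half-open intervals", {
  f <- classifyEI(c(0, 5, 10, 10.0001, 30, 30.5, 100))
  expect_equal(as.character(f),
               c("unsuitable", "marginal", "marginal", "suitable",
                 "suitable", "optimal", "optimal"))
  expect_true(is.na(classifyEI(NA_real_)))
  expect_error(classifyEI(101), "\\[0, 100\\]")
})

test_that("cell areas follow the spherical-segment formula", {
  # frozen oracle: numerical integration of R^2 cos(lat) over the cell
  expect_equal(cellAreaKm2(0, 1 / 6), 343.452982, tolerance = 2e-3)
  expect_equal(cellAreaKm2(60, 1 / 6), 171.726491, tolerance = 2e-3)
  expect_equal(cellAreaKm2(60, 1 / 6) / cellAreaKm2(0, 1 / 6), 0.5,
               tolerance = 0.01)
  # monotone decrease with |latitude|
  lats <- seq(0, 89, by = 1)
  expect_true(all(diff(cellAreaKm2(lats, 1 / 6)) < 0))
  # area vanishes with resolution
  expect_lt(cellAreaKm2(0, 1e-6), 1e-3)
})

test_that("category areas partition the region and track the classification", {
  spec <- smallSpec(6, 6, lat = 20)
  set.seed(8)
  ei <- gridLayer(spec, matrix(runif(36, 0, 100), 6, 6))
  cat <- classifyEI(ei)
  tab <- areaByCategory(cat)
  expect_equal(sum(tab$sharePct), 100, tolerance = 1e-9)
  expect_equal(sum(tab$areaKm2), sum(gridCellAreas(spec)), tolerance = 1e-9)
  # accounting agrees with an independent per-cell tally
  lab <- classifyEI(as.vector(layerValues(ei)))
  areas <- as.vector(gridCellAreas(spec))
  manual <- tapply(areas, lab, sum, default = 0)
  expect_equal(tab$areaKm2, as.numeric(manual))

  uniform <- classifyEI(gridLayer(spec, 50))
  tu <- areaByCategory(uniform)
  expect_equal(tu$sharePct[tu$category == "optimal"], 100)
  expect_error(areaByCategory(cat, gridLayer(spec, 0)), "empty region")
})

test_that("change tables are zero against self and flag undefined baselines", {
  spec <- smallSpec(6, 6)
  set.seed(9)
  base <- classifyEI(gridLayer(spec, matrix(runif(36, 0, 100), 6, 6)))
  self <- changeTable(base, base)
  expect_true(all(self$changePct == 0))

  # halve the optimal area on an equal-area (single-latitude-band) grid
  row <- smallSpec(1, 8)
  b <- classifyEI(gridLayer(row, matrix(50, 1, 8)))
  v <- matrix(50, 1, 8); v[1, 1:4] <- 20
  s <- classifyEI(gridLayer(row, v))
  ct <- changeTable(b, s)
  expect_equal(ct$changePct[ct$category == "optimal"], -50)
  expect_true(is.na(ct$changePct[ct$category == "suitable"]))  # 0 -> present
  expect_equal(ct$changePct[ct$category == "unsuitable"], 0)   # absent both
})

test_that("overlap area respects the threshold and self-overlap identity", {
  spec <- smallSpec(1, 10)             # single band: equal cell areas
  cellA <- cellAreaKm2(spec@latOrigin, spec@resolution)
  a <- gridLayer(spec, 50)
  expect_equal(overlapArea(a, a, 10), 10 * cellA, tolerance = 1e-9)

  v1 <- matrix(c(rep(50, 5), rep(0, 5)), 1)
  v2 <- matrix(c(rep(0, 5), rep(50, 5)), 1)
  expect_equal(overlapArea(gridLayer(spec, v1), gridLayer(spec, v2), 10), 0)

  chk <- matrix(rep(c(50, 0), 5), 1)
  expect_equal(overlapArea(gridLayer(spec, chk), a, 10), 5 * cellA,
               tolerance = 1e-9)
  # self-overlap = area above threshold
  set.seed(4)
  r <- gridLayer(spec, matrix(runif(10, 0, 30), 1))
  expect_equal(overlapArea(r, r, 10),
               sum(gridCellAreas(spec)[layerValues(r) > 10]))
})

test_that("performance statistics summarise extracted per-record EI", {
  spec <- smallSpec(2, 2, lat = 2, lon = 1, res = 1)
  ei <- gridLayer(spec, matrix(c(40, 40, 40, 40), 2, 2))
  occ <- data.frame(lon = runif(6, 0.5, 2.5), lat = runif(6, 0.5, 2.5),
                    source = "s")
  st <- performanceStats(ei, occ)
  expect_equal(st$mean, 40)
  expect_equal(st$median, 40)
  expect_equal(st$propAbove10, 1.0)
  expect_equal(sum(st$histogram$count), 6L)

  # half the records on EI 0, half on EI 40
  v <- matrix(c(0, 0, 40, 40), 2, 2)   # columns: west 0, east 40
  ei2 <- gridLayer(spec, v)
  occ2 <- data.frame(lon = c(0.7, 0.9, 2.1, 2.3), lat = c(1.2, 0.8, 1.1, 0.9),
                     source = "s")
  st2 <- performanceStats(ei2, occ2)
  expect_equal(st2$propAbove10, 0.5)
  expect_equal(st2$mean, 20)

  # off-grid records are excluded with a warning; empty input errors
  occ3 <- rbind(occ2, data.frame(lon = 50, lat = 50, source = "s"))
  expect_warning(st3 <- performanceStats(ei2, occ3), "excluded")
  expect_equal(st3$n, 4L)
  expect_error(performanceStats(ei2, occ2[0, ]), "no occurrence")
})
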