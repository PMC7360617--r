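# scipy.interpolate.Akima1DInterpolator values on a fixed dataset, frozen as
# an independent oracle for the in-package Akima implementation.
.akimaOracleX <- 0:10
.akimaOracleY <- c(0.5, -1.2, 3.4, 2.2, 2.0, -0.7, 0.3, 5.1, 4.9, -2.0, 1.5)
.akimaOracleXi <- c(0, 0.25, 0.5, 1.7, 3.14, 5.5, 7.75, 9.5, 9.9, 10)
.akimaOracleYi <- c(0.5, -0.521726497934, -1.153770661157, 2.565555892675,
                    2.14977800564, -0.680979748221, 5.405458603896,
                    -1.690643274854, 0.671873684211, 1.5)

test_that("grid constructor tiles stated ranges and enforces registration", {
  g <- makeGrid(0.5, c(-179.75, 179.75), c(-59.75, 89.75))
  expect_equal(nLon(g), 720L)
  expect_equal(nLat(g), 300L)
  expect_true(isPeriodicLon(g))
  expect_equal(gridRes(g), 0.5)

  g1 <- makeGrid(1, c(-179.5, 179.5), c(-89.5, 89.5))
  expect_equal(c(nLon(g1), nLat(g1)), c(360L, 180L))

  # centers not at edge + res/2
  expect_error(makeGrid(0.5, c(-179.75, 179.75), c(-59.6, 89.9)), "aligned|multiple")
  # range not an integer multiple of the resolution
  expect_error(makeGrid(0.5, c(-179.75, 179.6), c(-59.75, 89.75)), "multiple")
})

test_that("1-D Akima matches an independently computed oracle and its exact cases", {
  expect_equal(akima1(.akimaOracleX, .akimaOracleY, .akimaOracleXi),
               .akimaOracleYi, tolerance = 1e-10)
  x <- seq(0, 10, by = 1)
  xi <- c(0, 0.3, 2.71, 8.99, 10)
  expect_equal(akima1(x, 2 * x + 3, xi), 2 * xi + 3, tolerance = 1e-12)
  expect_equal(akima1(x, rep(7, 11), xi), rep(7, 5))
  expect_identical(akima1(x, .akimaOracleY, x), .akimaOracleY)
  expect_error(akima1(x, 2 * x, 11), "outside")
})

test_that("Akima regridding reproduces constants, linear fields and nodes", {
  src <- testField(nlon = 12, nlat = 10, res = 6, months = FALSE,
                   fun = function(lon, lat, m) 0 * lon + 4.5)
  tgt <- makeGrid(2, c(-33, 33), c(-27, 27))
  expect_equal(fieldValues(akimaRegrid(src, tgt)),
               matrix(4.5, nLon(tgt), nLat(tgt)))

  lin <- testField(nlon = 12, nlat = 10, res = 6, months = FALSE,
                   fun = function(lon, lat, m) 3 * lat - 2)
  out <- akimaRegrid(lin, tgt)
  expected <- outer(rep(1, nLon(tgt)), 3 * latCenters(tgt) - 2)
  expect_equal(fieldValues(out), expected, tolerance = 1e-10)

  # a factor-3 refinement's centers contain the source centers: restriction
  # back to source nodes is the identity
  rnd <- testField(nlon = 12, nlat = 10, res = 6, months = FALSE,
                   fun = function(lon, lat, m) sin(lon / 20) * cos(lat / 15))
  fine3 <- tgt
  o3 <- akimaRegrid(rnd, fine3)
  ii <- match(lonCenters(gridOf(rnd)), lonCenters(fine3))
  jj <- match(latCenters(gridOf(rnd)), latCenters(fine3))
  expect_false(anyNA(c(ii, jj)))
  expect_equal(fieldValues(o3)[ii, jj], fieldValues(rnd), tolerance = 1e-12)
})

test_that("Akima regridding commutes with constants and wraps the dateline", {
  src <- testField(nlon = 12, nlat = 4, res = 30, months = FALSE,
                   fun = function(lon, lat, m) sin(lon * pi / 90) + cos(lat / 40))
  expect_true(isPeriodicLon(gridOf(src)))
  tgt <- makeGrid(10, c(-175, 175), c(-55, 55))

  a <- akimaRegrid(src + 11.5, tgt)
  b <- akimaRegrid(src, tgt) + 11.5
  expect_equal(fieldValues(a), fieldValues(b), tolerance = 1e-12)

  # shifting the source by k columns shifts the (periodic) result by the
  # corresponding number of target columns
  k <- 3L                       # 3 * 30 deg = 90 deg = 9 target columns
  v <- fieldValues(src)
  shifted <- climField(gridOf(src), v[c((k + 1):12, 1:k), , drop = FALSE], variable = "T")
  os <- fieldValues(akimaRegrid(shifted, tgt))
  o <- fieldValues(akimaRegrid(src, tgt))
  expect_equal(os, o[c(10:36, 1:9), ], tolerance = 1e-10)
})

test_that("regridding refuses masked sources and clamps poleward targets", {
  src <- testField(nlon = 12, nlat = 10, res = 6, months = FALSE)
  msk <- fieldMask(src); msk[1, 1] <- FALSE
  holed <- climField(gridOf(src), fieldValues(src), mask = msk)
  expect_error(akimaRegrid(holed, gridOf(src)), "invalid cells")

  # target rows beyond the source's lat extent take the nearest source row
  wide <- makeGrid(3, c(-31.5, 31.5), c(-43.5, 43.5))
  lin <- testField(nlon = 12, nlat = 10, res = 6, months = FALSE,
                   fun = function(lon, lat, m) lat)
  out <- fieldValues(akimaRegrid(lin, wide))
  expect_equal(out[1, nLat(wide)], 27, tolerance = 1e-9)  # clamped to top row
})

test_that("IDW gap filling matches the all-pairs oracle and stays in range", {
  f <- testField(nlon = 12, nlat = 8, res = 5, months = FALSE,
                 fun = function(lon, lat, m) sin(lon / 30) + lat / 10)
  set.seed(42)
  msk <- matrix(runif(12 * 8) > 0.4, 12, 8)
  holed <- climField(gridOf(f), fieldValues(f), mask = msk)
  filled <- idwExtrapolate(holed, k = sum(msk))   # all donors -> oracle comparable
  expect_true(all(fieldMask(filled)))
  expect_equal(fieldValues(filled)[msk], fieldValues(f)[msk])  # donors untouched
  oracle <- oracleIDW(gridOf(f), fieldValues(f), msk)
  expect_equal(fieldValues(filled), oracle, tolerance = 1e-4)
  rng <- range(fieldValues(f)[msk])
  expect_true(all(fieldValues(filled) >= rng[1] & fieldValues(filled) <= rng[2]))
  # idempotent
  expect_equal(fieldValues(idwExtrapolate(filled)), fieldValues(filled))
})

test_that("IDW handles single donors and symmetric donor pairs", {
  f <- testField(nlon = 8, nlat = 4, res = 5, months = FALSE,
                 fun = function(lon, lat, m) 0 * lon)
  v <- fieldValues(f); v[] <- 0; v[2, 2] <- 3.25
  msk <- matrix(FALSE, 8, 4); msk[2, 2] <- TRUE
  one <- climField(gridOf(f), v, mask = msk)
  expect_equal(fieldValues(idwExtrapolate(one)),
               matrix(3.25, 8, 4))

  # hole equidistant from two donors with values 10 and 20 -> 15
  g <- makeGrid(10, c(-15, 15), c(-5, 5))     # 4 x 2
  v2 <- matrix(0, 4, 2); v2[1, 1] <- 10; v2[3, 1] <- 20
  m2 <- matrix(FALSE, 4, 2); m2[1, 1] <- TRUE; m2[3, 1] <- TRUE
  h <- climField(g, v2, mask = m2)
  expect_equal(fieldValues(idwExtrapolate(h, k = 2))[2, 1], 15)
  expect_error(idwExtrapolate(climField(g, v2, mask = matrix(FALSE, 4, 2))),
               "all cells invalid")
})
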