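bioclimInputs <- function(tFun, pFun, nlon = 8, nlat = 4, res = 15) {
  monthlyT <- testField(nlon, nlat, res, fun = tFun, variable = "T")
  monthlyP <- testField(nlon, nlat, res, fun = pFun, variable = "P")
  ep <- monthlyExtremeMaps(monthlyT)
  list(t = monthlyT, p = monthlyP, tmin = ep@coldest, tmax = ep@warmest)
}

asMat <- function(field) {
  v <- fieldValues(field)
  matrix(v, prod(dim(v)[1:2]), dim(v)[3])
}

test_that("constant climate gives zero seasonality and equal quarters", {
  x <- bioclimInputs(function(lon, lat, m) 10 + 0 * lon,
                     function(lon, lat, m) 50 + 0 * lon)
  bs <- deriveBioclim(x$t, x$p, x$tmin, x$tmax)
  L <- bioclimLayers(bs)
  expect_length(L, 17L)
  expect_true(all(fieldValues(L$BIO1) == 10))
  expect_true(all(fieldValues(L$BIO4) == 0))
  expect_true(all(fieldValues(L$BIO12) == 600))
  expect_true(all(fieldValues(L$BIO13) == 50))
  expect_true(all(fieldValues(L$BIO14) == 50))
  expect_true(all(fieldValues(L$BIO15) == 0))
  for (q in c("BIO16", "BIO17", "BIO18", "BIO19"))
    expect_true(all(fieldValues(L[[q]]) == 150))
})

test_that("a 1..12 degree temperature ramp gives the documented BIO1 and BIO4", {
  x <- bioclimInputs(function(lon, lat, m) m + 0 * lon,
                     function(lon, lat, m) 10 + 0 * lon)
  bs <- deriveBioclim(x$t, x$p, x$tmin, x$tmax)
  expect_true(all(fieldValues(bioclimLayers(bs)$BIO1) == 6.5))
  # population-form sd of 1..12: sqrt(143/12)
  expect_equal(unique(as.numeric(fieldValues(bioclimLayers(bs)$BIO4))),
               sqrt(143 / 12))
  bsS <- deriveBioclim(x$t, x$p, x$tmin, x$tmax, tempSeasonality = "sample")
  expect_equal(unique(as.numeric(fieldValues(bioclimLayers(bsS)$BIO4))),
               sd(1:12))
})

test_that("the wettest quarter wraps across the year boundary", {
  x <- bioclimInputs(function(lon, lat, m) m + 0 * lon,
                     function(lon, lat, m) ifelse(m %in% c(12, 1, 2), 100, 0) + 0 * lon)
  bs <- deriveBioclim(x$t, x$p, x$tmin, x$tmax)
  expect_true(all(fieldValues(bioclimLayers(bs)$BIO16) == 300))
  # Dec-Feb mean temperature (12 + 1 + 2)/3 = 5
  expect_true(all(fieldValues(bioclimLayers(bs)$BIO8) == 5))
})

test_that("quarter windows are circular and each month is counted thrice", {
  x <- bioclimInputs(function(lon, lat, m) m + lat / 10,
                     function(lon, lat, m) m^1.5 + abs(lon) / 20)
  qw <- quarterWindows(x$t, x$p)
  expect_length(qw, 12L)
  expect_equal(qw[[12]]$months, c(12L, 1L, 2L))
  expect_equal(unlist(lapply(qw, function(q) sort(q$months)))[1], 1L)
  allMonths <- unlist(lapply(qw, `[[`, "months"))
  expect_true(all(tabulate(allMonths, 12) == 3L))
  pSumAll <- Reduce(`+`, lapply(qw, `[[`, "pSum"))
  expect_equal(pSumAll, 3 * apply(fieldValues(x$p), c(1, 2), sum))
  # selected wettest window matches brute-force argmax at sampled cells
  pm <- asMat(x$p)
  qP <- vapply(qw, function(q) as.numeric(q$pSum), numeric(nrow(pm)))
  for (cell in c(1, 7, 19, 32)) {
    brute <- which.max(sapply(1:12, function(s)
      sum(pm[cell, ((s - 1 + 0:2) %% 12) + 1])))
    expect_equal(unname(which.max(qP[cell, ])), unname(brute))
  }
})

test_that("every layer matches the brute-force enumeration oracle on random climates", {
  set.seed(99)
  for (rep in 1:20) {
    x <- bioclimInputs(function(lon, lat, m) 0 * lon,
                       function(lon, lat, m) 0 * lon, nlon = 6, nlat = 4, res = 20)
    nl <- dim(fieldValues(x$t))[1]; np <- dim(fieldValues(x$t))[2]
    tv <- array(rnorm(nl * np * 12, 8, 10), dim = c(nl, np, 12))
    pv <- array(pmax(rnorm(nl * np * 12, 60, 50), 0), dim = c(nl, np, 12))
    g <- gridOf(x$t)
    monthlyT <- climField(g, tv, variable = "T")
    monthlyP <- climField(g, pv, variable = "P")
    ep <- monthlyExtremeMaps(monthlyT)
    bs <- deriveBioclim(monthlyT, monthlyP, ep@coldest, ep@warmest)
    oracle <- oracleBioclim(matrix(tv, nl * np, 12), matrix(pv, nl * np, 12),
                            as.numeric(fieldValues(ep@coldest)),
                            as.numeric(fieldValues(ep@warmest)))
    for (nm in colnames(oracle))
      expect_equal(as.numeric(fieldValues(bioclimLayers(bs)[[nm]])),
                   unname(oracle[, nm]), tolerance = 1e-12, label = nm)
  }
})

test_that("bioclim layers respect shift and cyclic-permutation symmetries", {
  set.seed(5)
  x <- bioclimInputs(function(lon, lat, m) sin(m) * 10 + lat / 5,
                     function(lon, lat, m) 40 + 30 * cos(2 * pi * m / 12) + abs(lat))
  bs <- deriveBioclim(x$t, x$p, x$tmin, x$tmax)
  # adding c to all monthly T shifts the temperature layers, fixes BIO4/BIO7
  ep2 <- monthlyExtremeMaps(x$t + 3)
  bs2 <- deriveBioclim(x$t + 3, x$p, ep2@coldest, ep2@warmest)
  for (nm in c("BIO1", "BIO5", "BIO6", "BIO8", "BIO9", "BIO10", "BIO11"))
    expect_equal(fieldValues(bioclimLayers(bs2)[[nm]]),
                 fieldValues(bioclimLayers(bs)[[nm]]) + 3, tolerance = 1e-12)
  for (nm in c("BIO4", "BIO7", "BIO12", "BIO13", "BIO14", "BIO15", "BIO16", "BIO17"))
    expect_equal(fieldValues(bioclimLayers(bs2)[[nm]]),
                 fieldValues(bioclimLayers(bs)[[nm]]), tolerance = 1e-12)
  # cyclic month permutation leaves order-free layers unchanged
  perm <- c(4:12, 1:3)
  tp <- climField(gridOf(x$t), fieldValues(x$t)[, , perm], variable = "T")
  pp <- climField(gridOf(x$p), fieldValues(x$p)[, , perm], variable = "P")
  bs3 <- deriveBioclim(tp, pp, x$tmin, x$tmax)
  for (nm in c("BIO1", "BIO4", "BIO12", "BIO13", "BIO14", "BIO15", "BIO16", "BIO17"))
    expect_equal(fieldValues(bioclimLayers(bs3)[[nm]]),
                 fieldValues(bioclimLayers(bs)[[nm]]), tolerance = 1e-12)
  # BIO7 invariant: BIO5 - BIO6, nonnegative
  expect_equal(fieldValues(bioclimLayers(bs)$BIO7),
               fieldValues(bioclimLayers(bs)$BIO5) - fieldValues(bioclimLayers(bs)$BIO6))
  expect_true(all(fieldValues(bioclimLayers(bs)$BIO7) >= 0))
  # BIO5/BIO6 equal the extremes-module outputs bit-for-bit
  expect_identical(fieldValues(bioclimLayers(bs)$BIO5), fieldValues(x$tmax))
  expect_identical(fieldValues(bioclimLayers(bs)$BIO6), fieldValues(x$tmin))
})
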