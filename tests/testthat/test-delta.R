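# small paired coarse/fine fields with a known fine-scale anomaly
makePair <- function(anomaly = 0, seedval = 1) {
  set.seed(seedval)
  coarse <- testField(nlon = 12, nlat = 6, res = 30,
                      fun = function(lon, lat, m) 10 * cos(lat * pi / 180) + m)
  fineGrid <- makeGrid(10, c(-175, 175), c(-85, 85))
  base <- akimaRegrid(coarse, fineGrid)
  fine <- base + anomaly
  list(coarse = coarse, fine = fine, base = base, fineGrid = fineGrid)
}

test_that("correction terms are the fine-minus-regridded-coarse anomaly", {
  p <- makePair(anomaly = 0)
  ct <- correctionTerm(p$fine, p$coarse, 21000)
  expect_equal(max(abs(fieldValues(ct@delta))), 0)

  p2 <- makePair(anomaly = 2)
  ct2 <- correctionTerm(p2$fine, p2$coarse, 21000)
  expect_equal(fieldValues(ct2@delta),
               array(2, dim = dim(fieldValues(ct2@delta))))

  # known smooth anomaly recovered exactly (oracle = direct subtraction)
  g <- p$fineGrid
  anom <- array(rnorm(nLon(g) * nLat(g) * 12), dim = c(nLon(g), nLat(g), 12))
  fine3 <- climField(g, fieldValues(p$base) + anom, variable = "T")
  ct3 <- correctionTerm(fine3, p$coarse, 18000)
  expect_equal(fieldValues(ct3@delta), anom, tolerance = 1e-12)

  single <- climField(g, fieldValues(p$base)[, , 1], variable = "T")
  expect_error(correctionTerm(single, p$coarse, 0), "month-dimension mismatch")
})

test_that("dynamic delta honours anchor identities, convexity and capping", {
  p <- makePair(anomaly = 3)
  cts <- list(correctionTerm(p$fine, p$coarse, 21000),
              correctionTerm(p$fine + 1, p$coarse, 0))
  bounds <- variableSpec("T")

  w <- c("21000" = 1, "0" = 0)
  out <- dynamicDelta(p$coarse, cts, w, bounds)
  expect_equal(fieldValues(out), fieldValues(p$fine), tolerance = 1e-12)

  # identical corrections: output independent of the weights (convexity)
  ctsSame <- list(correctionTerm(p$fine, p$coarse, 21000),
                  correctionTerm(p$fine, p$coarse, 0))
  o1 <- dynamicDelta(p$coarse, ctsSame, c("21000" = 0.3, "0" = 0.7), bounds)
  o2 <- dynamicDelta(p$coarse, ctsSame, c("21000" = 0.9, "0" = 0.1), bounds)
  expect_equal(fieldValues(o1), fieldValues(o2), tolerance = 1e-12)

  # translation equivariance in the (uncapped) input snapshot
  oShift <- dynamicDelta(p$coarse + 5, cts, c("21000" = 0.5, "0" = 0.5), bounds)
  oBase <- dynamicDelta(p$coarse, cts, c("21000" = 0.5, "0" = 0.5), bounds)
  expect_equal(fieldValues(oShift), fieldValues(oBase) + 5, tolerance = 1e-11)

  expect_error(dynamicDelta(p$coarse, cts, c("21000" = 0.6, "0" = 0.6), bounds),
               "sum to 1")
  expect_error(dynamicDelta(p$coarse, cts[1], w, bounds), "reference times")
})

test_that("capping clamps at bounds, counts events, and is idempotent", {
  g <- makeGrid(10, c(-175, 175), c(-25, 25))
  v <- array(50, dim = c(nLon(g), nLat(g), 12))
  v[1, 1, 3] <- 104; v[2, 2, 3] <- -6
  cl <- climField(g, v, variable = "C")
  capped <- capField(cl, variableSpec("C"))
  expect_equal(fieldValues(capped)[1, 1, 3], 100)
  expect_equal(fieldValues(capped)[2, 2, 3], 0)
  diag <- fieldMetadata(capped)$capping
  expect_equal(diag$nCapped[3], 2L)
  expect_equal(diag$maxExceedance[3], 6)
  expect_equal(sum(diag$nCapped[-3]), 0L)
  # idempotent; only out-of-bound cells altered
  again <- capField(capped, variableSpec("C"))
  expect_equal(fieldValues(again), fieldValues(capped))
  expect_equal(sum(fieldMetadata(again)$capping$nCapped), 0L)
  inb <- fieldValues(cl) >= 0 & fieldValues(cl) <= 100
  expect_equal(fieldValues(capped)[inb], fieldValues(cl)[inb])
  # temperature: capping is the identity
  tf <- climField(g, v - 200, variable = "T")
  expect_equal(fieldValues(capField(tf, variableSpec("T"))), fieldValues(tf))
})

test_that("classical delta anchors on observations and caps precipitation", {
  p <- makePair()
  obsGrid <- makeGrid(5, c(-177.5, 177.5), c(-82.5, 82.5))
  obs <- climField(obsGrid, array(rnorm(nLon(obsGrid) * nLat(obsGrid) * 12, 50, 10),
                                  dim = c(nLon(obsGrid), nLat(obsGrid), 12)),
                   variable = "T")
  out0 <- classicalDelta(p$fine, p$fine, obs, variableSpec("T"))
  expect_equal(fieldValues(out0), fieldValues(obs), tolerance = 1e-12)

  # no climate-change signal: output = observations
  other <- p$fine + 0   # distinct object, same values
  expect_equal(fieldValues(classicalDelta(other, p$fine, obs, variableSpec("T"))),
               fieldValues(obs), tolerance = 1e-12)

  # precipitation driven negative is capped at 0 and counted
  pObs <- climField(obsGrid, array(1, dim = c(nLon(obsGrid), nLat(obsGrid), 12)),
                    variable = "P")
  dry <- climField(p$fineGrid, fieldValues(p$fine) - 4, variable = "P")
  outP <- classicalDelta(dry, p$fine, pObs, variableSpec("P"))
  expect_true(all(fieldValues(outP) >= 0))
  expect_equal(fieldValues(outP)[1, 1, 1], 0)   # 1 - 4 = -3 -> 0
  expect_gt(sum(fieldMetadata(outP)$capping$nCapped), 0)

  masked <- climField(obsGrid, fieldValues(obs),
                      mask = matrix(c(FALSE, rep(TRUE, nLon(obsGrid) * nLat(obsGrid) - 1)),
                                    nLon(obsGrid), nLat(obsGrid)))
  expect_error(classicalDelta(p$fine, p$fine, masked, variableSpec("T")),
               "gap-fill")
})

test_that("multiplicative delta exhibits its documented failure modes", {
  obsGrid <- makeGrid(30, c(-165, 165), c(-45, 45))
  nl <- nLon(obsGrid); np <- nLat(obsGrid)
  mkF <- function(vals) climField(obsGrid, array(vals, dim = c(nl, np, 12)), variable = "P")
  simT <- mkF(8); sim0 <- mkF(4)
  obs <- mkF(10)
  ov <- fieldValues(obs); ov[3, 3, ] <- 0
  obs <- climField(obsGrid, ov, variable = "P")

  # zero-observation lock-in: obs 0 -> 0 forever, whatever the signal
  out <- multiplicativeDelta(simT, sim0, obs)
  expect_equal(fieldValues(out)[3, 3, ], rep(0, 12))
  expect_equal(fieldValues(multiplicativeDelta(mkF(100), sim0, obs))[3, 3, 1], 0)

  # unbounded growth as the simulated modern baseline tends to zero
  vals <- vapply(c(1, 0.1, 0.001), function(eps)
    fieldValues(multiplicativeDelta(simT, mkF(eps), obs))[1, 1, 1], numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_gt(vals[3], 1e4)

  # exact zero denominator: flagged undefined, not zeroed
  z0 <- fieldValues(sim0); z0[2, 2, ] <- 0
  outz <- multiplicativeDelta(simT, climField(obsGrid, z0, variable = "P"), obs)
  expect_false(fieldMask(outz)[2, 2])
  expect_gt(fieldMetadata(outz)$undefinedCells, 0)
})

test_that("additive delta is self-consistent under annual sums; multiplicative is not", {
  obsGrid <- makeGrid(30, c(-165, 165), c(-45, 45))
  nl <- nLon(obsGrid); np <- nLat(obsGrid)
  set.seed(11)
  mkR <- function(mu) climField(obsGrid,
    array(runif(nl * np * 12, mu * 0.5, mu * 1.5), dim = c(nl, np, 12)),
    variable = "P")
  simT <- mkR(40); sim0 <- mkR(60); obs <- mkR(55)
  annual <- function(f) climField(obsGrid, apply(fieldValues(f), c(1, 2), sum),
                                  variable = "P")
  noCap <- variableSpec("P", lower = -Inf, upper = Inf, units = "mm month-1")

  addMonthly <- classicalDelta(simT, sim0, obs, noCap)
  lhsAdd <- fieldValues(annual(addMonthly))
  rhsAdd <- fieldValues(classicalDelta(annual(simT), annual(sim0), annual(obs), noCap))
  expect_equal(lhsAdd, rhsAdd, tolerance = 1e-10)

  mulMonthly <- multiplicativeDelta(simT, sim0, obs)
  lhsMul <- fieldValues(annual(mulMonthly))
  rhsMul <- fieldValues(multiplicativeDelta(annual(simT), annual(sim0), annual(obs)))
  expect_gt(max(abs(lhsMul - rhsMul)), 1)
})

test_that("the two-stage pipeline anchors at the present and reaches the obs grid", {
  w <- makeWorld(worldSpec(seed = 4))
  res <- twoStagePipeline(w@coarse$T, w@fine$T, w@obs$T, w@co2,
                          variableSpec("T"), times = c(21000, 8000, 0))
  expect_s4_class(res, "SnapshotStack")
  expect_equal(snapshotTimes(res), c(21000, 8000, 0))
  expect_true(gridsIdentical(gridOf(snapshotFields(res)[[1]]), gridOf(w@obs$T)))
  i0 <- match(0, snapshotTimes(res))
  expect_equal(fieldValues(snapshotFields(res)[[i0]]), fieldValues(w@obs$T),
               tolerance = 1e-12)
  # with zero bias, zero noise and a CO2-independent fine-scale amplitude the
  # reconstruction tracks the generator truth closely at held-out times
  w0 <- makeWorld(worldSpec(seed = 5, biasAmp = 0, noiseSd = 0, fineAmp = 0))
  res0 <- twoStagePipeline(w0@coarse$T, w0@fine$T, w0@obs$T, w0@co2,
                           variableSpec("T"), times = c(40000, 0))
  truth <- w0@truthFun("T", gridOf(w0@obs$T), 40000)
  err <- fieldValues(snapshotFields(res0)[[1]]) - fieldValues(truth)
  expect_lt(sqrt(mean(err^2)), 0.1)
})
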