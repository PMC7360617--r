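#' Circular three-month quarter aggregates
#'
#' A "quarter" is any window of three consecutive months, circular across
#' the year boundary, so there are exactly 12 windows and each month belongs
#' to exactly 3 of them. Returns, per window start month, the member months,
#' the per-cell temperature mean and (when precipitation is supplied) the
#' per-cell precipitation sum. These windows underlie the quarter-based
#' bioclimatic layers (BIO8-BIO11, BIO16-BIO19).
#'
#' @param monthlyT 12-month [ClimField-class] of temperature.
#' @param monthlyP optional 12-month [ClimField-class] of precipitation on
#'   the same grid.
#' @return list of 12 entries, each with `startMonth`, `months` (the 3
#'   member months), `tMean` (matrix) and `pSum` (matrix or NULL).
#' @export
quarterWindows <- function(monthlyT, monthlyP = NULL) {
  if (nMonths(monthlyT) != 12L) stop("all 12 months are required")
  tv <- monthlyT@values
  pv <- if (!is.null(monthlyP)) {
    if (nMonths(monthlyP) != 12L) stop("all 12 months are required")
    if (!gridsIdentical(monthlyT@grid, monthlyP@grid)) stop("grid mismatch")
    monthlyP@values
  }
  lapply(1:12, function(s) {
    ms <- ((s - 1L + 0:2) %% 12L) + 1L
    list(startMonth = s, months = ms,
         tMean = (tv[, , ms[1]] + tv[, , ms[2]] + tv[, , ms[3]]) / 3,
         pSum = if (!is.null(pv)) pv[, , ms[1]] + pv[, , ms[2]] + pv[, , ms[3]])
  })
}

# per-cell argmax/argmin over a (ncell x 12) matrix; ties -> earliest window
.argSel <- function(mat, decreasing) {
  if (decreasing) max.col(mat, ties.method = "first")
  else max.col(-mat, ties.method = "first")
}

#' Derive the 17 bioclimatic variables
#'
#' Computes BIO1 and BIO4-BIO19 from monthly temperature, monthly
#' precipitation and the annual temperature extremes. BIO2 and BIO3 require
#' diurnal temperature range, which monthly means cannot provide, and are
#' therefore absent. Layer definitions:
#' \describe{
#'   \item{BIO1}{annual mean temperature (mean of the 12 monthly means, degC)}
#'   \item{BIO4}{temperature seasonality: standard deviation of the 12
#'     monthly temperatures, in degC. The 12 months are treated as the
#'     complete annual cycle (population form, divisor 12) by default;
#'     `tempSeasonality = "sample"` uses divisor 11 and `"worldclim"` the
#'     sample form scaled by 100.}
#'   \item{BIO5/BIO6}{maximum / minimum annual temperature, taken from the
#'     extremes module. (Some tabulations swap these two labels; here BIO5
#'     is always the maximum, consistent with BIO7 = BIO5 - BIO6 >= 0, and a
#'     note is recorded in the set's metadata.)}
#'   \item{BIO7}{temperature annual range, BIO5 - BIO6}
#'   \item{BIO8/BIO9}{mean temperature of the wettest / driest quarter}
#'   \item{BIO10/BIO11}{mean temperature of the warmest / coldest quarter}
#'   \item{BIO12}{annual precipitation (sum of months, mm/year)}
#'   \item{BIO13/BIO14}{precipitation of the wettest / driest month}
#'   \item{BIO15}{precipitation seasonality: coefficient of variation of
#'     monthly precipitation (population sd / mean, dimensionless), defined
#'     as 0 where the mean is 0; `precipSeasonality = "worldclim"` uses
#'     100 * sd / (mean + 1).}
#'   \item{BIO16/BIO17}{precipitation of the wettest / driest quarter}
#'   \item{BIO18/BIO19}{precipitation of the warmest / coldest quarter}
#' }
#' Quarters are circular three-month windows; ties between equally extreme
#' windows are broken by the earliest start month.
#'
#' @param monthlyT,monthlyP 12-month [ClimField-class] on a shared grid.
#' @param tMin,tMax single-layer [ClimField-class]: annual minimum / maximum
#'   temperature on the same grid (from [reconstructExtremes()]).
#' @param tempSeasonality BIO4 estimator: "population" (default), "sample"
#'   or "worldclim".
#' @param precipSeasonality BIO15 estimator: "cv" (default) or "worldclim".
#' @return a [BioclimSet-class] of 17 layers.
#' @export
deriveBioclim <- function(monthlyT, monthlyP, tMin, tMax,
                          tempSeasonality = c("population", "sample", "worldclim"),
                          precipSeasonality = c("cv", "worldclim")) {
  tempSeasonality <- match.arg(tempSeasonality)
  precipSeasonality <- match.arg(precipSeasonality)
  if (nMonths(monthlyT) != 12L || nMonths(monthlyP) != 12L)
    stop("all 12 months of T and P are required")
  g <- monthlyT@grid
  for (f in list(monthlyP, tMin, tMax))
    if (!gridsIdentical(g, f@grid)) stop("all inputs must share one grid")
  tv <- monthlyT@values; pv <- monthlyP@values
  nc <- nLon(g) * nLat(g)
  tm <- matrix(tv, nc, 12); pm <- matrix(pv, nc, 12)
  msk <- monthlyT@mask & monthlyP@mask & tMin@mask & tMax@mask

  tMean <- rowMeans(tm)
  tDev2 <- rowMeans((tm - tMean)^2)
  bio4 <- switch(tempSeasonality,
    population = sqrt(tDev2),
    sample     = sqrt(tDev2 * 12 / 11),
    worldclim  = 100 * sqrt(tDev2 * 12 / 11))
  pTot <- rowSums(pm)
  pMean <- pTot / 12
  pSd <- sqrt(rowMeans((pm - pMean)^2))
  bio15 <- switch(precipSeasonality,
    cv = ifelse(pMean == 0, 0, pSd / pMean),
    worldclim = 100 * sqrt(rowMeans((pm - pMean)^2) * 12 / 11) / (pMean + 1))

  qw <- quarterWindows(monthlyT, monthlyP)
  qT <- vapply(qw, function(q) as.numeric(q$tMean), numeric(nc))
  qP <- vapply(qw, function(q) as.numeric(q$pSum), numeric(nc))
  pick <- function(mat, idx) mat[cbind(seq_len(nc), idx)]
  wet <- .argSel(qP, TRUE);  dry <- .argSel(qP, FALSE)
  hot <- .argSel(qT, TRUE);  cold <- .argSel(qT, FALSE)

  shape <- c(nLon(g), nLat(g))
  lay <- function(vals, name, units) new("ClimField", grid = g, variable = name,
    values = array(vals, dim = shape), mask = msk, units = units, metadata = list())
  layers <- list(
    BIO1  = lay(tMean, "BIO1", "degC"),
    BIO4  = lay(bio4, "BIO4", if (tempSeasonality == "worldclim") "degC*100" else "degC"),
    BIO5  = lay(tMax@values, "BIO5", "degC"),
    BIO6  = lay(tMin@values, "BIO6", "degC"),
    BIO7  = lay(tMax@values - tMin@values, "BIO7", "degC"),
    BIO8  = lay(pick(qT, wet), "BIO8", "degC"),
    BIO9  = lay(pick(qT, dry), "BIO9", "degC"),
    BIO10 = lay(pick(qT, hot), "BIO10", "degC"),
    BIO11 = lay(pick(qT, cold), "BIO11", "degC"),
    BIO12 = lay(pTot, "BIO12", "mm year-1"),
    BIO13 = lay(apply(pm, 1, max), "BIO13", "mm month-1"),
    BIO14 = lay(apply(pm, 1, min), "BIO14", "mm month-1"),
    BIO15 = lay(bio15, "BIO15", "1"),
    BIO16 = lay(pick(qP, wet), "BIO16", "mm quarter-1"),
    BIO17 = lay(pick(qP, dry), "BIO17", "mm quarter-1"),
    BIO18 = lay(pick(qP, hot), "BIO18", "mm quarter-1"),
    BIO19 = lay(pick(qP, cold), "BIO19", "mm quarter-1"))
  new("BioclimSet", layers = layers,
      metadata = list(tempSeasonality = tempSeasonality,
                      precipSeasonality = precipSeasonality,
                      note = "BIO5 is the annual maximum and BIO6 the annual minimum temperature, so that BIO7 = BIO5 - BIO6 is nonnegative"))
}
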