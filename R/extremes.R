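#' Coldest- and warmest-month mean temperature maps
#'
#' Per-cell minimum and maximum over the 12-month dimension of a monthly
#' temperature field. Diurnal temperature data are not available from the
#' monthly simulation output, so annual temperature extremes are
#' reconstructed from these monthly-mean extremes (see
#' [reconstructExtremes()]).
#'
#' @param monthlyT a 12-month [ClimField-class] of temperature (degC).
#' @return an [ExtremePair-class] of single-layer fields.
#' @export
monthlyExtremeMaps <- function(monthlyT) {
  if (nMonths(monthlyT) != 12L) stop("all 12 months are required")
  v <- monthlyT@values
  mk <- function(vals, what) new("ClimField", grid = monthlyT@grid,
    variable = what, values = array(vals, dim = dim(v)[1:2]),
    mask = monthlyT@mask, units = monthlyT@units, metadata = monthlyT@metadata)
  new("ExtremePair",
      coldest = mk(apply(v, c(1, 2), min), "coldest_month_T"),
      warmest = mk(apply(v, c(1, 2), max), "warmest_month_T"))
}

#' Reconstruct past annual temperature extremes
#'
#' Estimates minimum and maximum annual temperature at a past time from the
#' coldest/warmest-month means of the downscaled simulation and modern
#' observed annual extremes:
#' `Tmin(t) = regrid(cold_t) + obs_min_0 - regrid(cold_0)` and analogously
#' for the maximum. This assumes the past-minus-present anomaly of the
#' coldest (warmest) month mean matches that of the coldest (warmest) day.
#' Temperature is unbounded, so no capping is applied. Cells where the
#' reconstructed minimum exceeds the maximum (possible because the two
#' anomalies are applied independently) are counted in the returned fields'
#' metadata under `$orderingViolations` and reported, never repaired.
#'
#' @param coldT,warmT single-layer [ClimField-class]: coldest/warmest-month
#'   means at the target time (stage-1 grid).
#' @param cold0,warm0 the same at time 0.
#' @param obsMin0,obsMax0 all-valid observed modern annual extremes on the
#'   target (observation) grid.
#' @return list with elements `tmin` and `tmax` ([ClimField-class]).
#' @export
reconstructExtremes <- function(coldT, warmT, cold0, warm0, obsMin0, obsMax0) {
  if (!all(obsMin0@mask) || !all(obsMax0@mask))
    stop("observed extremes contain invalid cells; gap-fill first")
  tgt <- obsMin0@grid
  if (!gridsIdentical(tgt, obsMax0@grid)) stop("observed extremes on different grids")
  tmin <- akimaRegrid(coldT, tgt) + obsMin0 - akimaRegrid(cold0, tgt)
  tmax <- akimaRegrid(warmT, tgt) + obsMax0 - akimaRegrid(warm0, tgt)
  viol <- sum(tmin@values > tmax@values)
  if (viol > 0)
    message(sprintf("reconstructExtremes: min > max at %d cells (anomalies applied independently)", viol))
  addMd <- function(f, var) {
    md <- f@metadata; md$orderingViolations <- viol
    new("ClimField", grid = f@grid, variable = var, values = f@values,
        mask = f@mask, units = f@units, metadata = md)
  }
  list(tmin = addMd(tmin, "min_annual_T"), tmax = addMd(tmax, "max_annual_T"))
}
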