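.VARIABLE_SPECS <- list(
  T = list(lower = -Inf, upper = Inf, units = "degC"),
  P = list(lower = 0,    upper = Inf, units = "mm month-1"),
  C = list(lower = 0,    upper = 100, units = "%"),
  H = list(lower = 0,    upper = 100, units = "%"),
  W = list(lower = 0,    upper = Inf, units = "m s-1")
)

#' Physical bounds preset for a climate variable
#'
#' Temperature (T) is unbounded; precipitation (P, mm/month) and wind speed
#' (W, m/s) are nonnegative; cloudiness (C) and relative humidity (H) lie in
#' \[0, 100\] percent. Corrected fields are capped at these bounds after each
#' delta stage.
#'
#' @param variable one of "T", "P", "C", "H", "W", or any id when `lower`,
#'   `upper` and `units` are supplied explicitly.
#' @param lower,upper,units explicit overrides for non-preset variables.
#' @return a [VariableSpec-class].
#' @export
variableSpec <- function(variable, lower = NULL, upper = NULL, units = NULL) {
  p <- .VARIABLE_SPECS[[variable]]
  if (is.null(p) && (is.null(lower) || is.null(upper) || is.null(units)))
    stop(sprintf("no bounds preset for variable '%s'; supply lower/upper/units", variable))
  new("VariableSpec", variable = variable,
      lower = if (is.null(lower)) p$lower else lower,
      upper = if (is.null(upper)) p$upper else upper,
      units = if (is.null(units)) p$units else units)
}

#' Cap a field at its physical bounds
#'
#' Clamps values to `[lower, upper]` of the variable's bounds and records,
#' in the returned field's metadata under `$capping`, the number of capped
#' cells and the maximum exceedance per month -- the diagnostic used to check
#' that capping only touches a very small number of points close to the
#' bounds. Idempotent, and the identity for unbounded variables such as
#' temperature.
#'
#' @param field a [ClimField-class].
#' @param bounds a [VariableSpec-class].
#' @return the capped [ClimField-class].
#' @export
capField <- function(field, bounds) {
  v <- .asMonthArray(field)
  nm <- dim(v)[3]
  nCap <- integer(nm); maxEx <- numeric(nm)
  for (k in seq_len(nm)) {
    s <- v[, , k]
    below <- s < bounds@lower; above <- s > bounds@upper
    below[is.na(below)] <- FALSE; above[is.na(above)] <- FALSE
    nCap[k] <- sum(below) + sum(above)
    maxEx[k] <- max(0,
                    if (any(below)) max(bounds@lower - s[below]) else 0,
                    if (any(above)) max(s[above] - bounds@upper) else 0)
    s[below] <- bounds@lower; s[above] <- bounds@upper
    v[, , k] <- s
  }
  md <- field@metadata
  md$capping <- data.frame(month = seq_len(nm), nCapped = nCap, maxExceedance = maxEx)
  .withValues(field, if (length(dim(field@values)) == 2L) array(v[, , 1L], dim = dim(v)[1:2]) else v,
              metadata = md)
}

#' Fine-grid correction term at a reference time
#'
#' The per-month difference between a high-resolution simulation snapshot
#' and the coarse simulation regridded (Akima) to the fine grid:
#' `delta(m, tau) = fine(m, tau) - regrid(coarse(m, tau))`. These anomalies
#' carry the fine-scale heterogeneity (orographic gradients, coastlines)
#' missing from the coarse model.
#'
#' @param fineSim 12-month [ClimField-class] on the fine grid.
#' @param coarseSim 12-month [ClimField-class] on the coarse grid, same
#'   variable and units.
#' @param tau reference time (years BP).
#' @return a [CorrectionTerm-class].
#' @export
correctionTerm <- function(fineSim, coarseSim, tau) {
  if (nMonths(fineSim) != nMonths(coarseSim))
    stop("month-dimension mismatch between fine and coarse snapshots")
  if (fineSim@units != coarseSim@units)
    stop("unit mismatch between fine and coarse snapshots")
  delta <- fineSim - akimaRegrid(coarseSim, fineSim@grid)
  new("CorrectionTerm", tau = tau, delta = delta)
}

#' Stage 1: the Dynamic Delta Method
#'
#' Downscales a coarse simulation snapshot to the fine grid by adding a
#' time-variable correction term: the CO2-similarity-weighted sum of the
#' fine-grid correction terms at the reference times,
#' `X'(m, t) = regrid(coarse_t)(m) + sum_tau w(t, tau) * delta(m, tau)`,
#' followed by capping at the variable's physical bounds. With indicator
#' weights (t equal to a reference time) the pre-capping output equals the
#' high-resolution simulation exactly.
#'
#' @param coarseT 12-month [ClimField-class] at the target time, coarse grid.
#' @param corrections list of [CorrectionTerm-class], one per reference time.
#' @param weights named weight vector from [co2Weights()]; names must cover
#'   exactly the corrections' reference times and sum to 1.
#' @param bounds a [VariableSpec-class].
#' @return capped [ClimField-class] on the fine grid; capping diagnostics in
#'   `fieldMetadata(x)$capping`.
#' @export
dynamicDelta <- function(coarseT, corrections, weights, bounds) {
  taus <- vapply(corrections, function(ct) ct@tau, numeric(1))
  if (!setequal(names(weights), as.character(taus)))
    stop("weights must cover exactly the corrections' reference times")
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  fineGrid <- corrections[[1]]@delta@grid
  if (coarseT@units != corrections[[1]]@delta@units)
    stop("unit mismatch between snapshot and correction terms")
  out <- akimaRegrid(coarseT, fineGrid)
  for (ct in corrections) {
    w <- weights[[as.character(ct@tau)]]
    if (w != 0) out <- out + w * ct@delta
  }
  capField(out, bounds)
}

#' Stage 2: the classical additive Delta Method
#'
#' Bias-corrects and downscales a simulated snapshot to the observation grid
#' by adding the modern-era correction term:
#' `X(m, t) = regrid(sim_t)(m) + obs_0(m) - regrid(sim_0)(m)`, followed by
#' capping. At t = 0 the output is identical to the observations. The
#' observational field must be gap-filled (all-valid) first, so the method
#' stays applicable where lower sea level exposes present-day ocean cells.
#'
#' @param simT [ClimField-class] at the target time (fine grid).
#' @param sim0 [ClimField-class] at time 0 on the same grid as `simT`.
#' @param obs0 all-valid [ClimField-class] on the target (observation) grid.
#' @param bounds a [VariableSpec-class].
#' @return capped [ClimField-class] on the observation grid.
#' @export
classicalDelta <- function(simT, sim0, obs0, bounds) {
  if (!all(obs0@mask))
    stop("observations contain invalid cells; gap-fill first (idwExtrapolate)")
  tgt <- obs0@grid
  out <- akimaRegrid(simT, tgt) + obs0 - akimaRegrid(sim0, tgt)
  capField(out, bounds)
}

#' Multiplicative Delta comparator
#'
#' The multiplicative variant `P(m, t) = regrid(sim_t) * obs_0 /
#' regrid(sim_0)` (equivalent to an additive delta on log-transformed data).
#' Provided for comparison experiments only: it locks any cell with zero
#' modern observation to zero at all times, grows without bound as the
#' simulated modern baseline approaches zero, and is not self-consistent
#' under annual summation. Cells with a zero denominator are flagged invalid
#' (counted in metadata under `$undefinedCells`), never silently zeroed.
#'
#' @inheritParams classicalDelta
#' @return [ClimField-class] on the observation grid with undefined cells
#'   masked.
#' @export
multiplicativeDelta <- function(simT, sim0, obs0) {
  if (!all(obs0@mask))
    stop("observations contain invalid cells; gap-fill first (idwExtrapolate)")
  tgt <- obs0@grid
  num <- akimaRegrid(simT, tgt)
  den <- akimaRegrid(sim0, tgt)
  dv <- .asMonthArray(den)
  undef <- apply(dv == 0, c(1, 2), any)
  v <- .asMonthArray(num) * .asMonthArray(obs0) / dv
  v[is.infinite(v) | is.nan(v)] <- NA_real_
  v[array(undef, dim = dim(v))] <- NA_real_
  if (length(dim(num@values)) == 2L) v <- array(v[, , 1L], dim = dim(undef))
  md <- num@metadata
  md$undefinedCells <- sum(undef)
  new("ClimField", grid = tgt, variable = num@variable, values = v,
      mask = num@mask & obs0@mask & !undef, units = num@units, metadata = md)
}

#' The full two-stage downscaling pipeline
#'
#' For each time on the coarse stack's axis: stage 1 applies the Dynamic
#' Delta Method (CO2-weighted correction terms from the fine reference
#' stack) to reach the fine-simulation grid; stage 2 applies the classical
#' additive Delta Method against the gap-filled modern observations to reach
#' the observation grid. Capping happens after each stage. At t = 0 the
#' final field equals the observations exactly.
#'
#' @param coarseStack [SnapshotStack-class] on the long (e.g. 120 kyr) axis.
#' @param fineStack [SnapshotStack-class] on the reference (21 kyr) axis;
#'   its times must be a subset of the coarse axis.
#' @param obs0 all-valid monthly [ClimField-class] on the observation grid.
#' @param co2 data.frame (time_BP, co2_ppm) covering both axes.
#' @param bounds a [VariableSpec-class].
#' @param times subset of the coarse axis to reconstruct (default: all);
#'   time 0 is always included as the modern anchor.
#' @param verbose logical; message per-time capping counts.
#' @return [SnapshotStack-class] on the observation grid; each field carries
#'   stage-2 capping diagnostics in its metadata, and `$stage1Capping` holds
#'   the stage-1 diagnostic.
#' @export
twoStagePipeline <- function(coarseStack, fineStack, obs0, co2, bounds,
                             times = coarseStack@times, verbose = FALSE) {
  refs <- fineStack@times
  if (!all(refs %in% coarseStack@times))
    stop("reference times must be a subset of the coarse axis")
  if (!all(times %in% coarseStack@times))
    stop("requested times not on the coarse axis")
  times <- sort(unique(c(times, 0)), decreasing = TRUE)
  corrections <- lapply(seq_along(refs), function(i)
    correctionTerm(fineStack@fields[[i]], coarseStack@fields[[match(refs[i], coarseStack@times)]],
                   refs[i]))
  stage1 <- lapply(times, function(t) {
    w <- co2Weights(t, co2, refs)
    dynamicDelta(coarseStack@fields[[match(t, coarseStack@times)]], corrections,
                 w, bounds)
  })
  s1zero <- stage1[[match(0, times)]]
  fields <- lapply(seq_along(stage1), function(i) {
    f <- classicalDelta(stage1[[i]], s1zero, obs0, bounds)
    md <- f@metadata
    md$stage1Capping <- stage1[[i]]@metadata$capping
    if (verbose)
      message(sprintf("t = %6d BP: stage1 capped %d, stage2 capped %d cells",
                      times[i], sum(md$stage1Capping$nCapped),
                      sum(md$capping$nCapped)))
    new("ClimField", grid = f@grid, variable = f@variable, values = f@values,
        mask = f@mask, units = f@units, metadata = md)
  })
  snapshotStack(times, fields, coarseStack@variable)
}
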