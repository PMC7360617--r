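#' @import methods
NULL

#' Equirectangular cell-centered latitude-longitude grid
#'
#' A regular lat-lon raster with uniform angular spacing and cell-centered
#' registration: cell edges fall on integer multiples of the resolution, so a
#' global 0.5 degree grid has centers at ...-0.25, 0.25, 0.75... . Longitude
#' is stored in degrees east within (-180, 180], ascending; latitude in
#' degrees north, ascending, strictly inside (-90, 90).
#'
#' @slot lon numeric, longitude cell centers (degrees east, ascending).
#' @slot lat numeric, latitude cell centers (degrees north, ascending).
#' @slot res numeric(1), grid step in degrees (shared by both axes).
#' @slot periodicLon logical(1), TRUE when the longitudes tile the full
#'   360-degree circle, so interpolation wraps across the dateline.
#'
#' @seealso [makeGrid()]
#' @export
setClass("ClimGrid",
  representation(lon = "numeric", lat = "numeric", res = "numeric",
                 periodicLon = "logical"),
  validity = function(object) {
    msg <- character()
    tol <- 1e-8 * max(object@res, 1)
    if (length(object@res) != 1L || object@res <= 0)
      msg <- c(msg, "res must be a single positive number")
    for (ax in c("lon", "lat")) {
      v <- slot(object, ax)
      if (length(v) < 1L) msg <- c(msg, paste(ax, "centers empty"))
      if (length(v) > 1L) {
        d <- diff(v)
        if (any(d <= 0)) msg <- c(msg, paste(ax, "centers must be ascending"))
        if (max(abs(d - object@res)) > tol)
          msg <- c(msg, paste(ax, "spacing not uniform at the stated resolution"))
      }
    }
    if (any(object@lat <= -90 | object@lat >= 90))
      msg <- c(msg, "latitude centers must lie strictly inside (-90, 90)")
    span <- diff(range(object@lon)) + object@res
    if (span > 360 + tol) msg <- c(msg, "longitude span exceeds 360 degrees")
    if (length(msg)) msg else TRUE
  })

#' Gridded climate variable
#'
#' A variable on a [ClimGrid-class], optionally with a 12-month dimension.
#' Values are stored as an array of dim (nlon, nlat) or (nlon, nlat, 12),
#' longitude fastest. The validity mask is shared across months; values must
#' be finite wherever the mask is TRUE (masked cells may hold NA).
#'
#' @slot grid a [ClimGrid-class].
#' @slot variable character(1), variable id ("T", "P", "C", "H", "W" or a
#'   derived-layer name).
#' @slot values numeric array, dim (nlon, nlat) or (nlon, nlat, 12).
#' @slot mask logical matrix (nlon, nlat); TRUE = valid cell.
#' @slot units character(1).
#' @slot metadata list of free-form annotations (e.g. capping diagnostics).
#'
#' @seealso [climField()]
#' @export
setClass("ClimField",
  representation(grid = "ClimGrid", variable = "character", values = "array",
                 mask = "matrix", units = "character", metadata = "list"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@values)
    nl <- length(object@grid@lon); np <- length(object@grid@lat)
    if (!(length(d) %in% c(2L, 3L)))
      msg <- c(msg, "values must have dim (nlon, nlat) or (nlon, nlat, 12)")
    else {
      if (d[1] != nl || d[2] != np)
        msg <- c(msg, "values dims do not match the grid")
      if (length(d) == 3L && d[3] != 12L)
        msg <- c(msg, "month dimension, when present, must have length 12")
    }
    if (!identical(dim(object@mask), c(nl, np)))
      msg <- c(msg, "mask dims do not match the grid")
    v <- object@values
    bad <- if (length(dim(v)) == 3L) apply(!is.finite(v), c(1, 2), any) else !is.finite(v)
    if (any(bad & object@mask))
      msg <- c(msg, "non-finite values at cells flagged valid")
    if (length(msg)) msg else TRUE
  })

#' Physical bounds and units of a climate variable
#'
#' Temperature is unbounded; precipitation and wind speed are bounded below
#' by 0; cloudiness and relative humidity lie in \[0, 100\] percent. Corrected
#' fields are capped (clamped) at these bounds after each delta stage.
#'
#' @slot variable character(1) variable id.
#' @slot lower numeric(1), lower bound (-Inf if none).
#' @slot upper numeric(1), upper bound (Inf if none).
#' @slot units character(1).
#'
#' @seealso [variableSpec()]
#' @export
setClass("VariableSpec",
  representation(variable = "character", lower = "numeric", upper = "numeric",
                 units = "character"),
  validity = function(object) {
    if (object@lower > object@upper) "lower bound exceeds upper bound" else TRUE
  })

#' Fine-grid correction term at a reference time
#'
#' The per-month anomaly between a high-resolution simulation snapshot and
#' the coarse simulation regridded to the fine grid, at one reference time
#' tau. These anomalies carry the fine-scale spatial heterogeneity that the
#' Dynamic Delta Method transfers to other times.
#'
#' @slot tau numeric(1), reference time (years BP).
#' @slot delta a 12-month [ClimField-class] on the fine simulation grid.
#'
#' @seealso [correctionTerm()]
#' @export
setClass("CorrectionTerm",
  representation(tau = "numeric", delta = "ClimField"),
  validity = function(object) {
    if (length(dim(object@delta@values)) != 3L)
      "correction term must hold all 12 months" else TRUE
  })

#' Stack of monthly snapshots along a time axis
#'
#' One monthly [ClimField-class] per entry of a years-BP time axis (ordered
#' oldest to youngest, i.e. strictly decreasing BP), sharing grid and units.
#'
#' @slot variable character(1).
#' @slot times numeric, years BP, strictly decreasing.
#' @slot fields list of [ClimField-class], one per time.
#' @slot units character(1).
#'
#' @seealso [snapshotStack()]
#' @export
setClass("SnapshotStack",
  representation(variable = "character", times = "numeric", fields = "list",
                 units = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@fields) != length(object@times))
      msg <- c(msg, "one field per time required")
    if (length(object@times) > 1L && any(diff(object@times) >= 0))
      msg <- c(msg, "times must be strictly decreasing (oldest first, years BP)")
    if (any(object@times < 0)) msg <- c(msg, "times must be >= 0 BP")
    if (length(object@fields)) {
      g1 <- object@fields[[1]]@grid
      same <- vapply(object@fields, function(f)
        isTRUE(all.equal(f@grid@lon, g1@lon)) && isTRUE(all.equal(f@grid@lat, g1@lat)),
        logical(1))
      if (!all(same)) msg <- c(msg, "all fields must share one grid")
      u <- vapply(object@fields, function(f) f@units, character(1))
      if (length(unique(u)) > 1L) msg <- c(msg, "all fields must share units")
    }
    if (length(msg)) msg else TRUE
  })

#' Coldest- and warmest-month mean temperature maps
#'
#' @slot coldest single-layer [ClimField-class] (degC).
#' @slot warmest single-layer [ClimField-class] (degC).
#' @export
setClass("ExtremePair",
  representation(coldest = "ClimField", warmest = "ClimField"),
  validity = function(object) {
    w <- object@warmest@values; c0 <- object@coldest@values
    ok <- object@warmest@mask & object@coldest@mask
    if (any((w < c0)[ok])) "warmest < coldest at a valid cell" else TRUE
  })

#' Sea-level-driven land configuration
#'
#' Per-cell category: 0 = ocean (connected to the open-ocean seed), 1 = land
#' (above sea level), 2 = inland depression at or below sea level that is not
#' connected to the ocean (endorheic basins such as the Caspian or Dead Sea,
#' which keep their climate values under masking).
#'
#' @slot grid a [ClimGrid-class].
#' @slot category integer matrix (nlon, nlat) with values in 0:2.
#' @slot seaLevel numeric(1), metres relative to modern.
#'
#' @seealso [landConfiguration()]
#' @export
setClass("LandMask",
  representation(grid = "ClimGrid", category = "matrix", seaLevel = "numeric"),
  validity = function(object) {
    if (!all(object@category %in% 0:2)) "category codes must be 0, 1 or 2" else TRUE
  })

#' Boolean ice-sheet cover at one time
#'
#' @slot grid a [ClimGrid-class].
#' @slot cover logical matrix (nlon, nlat); TRUE = ice-sheet covered.
#' @slot time numeric(1), years BP.
#' @export
setClass("IceMask",
  representation(grid = "ClimGrid", cover = "matrix", time = "numeric"),
  validity = function(object) {
    if (!is.logical(object@cover)) "cover must be logical" else TRUE
  })

.BIOCLIM_LAYERS <- c("BIO1", paste0("BIO", 4:19))

#' Set of 17 bioclimatic layers
#'
#' The layers BIO1 and BIO4-BIO19 derived from monthly temperature and
#' precipitation plus annual temperature extremes. BIO2 and BIO3 require
#' diurnal temperature range and are not derivable from monthly means.
#'
#' @slot layers named list of 17 single-layer [ClimField-class] objects.
#' @slot metadata list (estimator choices, layer-label notes).
#' @export
setClass("BioclimSet",
  representation(layers = "list", metadata = "list"),
  validity = function(object) {
    if (!identical(names(object@layers), .BIOCLIM_LAYERS))
      return("layers must be exactly BIO1, BIO4..BIO19, in order")
    TRUE
  })

#' Parameters of a synthetic test world
#'
#' Defines a seeded, fully reproducible miniature analogue of the real input
#' constellation: an analytic truth made of a large-scale smooth component
#' plus an orography-linked fine-scale pattern whose amplitude depends on
#' CO2, a coarse simulation (block-aggregated truth plus a fixed additive
#' bias), fine simulations at the 21 kyr reference times (truth plus small
#' noise), an observational field at time 0, elevation, a sea-level curve
#' tied to CO2, and ice masks. Identical spec and seed give a bit-identical
#' world.
#'
#' @slot seed integer(1).
#' @slot coarseRes,fineRes,obsRes numeric(1), grid steps in degrees (nested).
#' @slot latLimit numeric(1), domain half-width in latitude (cell edges at
#'   +/- latLimit).
#' @slot co2Mid,co2Amp,co2Period numeric(1), CO2 curve ppm midpoint,
#'   amplitude and period (years).
#' @slot biasAmp numeric(1), amplitude of the fixed additive coarse-model
#'   bias (variable units).
#' @slot fineAmp numeric(1), CO2 sensitivity of the fine-scale anomaly
#'   amplitude g(CO2) = 1 + fineAmp * (280 - CO2) / 90.
#' @slot noiseSd numeric(1), sd of noise added to fine simulations.
#' @slot seaLevelDrop numeric(1), metres of sea-level fall at CO2 = 190 ppm.
#' @slot variables character, which variables to generate ("T", "P").
#' @seealso [worldSpec()], [makeWorld()]
#' @export
setClass("WorldSpec",
  representation(seed = "integer", coarseRes = "numeric", fineRes = "numeric",
                 obsRes = "numeric", latLimit = "numeric", co2Mid = "numeric",
                 co2Amp = "numeric", co2Period = "numeric", biasAmp = "numeric",
                 fineAmp = "numeric", noiseSd = "numeric",
                 seaLevelDrop = "numeric", variables = "character"),
  validity = function(object) {
    msg <- character()
    r <- c(object@coarseRes, object@fineRes, object@obsRes)
    if (any(r <= 0)) msg <- c(msg, "resolutions must be positive")
    if (object@coarseRes < object@fineRes || object@fineRes < object@obsRes)
      msg <- c(msg, "grids must be ordered coarse >= fine >= obs")
    ratio1 <- object@coarseRes / object@fineRes
    ratio2 <- object@fineRes / object@obsRes
    if (abs(ratio1 - round(ratio1)) > 1e-9 || abs(ratio2 - round(ratio2)) > 1e-9)
      msg <- c(msg, "grid resolutions must nest by integer factors")
    if (!all(object@variables %in% c("T", "P")))
      msg <- c(msg, "variables must be a subset of c('T', 'P')")
    if (length(msg)) msg else TRUE
  })

#' A generated synthetic world
#'
#' @slot spec the [WorldSpec-class] that produced it.
#' @slot co2 data.frame (time_BP, co2_ppm) on the 120 kyr axis.
#' @slot seaLevel data.frame (time_BP, sea_level_m).
#' @slot elevation single-layer [ClimField-class] on the observation grid (m).
#' @slot coarse named list (per variable) of [SnapshotStack-class] on the
#'   120 kyr axis, coarse grid.
#' @slot fine named list (per variable) of [SnapshotStack-class] on the
#'   21 kyr axis, fine grid.
#' @slot obs named list (per variable) of monthly [ClimField-class] at time 0
#'   on the observation grid.
#' @slot iceMasks list of [IceMask-class], one per 120 kyr axis time.
#' @slot truthFun function(variable, grid, t) returning the noise-free truth
#'   as a 12-month [ClimField-class] on any requested grid.
#' @export
setClass("SyntheticWorld",
  representation(spec = "WorldSpec", co2 = "data.frame", seaLevel = "data.frame",
                 elevation = "ClimField", coarse = "list", fine = "list",
                 obs = "list", iceMasks = "list", truthFun = "function"))
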