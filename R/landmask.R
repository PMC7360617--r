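#' Sea-level-driven land configuration
#'
#' Classifies each cell by elevation against a sea level: cells above sea
#' level are land; cells at or below sea level that are 4-connected (with
#' longitude wrap, no diagonals) to the designated open-ocean seed are ocean;
#' the remaining depressions are inland-below-sea-level (endorheic basins
#' such as the Caspian, Aral or Dead Sea), which keep their climate values
#' under masking. The flood fill is a vectorized breadth-first frontier
#' expansion, so the ocean is a single wrap-connected component containing
#' the seed by construction.
#'
#' @param elevation single-layer, all-valid [ClimField-class] of elevation /
#'   bathymetry in metres (positive above modern sea level).
#' @param seaLevel sea level in metres relative to modern (negative during
#'   glacials).
#' @param oceanSeed numeric(2) `c(lon, lat)` of a point in the open ocean;
#'   default the deepest cell of the elevation field. Must lie at or below
#'   `seaLevel`.
#' @return a [LandMask-class].
#' @export
landConfiguration <- function(elevation, seaLevel, oceanSeed = NULL) {
  if (!all(elevation@mask)) stop("elevation must be defined everywhere")
  g <- elevation@grid
  e <- elevation@values
  if (length(dim(e)) == 3L) stop("elevation must be a single-layer field")
  if (is.null(oceanSeed)) {
    ij <- arrayInd(which.min(e), dim(e))
    seed <- c(ij[1], ij[2])
  } else {
    idx <- cellIndex(g, oceanSeed[1], oceanSeed[2])
    if (anyNA(idx)) stop("ocean seed outside the grid")
    seed <- c(idx[1, "i"], idx[1, "j"])
  }
  if (e[seed[1], seed[2]] > seaLevel)
    stop("ocean seed cell lies above the requested sea level")
  wet <- e <= seaLevel
  ocean <- matrix(FALSE, nrow(e), ncol(e))
  ocean[seed[1], seed[2]] <- TRUE
  shiftLon <- function(m, by) {
    n <- nrow(m)
    if (g@periodicLon) m[((seq_len(n) - 1L - by) %% n) + 1L, , drop = FALSE]
    else { out <- matrix(FALSE, n, ncol(m))
           if (by == 1L) out[2:n, ] <- m[1:(n - 1), ] else out[1:(n - 1), ] <- m[2:n, ]
           out }
  }
  shiftLat <- function(m, by) {
    n <- ncol(m); out <- matrix(FALSE, nrow(m), n)
    if (by == 1L) out[, 2:n] <- m[, 1:(n - 1)] else out[, 1:(n - 1)] <- m[, 2:n]
    out
  }
  repeat {
    grown <- (shiftLon(ocean, 1L) | shiftLon(ocean, -1L) |
              shiftLat(ocean, 1L) | shiftLat(ocean, -1L) | ocean) & wet
    if (identical(grown, ocean)) break
    ocean <- grown
  }
  category <- matrix(1L, nrow(e), ncol(e))        # land
  category[wet] <- 2L                             # inland depression unless...
  category[ocean] <- 0L                           # ...ocean-connected
  new("LandMask", grid = g, category = category, seaLevel = seaLevel)
}

#' Mask a climate field to the land configuration
#'
#' Ocean cells become missing (mask FALSE, values NA); land and
#' inland-below-sea-level cells are untouched.
#'
#' @param field a [ClimField-class].
#' @param mask a [LandMask-class] on the same grid.
#' @return the masked [ClimField-class].
#' @export
applyMask <- function(field, mask) {
  if (!gridsIdentical(field@grid, mask@grid)) stop("grid mismatch")
  ocean <- mask@category == 0L
  v <- .asMonthArray(field)
  for (k in seq_len(dim(v)[3])) { s <- v[, , k]; s[ocean] <- NA_real_; v[, , k] <- s }
  if (length(dim(field@values)) == 2L) v <- array(v[, , 1L], dim = dim(ocean))
  new("ClimField", grid = field@grid, variable = field@variable, values = v,
      mask = field@mask & !ocean, units = field@units, metadata = field@metadata)
}

#' Construct an ice mask
#'
#' @param grid a [ClimGrid-class].
#' @param cover logical matrix (nlon, nlat), TRUE where ice-sheet covered.
#' @param time years BP.
#' @return an [IceMask-class].
#' @export
iceMask <- function(grid, cover, time = 0) {
  new("IceMask", grid = grid, cover = cover, time = time)
}

#' Override vegetation outputs under ice sheets
#'
#' Climate-driven vegetation models estimate ice biomes from climate alone
#' and can underestimate ice-sheet extent. Wherever the ice mask covers a
#' cell, the biome is set to the ice category and net primary productivity
#' and leaf area index to 0; all other cells are unchanged. Idempotent.
#'
#' @param biomes categorical [ClimField-class] of integer biome codes.
#' @param npp,lai [ClimField-class] of net primary productivity and leaf
#'   area index.
#' @param ice an [IceMask-class] on the shared grid.
#' @param iceCode integer code of the ice biome category (default 28, the
#'   last category of a 28-class biome legend).
#' @param validCodes integer vector of known biome codes; unknown codes in
#'   `biomes` raise an error.
#' @return list with elements `biomes`, `npp`, `lai`.
#' @export
iceOverride <- function(biomes, npp, lai, ice, iceCode = 28L,
                        validCodes = seq_len(28L)) {
  for (f in list(npp, lai))
    if (!gridsIdentical(f@grid, biomes@grid)) stop("grid mismatch")
  if (!gridsIdentical(ice@grid, biomes@grid)) stop("grid mismatch")
  b <- biomes@values
  known <- is.na(b) | b %in% c(validCodes, iceCode)
  if (!all(known))
    stop(sprintf("unknown biome code(s): %s",
                 paste(unique(b[!known]), collapse = ", ")))
  cov <- ice@cover
  b[cov] <- iceCode
  nv <- npp@values; nv[cov] <- 0
  lv <- lai@values; lv[cov] <- 0
  list(biomes = .withValues(biomes, array(b, dim = dim(b))),
       npp = .withValues(npp, array(nv, dim = dim(nv))),
       lai = .withValues(lai, array(lv, dim = dim(lv))))
}
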