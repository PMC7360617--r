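#' Construct a cell-centered equirectangular grid
#'
#' `lonRange` and `latRange` give the first and last cell *centers*. Centers
#' must sit at cell-centered registration for the stated resolution, i.e.
#' cell edges on integer multiples of `res` (for 0.5 degrees: centers at
#' .25/.75 values). The reconstruction target of the full dataset is the
#' 0.5 degree grid with longitudes -179.75..179.75 and latitudes
#' -59.75..89.75, i.e. 720 x 300 cells.
#'
#' @param res grid step in degrees (> 0).
#' @param lonRange numeric(2), first and last longitude centers (degrees
#'   east, within (-180, 180]).
#' @param latRange numeric(2), first and last latitude centers (degrees
#'   north, strictly inside (-90, 90)).
#' @return a [ClimGrid-class].
#' @examples
#' g <- makeGrid(0.5, c(-179.75, 179.75), c(-59.75, 89.75))
#' nLon(g) * nLat(g)  # 216000 cells
#' @export
makeGrid <- function(res, lonRange, latRange) {
  stopifnot(is.numeric(res), length(res) == 1L, res > 0,
            length(lonRange) == 2L, length(latRange) == 2L)
  tol <- 1e-6 * res
  mk <- function(rng, what) {
    n <- (rng[2] - rng[1]) / res
    if (abs(n - round(n)) > tol)
      stop(sprintf("%s range %g..%g is not an integer multiple of the %g deg resolution",
                   what, rng[1], rng[2], res))
    # cell-centered registration: center/res must be an integer + 1/2
    reg <- rng[1] / res - 0.5
    if (abs(reg - round(reg)) > tol)
      stop(sprintf("%s range is not aligned to cell-centered registration at %g deg (centers must sit at edge + res/2)",
                   what, res))
    seq(rng[1], rng[2], by = res)
  }
  lon <- mk(lonRange, "longitude")
  lat <- mk(latRange, "latitude")
  periodic <- abs(length(lon) * res - 360) < tol
  new("ClimGrid", lon = lon, lat = lat, res = res, periodicLon = periodic)
}

#' Construct a gridded field
#'
#' @param grid a [ClimGrid-class].
#' @param values numeric array (nlon, nlat) or (nlon, nlat, 12); a scalar is
#'   recycled to a constant single-layer field.
#' @param variable variable id; "T", "P", "C", "H", "W" or a derived name.
#' @param units units string; defaults to the conventional units of known
#'   variable ids.
#' @param mask logical matrix (nlon, nlat); default all valid.
#' @param metadata list of annotations.
#' @return a [ClimField-class].
#' @export
climField <- function(grid, values, variable = "T", units = NULL, mask = NULL,
                      metadata = list()) {
  nl <- nLon(grid); np <- nLat(grid)
  if (length(values) == 1L) values <- matrix(values, nl, np)
  if (is.matrix(values)) values <- array(values, dim = dim(values))
  if (is.null(units)) {
    units <- tryCatch(variableSpec(variable)@units, error = function(e) "1")
  }
  if (is.null(mask)) mask <- matrix(TRUE, nl, np)
  new("ClimField", grid = grid, variable = variable, values = values,
      mask = mask, units = units, metadata = metadata)
}

#' Construct a snapshot stack
#'
#' @param times numeric years BP, strictly decreasing (oldest first).
#' @param fields list of [ClimField-class], one per time, sharing one grid.
#' @param variable variable id (defaults to the fields' id).
#' @return a [SnapshotStack-class].
#' @export
snapshotStack <- function(times, fields, variable = NULL) {
  stopifnot(length(fields) >= 1L)
  if (is.null(variable)) variable <- fields[[1]]@variable
  new("SnapshotStack", variable = variable, times = as.numeric(times),
      fields = fields, units = fields[[1]]@units)
}

#' Test whether two grids coincide
#'
#' @param a,b [ClimGrid-class] objects.
#' @param tol numeric tolerance on center coordinates (degrees).
#' @return logical(1).
#' @export
gridsIdentical <- function(a, b, tol = 1e-9) {
  length(a@lon) == length(b@lon) && length(a@lat) == length(b@lat) &&
    max(abs(a@lon - b@lon)) <= tol && max(abs(a@lat - b@lat)) <= tol
}

#' Cell-area gain between two grid resolutions
#'
#' Ratio of angular cell areas, e.g. from a 3.75 x 2.5 degree grid to a
#' 1.25 x 0.83 degree grid the gain is ~9: the factor by which the first
#' downscaling stage increases the number of cells per unit area.
#'
#' @param coarse numeric(2), (lon, lat) steps of the coarse grid in degrees.
#' @param fine numeric(2), (lon, lat) steps of the fine grid in degrees.
#' @return numeric(1) area ratio.
#' @examples
#' cellAreaRatio(c(3.75, 2.5), c(1.25, 0.83))  # ~9
#' @export
cellAreaRatio <- function(coarse, fine) {
  stopifnot(length(coarse) == 2L, length(fine) == 2L, all(fine > 0))
  prod(coarse) / prod(fine)
}

#' Wrap longitudes into (-180, 180]
#'
#' @param lon numeric degrees east.
#' @return numeric in (-180, 180].
#' @export
wrapLon <- function(lon) {
  w <- lon - 360 * floor((lon + 180) / 360)
  w[w == -180] <- 180
  w
}

# Cell index containing a point, half-open cells [center - res/2, center + res/2).
# Returns NA for points outside the (non-periodic) extent.
.cellIndex1 <- function(coord, centers, res, periodic = FALSE) {
  lo <- centers[1] - res / 2
  if (periodic) {
    i <- floor((coord - lo) / res) %% length(centers) + 1L
  } else {
    i <- floor((coord - lo) / res) + 1L
    i[coord < lo | coord >= centers[length(centers)] + res / 2] <- NA_integer_
  }
  as.integer(i)
}

#' Locate grid cells containing points
#'
#' Half-open cell intervals `[center - res/2, center + res/2)`, with
#' longitude wrap at the dateline on periodic grids.
#'
#' @param grid a [ClimGrid-class].
#' @param lon,lat point coordinates in degrees.
#' @return integer matrix with columns `i` (lon index) and `j` (lat index);
#'   NA where the point falls outside the grid.
#' @export
cellIndex <- function(grid, lon, lat) {
  lon <- wrapLon(lon)
  i <- .cellIndex1(lon, grid@lon, grid@res, grid@periodicLon)
  j <- .cellIndex1(lat, grid@lat, grid@res, FALSE)
  cbind(i = i, j = j)
}

# month-slice helper: returns values as (nlon, nlat, nm) array regardless
.asMonthArray <- function(field) {
  v <- field@values
  if (length(dim(v)) == 2L) array(v, dim = c(dim(v), 1L)) else v
}

# rebuild a field with new values, preserving everything else
.withValues <- function(field, values, metadata = field@metadata) {
  if (length(dim(values)) == 3L && dim(values)[3] == 1L)
    values <- array(values[, , 1L], dim = dim(values)[1:2])
  new("ClimField", grid = field@grid, variable = field@variable,
      values = values, mask = field@mask, units = field@units,
      metadata = metadata)
}
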