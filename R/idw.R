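#' Gap-fill a field by inverse-distance weighting
#'
#' Fills every invalid cell with an inverse-distance-weighted mean of the
#' `k` nearest valid donor cells, with distances measured as great-circle
#' distances between cell centers (haversine). Used to extrapolate modern
#' observational climatologies over present-day ocean cells so the Delta
#' Method remains applicable at times of lower sea level, when shelf cells
#' are land. Valid cells are never altered; filled values are convex
#' combinations of donor values, hence within the donors' range. The same
#' donor neighbourhood (from the shared mask) is used for every month.
#'
#' @param field a [ClimField-class] with at least one valid cell.
#' @param k number of nearest donors per filled cell (default 10; capped at
#'   the number of valid cells). Ties at the k-th distance are broken by
#'   donor cell order (longitude fastest), deterministically.
#' @param power inverse-distance exponent (default 2, inverse-square).
#' @return a [ClimField-class] with an all-valid mask.
#' @export
idwExtrapolate <- function(field, k = 10L, power = 2) {
  stopifnot(power > 0, k >= 1L)
  m <- field@mask
  if (!any(m)) stop("all cells invalid: nothing to extrapolate from")
  if (all(m)) return(field)
  g <- field@grid
  lonM <- matrix(g@lon, nLon(g), nLat(g))
  latM <- matrix(g@lat, nLon(g), nLat(g), byrow = TRUE)
  donors <- which(m)
  holes <- which(!m)
  k <- min(as.integer(k), length(donors))
  varr <- .asMonthArray(field)
  nm <- dim(varr)[3]
  dval <- matrix(varr, ncol = nm)[donors, , drop = FALSE]
  out <- varr
  dpts <- cbind(lonM[donors], latM[donors])
  for (h in holes) {
    d <- geosphere::distHaversine(c(lonM[h], latM[h]), dpts)
    sel <- order(d)[seq_len(k)]
    w <- 1 / pmax(d[sel], 1e-6)^power
    w <- w / sum(w)
    ij <- arrayInd(h, dim(m))
    out[ij[1], ij[2], ] <- as.numeric(w %*% dval[sel, , drop = FALSE])
  }
  if (length(dim(field@values)) == 2L) out <- array(out[, , 1L], dim = dim(m))
  new("ClimField", grid = g, variable = field@variable, values = out,
      mask = matrix(TRUE, nLon(g), nLat(g)), units = field@units,
      metadata = field@metadata)
}
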