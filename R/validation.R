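#' Read a proxy point table from CSV
#'
#' Expected columns: lon, lat, time_BP, variable, value, and optionally
#' sigma (a per-point reconstruction uncertainty, carried but unused by the
#' summary statistics).
#'
#' @param path CSV file path.
#' @return data.frame of proxy points.
#' @export
readProxies <- function(path) {
  # variable ids like "T" must never be parsed as logicals
  d <- utils::read.csv(path, colClasses = c(variable = "character"))
  need <- c("lon", "lat", "time_BP", "variable", "value")
  if (!all(need %in% names(d)))
    stop(sprintf("proxy CSV must have columns %s", paste(need, collapse = ", ")))
  d
}

#' Pair proxy points with grid-cell values
#'
#' Each point is assigned the value of the grid cell containing it
#' (half-open cells `[center - res/2, center + res/2)`, longitude wrapped at
#' the dateline). If that cell is masked, the nearest valid cell within the
#' surrounding 1-cell ring (8 neighbours, longitude wrap) is used, nearest
#' by great-circle distance from the point; if none is valid the point is
#' dropped and reported. Points outside the grid's latitude extent are also
#' dropped.
#'
#' @param field a [ClimField-class] (single layer) for the points' variable
#'   and time.
#' @param points data.frame with at least lon and lat columns (see
#'   [readProxies()]).
#' @return the points data.frame with an added `model` column, one row per
#'   retained point; the number of dropped points is attached as attribute
#'   `"nDropped"` and reported via a message when nonzero.
#' @export
extractAtPoints <- function(field, points) {
  g <- field@grid
  v <- field@values
  if (length(dim(v)) == 3L) stop("extractAtPoints expects a single-layer field")
  idx <- cellIndex(g, points$lon, points$lat)
  model <- rep(NA_real_, nrow(points))
  for (r in seq_len(nrow(points))) {
    i <- idx[r, "i"]; j <- idx[r, "j"]
    if (is.na(i) || is.na(j)) next
    if (field@mask[i, j]) { model[r] <- v[i, j]; next }
    # 1-cell ring fallback
    ring <- expand.grid(di = -1:1, dj = -1:1)
    ring <- ring[!(ring$di == 0 & ring$dj == 0), ]
    ii <- if (g@periodicLon) ((i - 1L + ring$di) %% nLon(g)) + 1L else i + ring$di
    jj <- j + ring$dj
    ok <- ii >= 1L & ii <= nLon(g) & jj >= 1L & jj <= nLat(g)
    ii <- ii[ok]; jj <- jj[ok]
    valid <- field@mask[cbind(ii, jj)]
    if (!any(valid)) next
    ii <- ii[valid]; jj <- jj[valid]
    d <- geosphere::distHaversine(c(points$lon[r], points$lat[r]),
                                  cbind(g@lon[ii], g@lat[jj]))
    b <- which.min(d)
    model[r] <- v[ii[b], jj[b]]
  }
  keep <- !is.na(model)
  nDropped <- sum(!keep)
  if (nDropped > 0)
    message(sprintf("extractAtPoints: dropped %d point(s) with no valid cell", nDropped))
  out <- cbind(points[keep, , drop = FALSE], model = model[keep])
  attr(out, "nDropped") <- nDropped
  out
}

# linear-interpolation quantiles (R type 7): the documented convention
.quartiles <- function(x) {
  stats::quantile(x, probs = c(0.25, 0.5, 0.75), type = 7, names = FALSE)
}

#' Summary statistics of model-proxy absolute differences
#'
#' The median and the lower and upper quartiles of the set of absolute
#' differences between gridded model values and point proxy reconstructions.
#' Quartiles use the linear-interpolation convention between order
#' statistics (R type 7). With a `by` grouping (e.g. per variable and time
#' period) one summary row is produced per group; with `by = NULL` all pairs
#' are pooled.
#'
#' @param pairs data.frame with columns `model` and `value` (the proxy
#'   reconstruction), as produced by [extractAtPoints()].
#' @param by optional character vector of grouping columns present in
#'   `pairs` (e.g. `c("variable", "time_BP")`).
#' @return data.frame with columns (grouping columns,) `n`, `lowerQuartile`,
#'   `median`, `upperQuartile`.
#' @export
absDiffSummary <- function(pairs, by = NULL) {
  if (NROW(pairs) == 0L) stop("no model-proxy pairs")
  if (!all(c("model", "value") %in% names(pairs)))
    stop("pairs must have 'model' and 'value' columns")
  one <- function(d) {
    q <- .quartiles(abs(d$model - d$value))
    data.frame(n = nrow(d), lowerQuartile = q[1], median = q[2], upperQuartile = q[3])
  }
  if (is.null(by)) return(one(pairs))
  parts <- split(pairs, pairs[by], drop = TRUE)
  out <- do.call(rbind, lapply(parts, function(d)
    cbind(d[1, by, drop = FALSE], one(d))))
  rownames(out) <- NULL
  out
}

#' Residuals binned across the proxy value spectrum
#'
#' Bins the signed residuals (model minus proxy) by the proxy value and
#' returns per-bin count, mean and standard deviation -- the diagnostic used
#' to check that residual biases are centred on zero across the value
#' spectrum rather than only on average. If all proxy values coincide, a
#' single bin is returned.
#'
#' @param pairs data.frame with `model` and `value` columns.
#' @param bins number of equal-width bins over the proxy value range.
#' @return data.frame with columns `binMid`, `n`, `meanResidual`,
#'   `sdResidual`.
#' @export
residualSpectrum <- function(pairs, bins = 10L) {
  if (NROW(pairs) == 0L) stop("no model-proxy pairs")
  res <- pairs$model - pairs$value
  rng <- range(pairs$value)
  if (diff(rng) == 0) {
    return(data.frame(binMid = rng[1], n = length(res),
                      meanResidual = mean(res), sdResidual = stats::sd(res)))
  }
  edges <- seq(rng[1], rng[2], length.out = bins + 1L)
  bin <- pmin(findInterval(pairs$value, edges), bins)
  mids <- (edges[-1] + edges[-(bins + 1L)]) / 2
  out <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    r <- res[bin == b]
    data.frame(binMid = mids[b], n = length(r), meanResidual = mean(r),
               sdResidual = if (length(r) > 1L) stats::sd(r) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}
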