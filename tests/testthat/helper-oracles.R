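# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths (and its dependencies' where feasible).

# great-circle distance (spherical law of cosines), metres on a 6378137 m sphere
oracleGCD <- function(lon1, lat1, lon2, lat2) {
  d2r <- pi / 180
  cs <- sin(lat1 * d2r) * sin(lat2 * d2r) +
    cos(lat1 * d2r) * cos(lat2 * d2r) * cos((lon2 - lon1) * d2r)
  6378137 * acos(pmin(pmax(cs, -1), 1))
}

# all-pairs inverse-distance weighting from every donor cell
oracleIDW <- function(grid, values, mask, power = 2) {
  lon <- lonCenters(grid); lat <- latCenters(grid)
  out <- values
  donors <- which(mask)
  di <- arrayInd(donors, dim(mask))
  for (h in which(!mask)) {
    ij <- arrayInd(h, dim(mask))
    d <- oracleGCD(lon[ij[1]], lat[ij[2]], lon[di[, 1]], lat[di[, 2]])
    w <- 1 / pmax(d, 1e-6)^power
    out[h] <- sum(w * values[donors]) / sum(w)
  }
  out
}

# per-cell bioclim layers by explicit month/quarter enumeration
oracleBioclim <- function(tm, pm, tmin, tmax) {
  quarters <- lapply(1:12, function(s) ((s - 1L + 0:2) %% 12L) + 1L)
  ncell <- nrow(tm)
  out <- matrix(NA_real_, ncell, 17,
                dimnames = list(NULL, c("BIO1", paste0("BIO", 4:19))))
  for (c in seq_len(ncell)) {
    tv <- tm[c, ]; pv <- pm[c, ]
    qT <- sapply(quarters, function(q) mean(tv[q]))
    qP <- sapply(quarters, function(q) sum(pv[q]))
    wet <- which(qP == max(qP))[1]; dry <- which(qP == min(qP))[1]
    hot <- which(qT == max(qT))[1]; cold <- which(qT == min(qT))[1]
    mu <- mean(pv)
    out[c, ] <- c(
      mean(tv),
      sqrt(sum((tv - mean(tv))^2) / 12),
      tmax[c], tmin[c], tmax[c] - tmin[c],
      qT[wet], qT[dry], qT[hot], qT[cold],
      sum(pv), max(pv), min(pv),
      if (mu == 0) 0 else sqrt(sum((pv - mu)^2) / 12) / mu,
      qP[wet], qP[dry], qP[hot], qP[cold])
  }
  out
}

# queue-based breadth-first flood fill over wet cells, 4-connectivity + lon wrap
oracleFlood <- function(wet, seed, periodic = TRUE) {
  nl <- nrow(wet); np <- ncol(wet)
  ocean <- matrix(FALSE, nl, np)
  if (!wet[seed[1], seed[2]]) return(ocean)
  queue <- list(seed); ocean[seed[1], seed[2]] <- TRUE
  while (length(queue)) {
    cur <- queue[[1]]; queue <- queue[-1]
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      i <- cur[1] + d[1]; j <- cur[2] + d[2]
      if (periodic) i <- ((i - 1) %% nl) + 1
      if (i < 1 || i > nl || j < 1 || j > np) next
      if (wet[i, j] && !ocean[i, j]) {
        ocean[i, j] <- TRUE
        queue[[length(queue) + 1]] <- c(i, j)
      }
    }
  }
  ocean
}

# sort-based quantile with linear interpolation between order statistics
oracleQuantile <- function(x, p) {
  x <- sort(x); n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[pmin(lo + 1, n)] - x[lo])
}

# small all-valid field on a fresh grid for quick tests
testField <- function(nlon = 12, nlat = 8, res = 5, months = TRUE,
                      fun = function(lon, lat, m) sin(lon * pi / 180) + lat / 30 + m,
                      variable = "T") {
  g <- makeGrid(res, c(-nlon / 2 * res + res / 2, nlon / 2 * res - res / 2),
                c(-nlat / 2 * res + res / 2, nlat / 2 * res - res / 2))
  lonM <- matrix(lonCenters(g), nLon(g), nLat(g))
  latM <- matrix(latCenters(g), nLon(g), nLat(g), byrow = TRUE)
  if (months) {
    v <- array(NA_real_, dim = c(nLon(g), nLat(g), 12))
    for (m in 1:12) v[, , m] <- fun(lonM, latM, m)
  } else v <- fun(lonM, latM, 1)
  climField(g, v, variable = variable)
}
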