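#' Time axes of the snapshot sets
#'
#' `axis120k()` returns the 72-snapshot axis covering the last 120,000 years:
#' 2,000-year steps from 120,000 BP down to 22,000 BP, then 1,000-year steps
#' from 21,000 BP to 0 BP (the pre-industrial modern era). `axis21k()`
#' returns the 9-snapshot axis of the high-resolution reference simulations:
#' 21,000, 18,000, 15,000, 12,000, 10,000, 8,000, 6,000, 3,000 and 0 BP
#' (2,000-year steps between 12,000 and 6,000 BP, 3,000-year steps
#' otherwise). Both are ordered oldest to youngest, i.e. strictly decreasing
#' years BP, and the 9-point axis is a subset of the 72-point axis.
#'
#' @return numeric vector of years BP, strictly decreasing.
#' @examples
#' length(axis120k())  # 72
#' length(axis21k())   # 9
#' @export
axis120k <- function() {
  c(seq(120000, 22000, by = -2000), seq(21000, 0, by = -1000))
}

#' @rdname axis120k
#' @export
axis21k <- function() {
  c(21000, 18000, 15000, 12000, 10000, 8000, 6000, 3000, 0)
}

#' Read a CO2 series from CSV
#'
#' Expects columns `time_BP` and `co2_ppm`. Returned sorted oldest first.
#'
#' @param path CSV file path.
#' @return data.frame with columns time_BP, co2_ppm.
#' @export
readCO2 <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time_BP", "co2_ppm") %in% names(d)))
    stop("CO2 CSV must have columns time_BP and co2_ppm")
  if (any(d$co2_ppm <= 0)) stop("CO2 concentrations must be positive")
  d[order(-d$time_BP), c("time_BP", "co2_ppm"), drop = FALSE]
}

# look up CO2 at given times, erroring on gaps
.co2At <- function(co2, t) {
  i <- match(t, co2$time_BP)
  if (anyNA(i))
    stop(sprintf("CO2 series undefined at time(s) %s BP",
                 paste(t[is.na(i)], collapse = ", ")))
  co2$co2_ppm[i]
}

#' CO2-similarity weights of the Dynamic Delta Method
#'
#' The correction term applied at a target time `t` is a weighted sum of
#' fine-grid correction terms at the reference times. Reference times whose
#' CO2 concentration is close to that at `t` receive more weight:
#' `w'(t, tau) = 1 / (CO2(t) - CO2(tau))^2`, normalized to sum to one --
#' formally an inverse-square-distance interpolation of the correction terms
#' with respect to CO2. When CO2(t) coincides with the CO2 of one or more
#' reference times (relative difference below `tol`) the weight concentrates
#' entirely on those exact matches, split equally -- the continuous limit of
#' the inverse-square form. In particular, when `t` is itself a reference
#' time with a unique CO2 value, w(t, t) = 1 and all other weights are 0, so
#' stage-1 output reduces to the high-resolution simulation there.
#'
#' @param t target time (years BP).
#' @param co2 data.frame (time_BP, co2_ppm) covering `t` and all `refs`.
#' @param refs numeric reference times (years BP), e.g. [axis21k()].
#' @param tol relative CO2 difference below which a reference counts as an
#'   exact match (default 1e-12).
#' @return named numeric vector of weights (names = reference times BP),
#'   nonnegative, summing to 1.
#' @examples
#' co2 <- data.frame(time_BP = c(4000, 2000, 0), co2_ppm = c(220, 240, 280))
#' co2Weights(4000, co2, refs = c(2000, 0))
#' @export
co2Weights <- function(t, co2, refs, tol = 1e-12) {
  if (length(refs) == 0L) stop("empty reference time axis")
  ct <- .co2At(co2, t)
  cr <- .co2At(co2, refs)
  d <- abs(ct - cr)
  exact <- d <= tol * max(abs(ct), abs(cr), 1)
  if (any(exact)) {
    w <- as.numeric(exact) / sum(exact)
  } else {
    wp <- 1 / d^2
    w <- wp / sum(wp)
  }
  names(w) <- as.character(refs)
  w
}
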