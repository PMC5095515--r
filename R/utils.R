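#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Rescale a numeric vector to [0, 1]
#'
#' Constant vectors map to 0.5 so that downstream monotone combinations of
#' covariates degenerate gracefully (no heterogeneity in, none out).
#' @param x numeric vector
#' @return numeric vector in [0, 1]
#' @keywords internal
rescale01 <- function(x) {
  r <- range(x, na.rm = TRUE)
  if (!is.finite(r[1]) || r[2] - r[1] < .Machine$double.eps) {
    return(rep(0.5, length(x)))
  }
  (x - r[1]) / (r[2] - r[1])
}

#' First-order autoregressive Gaussian field
#'
#' Stationary AR(1) series with autocorrelation length `len` windows
#' (lag-1 coefficient exp(-1/len)), unit marginal variance.
#' @keywords internal
ar1_field <- function(n, len) {
  stopifnot(n >= 1, len > 0)
  phi <- exp(-1 / len)
  x <- numeric(n)
  x[1] <- stats::rnorm(1)
  if (n > 1) {
    innov <- stats::rnorm(n - 1, sd = sqrt(1 - phi^2))
    for (i in 2:n) x[i] <- phi * x[i - 1] + innov[i - 1]
  }
  x
}

#' Run lengths of TRUE values
#' @return data.frame with columns start, end (inclusive indices) and length
#' @keywords internal
true_runs <- function(flags) {
  flags[is.na(flags)] <- FALSE
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep], length = r$lengths[keep])
}

#' Weighted mean latitude/longitude for pooled sampling locations
#'
#' Pooled locations are summarized by the sample-size-weighted mean of their
#' coordinates.
#' @param lat,lon numeric vectors
#' @param n sample sizes (weights)
#' @return c(lat, lon)
#' @export
pooled_coordinates <- function(lat, lon, n) {
  stopifnot(length(lat) == length(lon), length(lat) == length(n))
  c(lat = sum(lat * n) / sum(n), lon = sum(lon * n) / sum(n))
}
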