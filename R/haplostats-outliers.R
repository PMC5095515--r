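#' Standardize a haplotype statistic within derived-frequency bins
#'
#' Standardizes raw iHS / nSL values to mean 0 and s.d. 1 within equal-width
#' derived-allele-frequency bins (100 bins by default), removing the
#' frequency dependence of the unstandardized statistic. Bins with fewer
#' than `min_bin_n` non-missing values, or zero spread, yield NA.
#' Standardizing an already standardized track (with its own frequencies)
#' changes nothing beyond numerical tolerance.
#'
#' @param values raw statistic values (NA allowed)
#' @param freq derived-allele frequencies in (0, 1)
#' @param n_bins number of equal-width frequency bins
#' @param min_bin_n minimum values per bin
#' @return numeric vector of standardized values
#' @export
standardize_freq_bins <- function(values, freq, n_bins = 100, min_bin_n = 2) {
  stopifnot(length(values) == length(freq))
  bin <- pmin(pmax(floor(freq * n_bins) + 1L, 1L), n_bins)
  out <- rep(NA_real_, length(values))
  for (b in unique(bin)) {
    idx <- which(bin == b & !is.na(values))
    if (length(idx) < min_bin_n) next
    m <- mean(values[idx])
    s <- stats::sd(values[idx])
    if (!is.finite(s) || s == 0) next
    out[idx] <- (values[idx] - m) / s
  }
  out
}

#' Flag single-SNP outliers of a standardized track
#'
#' Flags sites below the `alpha_low` empirical quantile or above the
#' `alpha_high` quantile (defaults: 0.5th and 99.5th percentiles, 1% of
#' sites combined across the two tails).
#'
#' @param values standardized statistic (NA ignored)
#' @param alpha_low,alpha_high tail quantiles
#' @return logical vector (NA values are FALSE); attributes `cut_low` and
#'   `cut_high` hold the thresholds
#' @export
snp_outliers <- function(values, alpha_low = 0.005, alpha_high = 0.995) {
  ok <- !is.na(values)
  n <- sum(ok)
  min_tail <- min(alpha_low, 1 - alpha_high)
  if (n < 1 / min_tail) {
    warning("fewer than ", ceiling(1 / min_tail),
            " sites; outlier quantiles are unstable")
  }
  if (n == 0 || stats::sd(values[ok]) == 0) {
    if (n > 0) warning("constant track; no outliers flagged")
    out <- rep(FALSE, length(values))
    attr(out, "cut_low") <- NA_real_
    attr(out, "cut_high") <- NA_real_
    return(out)
  }
  q <- stats::quantile(values[ok], c(alpha_low, alpha_high), names = FALSE)
  out <- ok & (values < q[1] | values > q[2])
  out[is.na(out)] <- FALSE
  attr(out, "cut_low") <- q[1]
  attr(out, "cut_high") <- q[2]
  out
}

#' Expected number of cross-zone shared outlier SNPs under independence
#'
#' With a per-zone outlier fraction `alpha`, per-zone proportions `props` of
#' each zone's outliers that fall in the cross-zone shared-SNP set, and
#' `n_shared` SNPs segregating in all zones, the expected number of SNPs
#' flagged in every zone by chance is
#'
#'   E = n_shared * prod(alpha * props)
#'
#' With three zones at alpha = 0.01, proportions 1.00 / 0.69 / 0.48 and
#' 5,447,980 shared SNPs this gives ~1.8. When an observed shared-outlier
#' count is supplied the observed/expected ratio is returned alongside.
#'
#' @param alpha per-zone outlier fraction in (0, 1) (scalar or one per zone)
#' @param props per-zone proportions in [0, 1]
#' @param n_shared number of SNPs segregating across all zones
#' @param observed optional observed shared-outlier count
#' @return list(expected, observed, ratio)
#' @export
shared_outlier_expectation <- function(alpha, props, n_shared,
                                       observed = NULL) {
  stopifnot(all(alpha > 0), all(alpha < 1),
            all(props >= 0), all(props <= 1), n_shared >= 0)
  alpha <- rep(alpha, length.out = length(props))
  expected <- n_shared * prod(alpha * props)
  list(expected = expected,
       observed = observed,
       ratio = if (!is.null(observed)) observed / expected else NULL)
}
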