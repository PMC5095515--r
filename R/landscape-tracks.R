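#' Z-standardize a window F_ST track (F_ST')
#'
#' F_ST' = (F_ST - genome-wide mean) / genome-wide s.d., computed per
#' comparison over all non-missing windows, expressing differentiation in
#' units of genome-wide standard deviations.
#'
#' @param fst numeric vector of window F_ST (NA for missing windows)
#' @return numeric vector with mean 0 and s.d. 1 over non-missing windows
#' @export
zscore_fst <- function(fst) {
  ok <- !is.na(fst)
  if (sum(ok) < 2) stop("need at least 2 non-missing windows")
  s <- stats::sd(fst[ok])
  if (s == 0) stop("zero variance: constant F_ST track cannot be standardized")
  (fst - mean(fst[ok])) / s
}

#' Net differentiation against allopatric controls (Delta F_ST')
#'
#' Subtracts, window by window, the maximum standardized differentiation
#' observed in any control comparison from the focal track:
#' Delta F_ST'(w) = focal(w) - max over controls of control(w).
#' The control maximum is taken over the controls available at that window;
#' the result is missing only where the focal window or all control windows
#' are missing.
#'
#' @param focal numeric vector of focal F_ST' values
#' @param controls list (or matrix columns) of control F_ST' tracks on the
#'   same window index
#' @return numeric vector of Delta F_ST'; attribute `n_controls_used` counts
#'   the controls available per window
#' @export
delta_fst <- function(focal, controls) {
  if (is.list(controls)) controls <- do.call(cbind, controls)
  if (is.null(dim(controls)) || ncol(controls) < 1) {
    stop("empty control set")
  }
  if (nrow(controls) != length(focal)) stop("tracks on different window indices")
  n_used <- rowSums(!is.na(controls))
  ctrl_max <- apply(controls, 1, function(x)
    if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
  out <- focal - ctrl_max
  attr(out, "n_controls_used") <- n_used
  out
}

#' Flag outlier windows above an empirical percentile
#'
#' Flags windows strictly above the given empirical percentile (linear
#' interpolation, type 7) of the non-missing values.
#'
#' @param values numeric track
#' @param percentile percentile in (0, 100), default 99
#' @return logical vector (missing windows FALSE); attribute `cutoff`
#' @export
call_outlier_windows <- function(values, percentile = 99) {
  ok <- !is.na(values)
  if (sum(ok) < 100) {
    warning("fewer than 100 non-missing windows; percentile is unstable")
  }
  cut <- stats::quantile(values[ok], percentile / 100, names = FALSE)
  flags <- ok & values > cut
  flags[is.na(flags)] <- FALSE
  attr(flags, "cutoff") <- cut
  flags
}
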