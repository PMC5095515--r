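#' Weir-Cockerham (1984) per-site variance components for two populations
#'
#' For every biallelic site passing the pair-specific coverage filter and
#' polymorphic across the two populations, computes the among-population (a),
#' among-individual-within-population (b) and within-individual (c) variance
#' components of the Weir-Cockerham estimator for diploid data, accounting
#' for observed heterozygosity and unequal sample sizes. The per-site
#' estimate is a / (a + b + c); window estimates come from
#' [window_fst()] as a ratio of summed components.
#'
#' @param vm variant_matrix
#' @param popA,popB population labels
#' @param sites optional logical vector of sites to use; defaults to
#'   [site_coverage_filter()]
#' @return data.frame(site = site index into vm, a, b, c)
#' @export
wc_fst_per_site <- function(vm, popA, popB, sites = NULL) {
  if (is.null(sites)) sites <- site_coverage_filter(vm, popA, popB)
  colsA <- which(vm$popmap$population == popA)
  colsB <- which(vm$popmap$population == popB)
  gA <- vm$geno[, colsA, drop = FALSE]
  gB <- vm$geno[, colsB, drop = FALSE]

  nA <- rowSums(!is.na(gA))            # called diploid individuals
  nB <- rowSums(!is.na(gB))
  pA <- rowSums(gA, na.rm = TRUE) / (2 * nA)
  pB <- rowSums(gB, na.rm = TRUE) / (2 * nB)
  hA <- rowSums(gA == 1L, na.rm = TRUE) / nA  # observed heterozygote freq
  hB <- rowSums(gB == 1L, na.rm = TRUE) / nB

  poly <- sites & nA > 0 & nB > 0 &
    !((pA == 0 & pB == 0) | (pA == 1 & pB == 1))
  idx <- which(poly)

  r <- 2
  n1 <- nA[idx]; n2 <- nB[idx]
  p1 <- pA[idx]; p2 <- pB[idx]
  h1 <- hA[idx]; h2 <- hB[idx]
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)

  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2

  data.frame(site = idx, a = a, b = b, c = cc)
}

#' Window F_ST as a ratio of summed variance components
#'
#' Window F_ST = sum(a) / sum(a + b + c) over the window's segregating sites
#' (components averaged across sites, then the ratio taken). Windows with no
#' usable site are NA; negative window values are reported as computed.
#'
#' @param components output of [wc_fst_per_site()]
#' @param windows window_index
#' @return data.frame per window: scaffold, start, end, fst, n_sites
#' @export
window_fst <- function(components, windows) {
  out <- windows$windows[, c("scaffold", "start", "end")]
  nw <- nrow(out)
  w <- windows$site_window[components$site]
  num <- den <- numeric(nw)
  agg <- rowsum(cbind(components$a,
                      components$a + components$b + components$c), w)
  rows <- as.integer(rownames(agg))
  num[rows] <- agg[, 1]
  den[rows] <- agg[, 2]
  n_sites <- tabulate(w, nbins = nw)
  out$fst <- ifelse(n_sites > 0 & den != 0, num / den, NA_real_)
  out$fst[n_sites > 0 & den == 0] <- 0
  out$n_sites <- n_sites
  out
}

#' Genome-wide F_ST for a population pair
#'
#' Ratio of summed Weir-Cockerham components over all usable sites; the
#' scalar used for isolation-by-distance.
#' @param vm variant_matrix
#' @param popA,popB labels
#' @return scalar F_ST
#' @export
genomewide_fst <- function(vm, popA, popB) {
  comp <- wc_fst_per_site(vm, popA, popB)
  sum(comp$a) / sum(comp$a + comp$b + comp$c)
}

#' Absolute divergence D_xy per window
#'
#' D_xy = sum over segregating sites of pA (1 - pB) + pB (1 - pA), divided by
#' the number of callable sites in the window (monomorphic callable sites
#' contribute zero to the numerator and count in the denominator). Windows
#' with zero callable sites are NA.
#'
#' @param vm variant_matrix
#' @param popA,popB labels
#' @param windows window_index (its n_callable column is the denominator)
#' @param sites optional logical site filter; defaults to the pair coverage
#'   filter
#' @return data.frame per window: scaffold, start, end, dxy, n_sites
#' @export
dxy <- function(vm, popA, popB, windows, sites = NULL) {
  if (is.null(sites)) sites <- site_coverage_filter(vm, popA, popB)
  colsA <- which(vm$popmap$population == popA)
  colsB <- which(vm$popmap$population == popB)
  gA <- vm$geno[, colsA, drop = FALSE]
  gB <- vm$geno[, colsB, drop = FALSE]
  pA <- rowSums(gA, na.rm = TRUE) / (2 * rowSums(!is.na(gA)))
  pB <- rowSums(gB, na.rm = TRUE) / (2 * rowSums(!is.na(gB)))
  contrib <- ifelse(sites, pA * (1 - pB) + pB * (1 - pA), 0)

  w <- windows$site_window
  nw <- nrow(windows$windows)
  num <- numeric(nw)
  agg <- rowsum(contrib, w)
  num[as.integer(rownames(agg))] <- agg[, 1]
  out <- windows$windows[, c("scaffold", "start", "end")]
  callable <- windows$windows$n_callable
  out$dxy <- ifelse(callable > 0, num / callable, NA_real_)
  out$n_sites <- tabulate(w[sites], nbins = nw)
  out
}

#' Population branch statistic
#'
#' PBS for population 1 from the three pairwise window F_ST tracks:
#' PBS_1 = (-log(1 - F_12) - log(1 - F_13) + log(1 - F_23)) / 2,
#' with each F clamped to [0, 1 - 1e-9] before the log. Windows missing in
#' any input are missing in the output.
#'
#' @param fst_12,fst_13,fst_23 numeric vectors of window F_ST on one
#'   window index (population order: 1-2, 1-3, 2-3)
#' @return numeric vector of PBS values for population 1
#' @export
pbs <- function(fst_12, fst_13, fst_23) {
  n <- length(fst_12)
  if (length(fst_13) != n || length(fst_23) != n) {
    stop("mismatched window indices across F_ST tracks")
  }
  tl <- function(f) -log(1 - pmin(pmax(f, 0), 1 - 1e-9))
  (tl(fst_12) + tl(fst_13) - tl(fst_23)) / 2
}
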