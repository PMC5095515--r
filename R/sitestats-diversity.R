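#' Unfolded site frequency spectrum
#'
#' Tally of derived-allele counts i = 1..(2n - 1) among called alleles for
#' one population; sites with missing ancestral state are excluded.
#'
#' @param vm variant_matrix
#' @param population label
#' @return integer vector of length 2n - 1 (n = diploid sample size), named
#'   by derived count
#' @export
unfolded_sfs <- function(vm, population) {
  ac <- pop_allele_counts(vm, population)
  n_dip <- sum(vm$popmap$population == population)
  two_n <- 2L * n_dip
  der <- ac$derived
  usable <- !is.na(der) & der > 0 & der < ac$called
  if (!any(usable)) {
    warning("no polarizable segregating sites for ", population)
  }
  counts <- tabulate(der[usable], nbins = two_n - 1L)
  stats::setNames(counts, seq_len(two_n - 1L))
}

#' Harmonic-number helpers for SFS statistics
#' @keywords internal
harmonic <- function(n, power = 1) sum(1 / seq_len(n)^power)

#' Tajima's D from S and the pairwise-difference sum
#' @param s segregating sites
#' @param pi_sum sum over sites of pairwise differences (not per-site)
#' @param n number of sequences (called alleles)
#' @keywords internal
tajimas_d <- function(s, pi_sum, n) {
  if (s == 0 || n < 4) return(NA_real_)
  a1 <- harmonic(n - 1)
  a2 <- harmonic(n - 1, 2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_sum - s / a1) / sqrt(e1 * s + e2 * s * (s - 1))
}

#' Fu and Li's D (with outgroup) from S and derived singleton count
#' @keywords internal
fu_li_d <- function(s, eta_s, n) {
  if (s == 0 || n < 4) return(NA_real_)
  a_n <- harmonic(n - 1)
  b_n <- harmonic(n - 1, 2)
  c_n <- if (n == 2) 1 else 2 * (n * a_n - 2 * (n - 1)) / ((n - 1) * (n - 2))
  v_d <- 1 + a_n^2 / (b_n + a_n^2) * (c_n - (n + 1) / (n - 1))
  u_d <- a_n - 1 - v_d
  (s - a_n * eta_s) / sqrt(u_d * s + v_d * s^2)
}

#' Per-window diversity and SFS statistics
#'
#' Computes, for one population, per-window nucleotide diversity pi (mean
#' pairwise difference normalized by callable sites), Watterson's theta
#' (S / a_n per callable site), Tajima's D, Fay and Wu's H
#' (theta_pi - theta_H with theta_H = sum 2 S_i i^2 / (n (n - 1))) and
#' Fu and Li's D, from called genotypes.
#'
#' The textbook formulas assume a constant number of sequences: within each
#' window the modal called-allele count is used and sites deviating from it
#' are excluded (their number is recorded in the `n_dropped` column).
#' Unfolded statistics (H, Fu & Li's D) additionally require the ancestral
#' state and skip unpolarizable sites. Windows with no segregating site have
#' pi = 0 and theta_W = 0 but undefined D/H (NA); windows with fewer than 4
#' called alleles are entirely NA.
#'
#' @param vm variant_matrix
#' @param population label
#' @param windows window_index from [assign_windows()]
#' @return data.frame, one row per window: scaffold, start, end, pi, theta_w,
#'   taj_d, faywu_h, fuli_d, n_segregating, n_callable, n_dropped
#' @export
diversity_stats <- function(vm, population, windows) {
  ac <- pop_allele_counts(vm, population)
  w <- windows$site_window
  nw <- nrow(windows$windows)
  out <- windows$windows[, c("scaffold", "start", "end")]
  out$pi <- 0
  out$theta_w <- 0
  out$taj_d <- NA_real_
  out$faywu_h <- NA_real_
  out$fuli_d <- NA_real_
  out$n_segregating <- 0L
  out$n_callable <- windows$windows$n_callable
  out$n_dropped <- 0L

  idx_by_win <- split(seq_along(w), w)
  for (wi_chr in names(idx_by_win)) {
    wi <- as.integer(wi_chr)
    idx <- idx_by_win[[wi_chr]]
    called <- ac$called[idx]
    n_modal <- as.integer(names(which.max(table(called))))
    drop <- called != n_modal
    out$n_dropped[wi] <- sum(drop)
    idx <- idx[!drop]
    n <- n_modal
    if (n < 4) {
      out$pi[wi] <- NA_real_
      out$theta_w[wi] <- NA_real_
      next
    }
    alt <- ac$alt[idx]
    seg <- alt > 0 & alt < n
    s <- sum(seg)
    out$n_segregating[wi] <- s
    callable <- out$n_callable[wi]
    if (callable <= 0) {
      out$pi[wi] <- NA_real_
      out$theta_w[wi] <- NA_real_
      next
    }
    if (s == 0) next
    a <- alt[seg]
    pi_sum <- sum(2 * a * (n - a) / (n * (n - 1)))
    out$pi[wi] <- pi_sum / callable
    out$theta_w[wi] <- s / harmonic(n - 1) / callable
    out$taj_d[wi] <- tajimas_d(s, pi_sum, n)
    # unfolded statistics on the polarizable subset
    der <- ac$derived[idx][seg]
    pol <- !is.na(der) & der > 0 & der < n
    if (any(pol)) {
      d <- der[pol]
      theta_pi <- sum(2 * d * (n - d)) / (n * (n - 1))
      theta_h <- sum(2 * d^2) / (n * (n - 1))
      out$faywu_h[wi] <- theta_pi - theta_h
      out$fuli_d[wi] <- fu_li_d(sum(pol), sum(d == 1), n)
    }
  }
  out
}

#' Mean pairwise r-squared per window
#'
#' LD summarized as the mean r2 over all pairwise combinations of SNPs with
#' minor allele frequency above `maf_min` within each window, from phased
#' haplotypes. Windows with fewer than two qualifying SNPs are NA; scaffolds
#' shorter than the window size are excluded.
#'
#' @param hapsets list of hap_set objects (one per scaffold), e.g. from
#'   [haplotype_set()]
#' @param windows window_index
#' @param maf_min minor-allele-frequency threshold (exclusive)
#' @return data.frame per window: scaffold, start, end, mean_r2, n_snps
#' @export
window_r2 <- function(hapsets, windows, maf_min = 0.1) {
  wt <- windows$windows
  out <- wt[, c("scaffold", "start", "end")]
  out$mean_r2 <- NA_real_
  out$n_snps <- 0L
  scaffold_len <- tapply(wt$end, wt$scaffold, max)
  for (hs in hapsets) {
    if (scaffold_len[[hs$scaffold]] < windows$window_size) next
    maf <- pmin(hs$freq, 1 - hs$freq)
    use <- maf > maf_min
    win_of <- (hs$pos - 1L) %/% windows$window_size
    for (wv in unique(win_of)) {
      row <- which(wt$scaffold == hs$scaffold & wt$win == wv)
      if (!length(row)) next
      idx <- which(use & win_of == wv)
      out$n_snps[row] <- length(idx)
      if (length(idx) < 2) next
      h <- hs$haps[idx, , drop = FALSE]
      p <- rowMeans(h)
      # r2 = cor(x_i, x_j)^2 over haplotypes, all pairs
      cc <- suppressWarnings(stats::cor(t(h)))
      r2 <- cc[upper.tri(cc)]^2
      out$mean_r2[row] <- mean(r2, na.rm = TRUE)
    }
  }
  out
}
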