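#' ABBA-BABA (Patterson's D) test with block jackknife
#'
#' Tests whether the ABBA or BABA site pattern is in excess for the taxon
#' topology (((P1, P2), P3), O), where the outgroup allele is the ancestral
#' state (from the `AA` annotation). Per site, with derived-allele
#' frequencies p1, p2, p3 and the outgroup fixed ancestral:
#' ABBA = (1 - p1) p2 p3 and BABA = p1 (1 - p2) p3;
#' D = (sum ABBA - sum BABA) / (sum ABBA + sum BABA). The Z-score comes from
#' a delete-one block jackknife over contiguous blocks of `block_size`
#' windows; |Z| >= 3 is flagged significant.
#'
#' By default one diploid individual represents each population (the first
#' individual of the population, or the one named in `individuals`), as in
#' single-genome formulations of the test; `mode = "frequency"` uses
#' population allele frequencies instead.
#'
#' @param vm variant_matrix with ancestral-state annotation
#' @param p1,p2,p3 population labels for the trio
#' @param windows window_index used to form jackknife blocks
#' @param block_size block size in windows (default 50, i.e. 2.5 Mb at 50 kb)
#' @param mode "individual" or "frequency"
#' @param individuals optional named character vector individual per population
#' @return list(d, z, se, n_abba, n_baba, n_blocks, significant, defined)
#' @export
abba_baba <- function(vm, p1, p2, p3, windows, block_size = 50,
                      mode = c("individual", "frequency"),
                      individuals = NULL) {
  mode <- match.arg(mode)
  freq_of <- function(p) {
    if (mode == "frequency") {
      ac <- pop_allele_counts(vm, p)
      return(ac$derived / ac$called)
    }
    ind <- individuals[[p]] %||% vm$popmap$individual[vm$popmap$population == p][1]
    col <- match(ind, vm$individuals)
    if (is.na(col)) stop("individual not found: ", ind)
    g <- vm$geno[, col]
    der <- rep(NA_real_, length(g))
    known <- !is.na(vm$aa)
    der[known & vm$aa == vm$ref] <- g[known & vm$aa == vm$ref] / 2
    der[known & vm$aa == vm$alt] <- (2 - g[known & vm$aa == vm$alt]) / 2
    der
  }
  f1 <- freq_of(p1); f2 <- freq_of(p2); f3 <- freq_of(p3)
  ok <- !is.na(f1) & !is.na(f2) & !is.na(f3)
  abba <- ifelse(ok, (1 - f1) * f2 * f3, 0)
  baba <- ifelse(ok, f1 * (1 - f2) * f3, 0)

  # contiguous blocks of block_size windows, genome-wide window order
  block <- (windows$site_window - 1L) %/% as.integer(block_size)
  tot_abba <- sum(abba); tot_baba <- sum(baba)
  if (tot_abba + tot_baba == 0) {
    return(list(d = NA_real_, z = NA_real_, se = NA_real_,
                n_abba = 0, n_baba = 0, n_blocks = 0L,
                significant = FALSE, defined = FALSE))
  }
  d <- (tot_abba - tot_baba) / (tot_abba + tot_baba)

  ba <- rowsum(cbind(abba, baba), block)
  m <- nrow(ba)
  d_loo <- vapply(seq_len(m), function(j) {
    a <- tot_abba - ba[j, 1]; b <- tot_baba - ba[j, 2]
    if (a + b == 0) return(NA_real_)
    (a - b) / (a + b)
  }, numeric(1))
  d_loo <- d_loo[!is.na(d_loo)]
  m_eff <- length(d_loo)
  se <- if (m_eff > 1) {
    sqrt((m_eff - 1) / m_eff * sum((d_loo - mean(d_loo))^2))
  } else NA_real_
  z <- d / se
  list(d = d, z = z, se = se, n_abba = tot_abba, n_baba = tot_baba,
       n_blocks = m, significant = is.finite(z) && abs(z) >= 3,
       defined = TRUE)
}
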