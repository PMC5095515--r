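# Independent brute-force oracles, written directly from the textbook
# definitions. These deliberately use naive loops rather than the package's
# vectorized code paths.

# mean number of pairwise differences per site, by enumerating every pair of
# allele copies at every site; alt = alt-allele count per site, n = called
# allele copies per site
oracle_pi_sum <- function(alt, n) {
  total <- 0
  for (s in seq_along(alt)) {
    alleles <- c(rep(1, alt[s]), rep(0, n[s] - alt[s]))
    diff <- 0
    npairs <- 0
    if (n[s] >= 2) {
      for (i in 1:(n[s] - 1)) for (j in (i + 1):n[s]) {
        diff <- diff + (alleles[i] != alleles[j])
        npairs <- npairs + 1
      }
      total <- total + diff / npairs
    }
  }
  total
}

oracle_theta_w <- function(s_seg, n) s_seg / sum(1 / seq_len(n - 1))

oracle_tajimas_d <- function(alt, n) {
  seg <- alt > 0 & alt < n
  s <- sum(seg)
  if (s == 0) return(NA_real_)
  pi_sum <- oracle_pi_sum(alt[seg], rep(n, s))
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (pi_sum - s / a1) / sqrt(c1 / a1 * s + c2 / (a1^2 + a2) * s * (s - 1))
}

# Fay & Wu's H = theta_pi - theta_H from the unfolded spectrum
oracle_faywu_h <- function(der, n) {
  seg <- der > 0 & der < n
  d <- der[seg]
  if (!length(d)) return(NA_real_)
  sfs <- tabulate(d, nbins = n - 1)
  theta_pi <- 0; theta_h <- 0
  for (i in seq_len(n - 1)) {
    theta_pi <- theta_pi + 2 * sfs[i] * i * (n - i) / (n * (n - 1))
    theta_h <- theta_h + 2 * sfs[i] * i^2 / (n * (n - 1))
  }
  theta_pi - theta_h
}

oracle_fuli_d <- function(der, n) {
  seg <- der > 0 & der < n
  s <- sum(seg)
  if (s == 0) return(NA_real_)
  eta_s <- sum(der[seg] == 1)
  a_n <- sum(1 / seq_len(n - 1)); b_n <- sum(1 / seq_len(n - 1)^2)
  c_n <- 2 * (n * a_n - 2 * (n - 1)) / ((n - 1) * (n - 2))
  v_d <- 1 + a_n^2 / (b_n + a_n^2) * (c_n - (n + 1) / (n - 1))
  u_d <- a_n - 1 - v_d
  (s - a_n * eta_s) / sqrt(u_d * s + v_d * s^2)
}

# Weir & Cockerham (1984) two-population variance components for one site,
# from explicit per-population sums (n_i diploids called, p_i alt frequency,
# h_i observed heterozygote proportion)
oracle_wc_site <- function(n_i, p_i, h_i) {
  r <- length(n_i)
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                      (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  c(a = a, b = b, c = hbar / 2)
}

oracle_dxy_window <- function(pa, pb, callable) {
  total <- 0
  for (s in seq_along(pa)) total <- total + pa[s] * (1 - pb[s]) + pb[s] * (1 - pa[s])
  total / callable
}

# EHH at every site from the core outward by enumerating carrier pairs
oracle_ehh_curve <- function(haps, core, allele, direction) {
  carriers <- which(haps[core, ] == allele)
  k <- length(carriers)
  steps <- if (direction == "right") core:nrow(haps) else core:1
  out <- numeric(length(steps))
  for (si in seq_along(steps)) {
    span <- if (direction == "right") core:steps[si] else steps[si]:core
    same <- 0
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      if (all(haps[span, carriers[i]] == haps[span, carriers[j]])) same <- same + 1
    }
    out[si] <- same / (k * (k - 1) / 2)
  }
  out
}

# mean r2 over all pairs of sites from phased haplotypes
oracle_mean_r2 <- function(haps) {
  s <- nrow(haps)
  vals <- c()
  for (i in 1:(s - 1)) for (j in (i + 1):s) {
    pa <- mean(haps[i, ]); pb <- mean(haps[j, ])
    pab <- mean(haps[i, ] == 1 & haps[j, ] == 1)
    d <- pab - pa * pb
    vals <- c(vals, d^2 / (pa * (1 - pa) * pb * (1 - pb)))
  }
  mean(vals)
}

oracle_d_stat <- function(p1, p2, p3) {
  abba <- 0; baba <- 0
  for (s in seq_along(p1)) {
    abba <- abba + (1 - p1[s]) * p2[s] * p3[s]
    baba <- baba + p1[s] * (1 - p2[s]) * p3[s]
  }
  (abba - baba) / (abba + baba)
}
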