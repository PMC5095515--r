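# small genotype fixture: one population, optionally with missing ancestral
# states, wrapped as a variant_matrix on a single 50 kb window
fixture_vm <- function(seed, n_sites = 20, n_dip = 5, p_missing_aa = 0,
                       two_pop = FALSE) {
  set.seed(seed)
  n_ind <- if (two_pop) 2 * n_dip else n_dip
  p <- runif(n_sites, 0.05, 0.95)
  geno <- matrix(rbinom(n_sites * n_ind, 2, rep(p, n_ind)), n_sites, n_ind)
  ref <- sample(c("A", "C"), n_sites, TRUE)
  alt <- ifelse(ref == "A", "T", "G")
  aa <- ifelse(runif(n_sites) < 0.5, ref, alt)
  aa[runif(n_sites) < p_missing_aa] <- NA
  structure(list(
    scaffold = rep("s1", n_sites), pos = sort(sample.int(49000, n_sites)),
    ref = ref, alt = alt, aa = aa, geno = geno,
    individuals = paste0("i", seq_len(n_ind)),
    popmap = data.frame(individual = paste0("i", seq_len(n_ind)),
                        population = rep(if (two_pop) c("A", "B") else "A",
                                         each = n_dip))
  ), class = "variant_matrix")
}

fixture_windows <- function(vm) assign_windows(vm, 50000,
                                               scaffold_lengths = c(s1 = 50000))

test_that("unfolded SFS equals a brute-force tally", {
  vm <- fixture_vm(1, n_sites = 50, p_missing_aa = 0.2)
  sfs <- unfolded_sfs(vm, "A")
  n <- 10
  der <- ifelse(vm$aa == vm$ref, rowSums(vm$geno), n - rowSums(vm$geno))
  manual <- integer(n - 1)
  for (s in seq_len(50)) {
    if (!is.na(der[s]) && der[s] >= 1 && der[s] <= n - 1) {
      manual[der[s]] <- manual[der[s]] + 1L
    }
  }
  expect_equal(unname(sfs), manual)
  # one site with 3 derived of 8 alleles increments bin 3
  vm2 <- fixture_vm(2, n_sites = 1, n_dip = 4)
  vm2$geno[1, ] <- c(2L, 1L, 0L, 0L)
  vm2$aa <- vm2$ref
  expect_equal(unname(unfolded_sfs(vm2, "A")), c(0L, 0L, 1L, 0L, 0L, 0L, 0L))
})

test_that("diversity statistics match brute-force textbook evaluations", {
  vm <- fixture_vm(3, n_sites = 20)
  wi <- fixture_windows(vm)
  ds <- diversity_stats(vm, "A", wi)
  n <- 10
  alt <- rowSums(vm$geno)
  der <- ifelse(vm$aa == vm$ref, alt, n - alt)
  seg <- alt > 0 & alt < n
  expect_equal(ds$pi, oracle_pi_sum(alt[seg], rep(n, sum(seg))) / 50000,
               tolerance = 1e-10)
  expect_equal(ds$theta_w, oracle_theta_w(sum(seg), n) / 50000,
               tolerance = 1e-10)
  expect_equal(ds$taj_d, oracle_tajimas_d(alt, n), tolerance = 1e-10)
  expect_equal(ds$faywu_h, oracle_faywu_h(der, n), tolerance = 1e-10)
  expect_equal(ds$fuli_d, oracle_fuli_d(der, n), tolerance = 1e-10)
})

test_that("windows with no segregating sites give pi = 0 and undefined D", {
  vm <- fixture_vm(4, n_sites = 5)
  vm$geno[] <- 0L
  wi <- fixture_windows(vm)
  ds <- diversity_stats(vm, "A", wi)
  expect_equal(ds$pi, 0)
  expect_equal(ds$theta_w, 0)
  expect_true(is.na(ds$taj_d))
})

test_that("an excess of singletons forces Tajima's D negative", {
  vm <- fixture_vm(5, n_sites = 5)
  vm$geno[] <- 0L
  vm$geno[, 1] <- 1L  # five singletons among 10 haplotypes
  wi <- fixture_windows(vm)
  expect_lt(diversity_stats(vm, "A", wi)$taj_d, 0)
})

test_that("Weir-Cockerham components match a direct evaluation", {
  # toy table: pop1 AA, AA, Aa; pop2 aa, aa, Aa (A = ref)
  vm <- fixture_vm(6, n_sites = 1, n_dip = 3, two_pop = TRUE)
  vm$geno[1, ] <- c(0L, 0L, 1L, 2L, 2L, 1L)
  comp <- wc_fst_per_site(vm, "A", "B")
  o <- oracle_wc_site(n_i = c(3, 3), p_i = c(1 / 6, 5 / 6), h_i = c(1 / 3, 1 / 3))
  expect_equal(comp$a, unname(o["a"]), tolerance = 1e-10)
  expect_equal(comp$b, unname(o["b"]), tolerance = 1e-10)
  expect_equal(comp$c, unname(o["c"]), tolerance = 1e-10)

  # reciprocally fixed site with full calls -> F_ST = 1
  vm$geno[1, ] <- c(0L, 0L, 0L, 2L, 2L, 2L)
  comp <- wc_fst_per_site(vm, "A", "B")
  expect_equal(with(comp, a / (a + b + c)), 1)

  # identical frequencies and heterozygosities -> a ~ 0, estimate <= 0
  vm$geno[1, ] <- c(0L, 1L, 1L, 0L, 1L, 1L)
  comp <- wc_fst_per_site(vm, "A", "B")
  expect_lte(with(comp, a / (a + b + c)), 0)

  # 20-site random fixture, with missing genotypes, against the oracle
  vm <- fixture_vm(7, n_sites = 20, n_dip = 6, two_pop = TRUE)
  vm$geno[sample(length(vm$geno), 15)] <- NA
  keep <- site_coverage_filter(vm, "A", "B")
  comp <- wc_fst_per_site(vm, "A", "B")
  for (k in seq_len(nrow(comp))) {
    s <- comp$site[k]
    gA <- vm$geno[s, 1:6]; gB <- vm$geno[s, 7:12]
    o <- oracle_wc_site(
      n_i = c(sum(!is.na(gA)), sum(!is.na(gB))),
      p_i = c(mean(gA, na.rm = TRUE), mean(gB, na.rm = TRUE)) / 2,
      h_i = c(mean(gA == 1, na.rm = TRUE), mean(gB == 1, na.rm = TRUE)))
    expect_equal(unlist(comp[k, c("a", "b", "c")]), o, tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
  # window estimate is the ratio of summed components
  wi <- fixture_windows(vm)
  wf <- window_fst(comp, wi)
  expect_equal(wf$fst[1], sum(comp$a) / sum(comp$a + comp$b + comp$c),
               tolerance = 1e-10)
  expect_equal(wf$n_sites[1], nrow(comp))
})

test_that("D_xy matches hand-computed sums and label swapping", {
  vm <- fixture_vm(8, n_sites = 3, n_dip = 5, two_pop = TRUE)
  wi <- fixture_windows(vm)
  pa <- rowMeans(vm$geno[, 1:5]) / 2
  pb <- rowMeans(vm$geno[, 6:10]) / 2
  dx <- dxy(vm, "A", "B", wi)
  expect_equal(dx$dxy[1], oracle_dxy_window(pa, pb, 50000), tolerance = 1e-10)
  expect_equal(dxy(vm, "B", "A", wi)$dxy, dx$dxy)
  # one reciprocally fixed site over 10 kb callable -> 1e-4
  vm2 <- fixture_vm(9, n_sites = 1, n_dip = 5, two_pop = TRUE)
  vm2$geno[1, ] <- c(rep(0L, 5), rep(2L, 5))
  vm2$pos <- 500L
  wi2 <- assign_windows(vm2, 10000, scaffold_lengths = c(s1 = 10000))
  expect_equal(dxy(vm2, "A", "B", wi2)$dxy[1], 1e-4)
})

test_that("PBS follows its closed form and additivity identity", {
  expect_equal(pbs(0.5, 0.5, 0), log(2))
  f <- 0.3
  expect_equal(pbs(f, f, f), -log(1 - f) / 2)
  set.seed(10)
  f12 <- runif(50, 0, 0.8); f13 <- runif(50, 0, 0.8); f23 <- runif(50, 0, 0.8)
  total <- pbs(f12, f13, f23) + pbs(f12, f23, f13) + pbs(f23, f13, f12)
  expect_equal(total, (-log(1 - f12) - log(1 - f13) - log(1 - f23)) / 2,
               tolerance = 1e-12)
  expect_error(pbs(c(0.1, 0.2), 0.1, c(0.1, 0.2)), "mismatch")
})

test_that("PBS isolates the population with excess drift", {
  # trio a1, a2, b1 from the star scenario with a1's drift doubled at one
  # window via a private boost
  cfg <- star_config(seed = 23, b_min = 1, b_max = 1)
  cfg$contact_zones <- data.frame(popA = "a2", popB = "a1",
                                  n_divergent_windows = 1L,
                                  divergence_boost = 0.3)
  sim <- simulate_dataset(cfg, haplotypes = "none")
  vm <- sim_variant_matrix(sim)
  wi <- sim_window_index(sim)
  k <- sim$truth$contact_windows$window
  f12 <- window_fst(wc_fst_per_site(vm, "a1", "a2"), wi)$fst
  f13 <- window_fst(wc_fst_per_site(vm, "a1", "b1"), wi)$fst
  f23 <- window_fst(wc_fst_per_site(vm, "a2", "b1"), wi)$fst
  pbs1 <- pbs(f12, f13, f23)
  pbs2 <- pbs(f12, f23, f13)
  pbs3 <- pbs(f13, f23, f12)
  ex1 <- pbs1[k] - stats::median(pbs1, na.rm = TRUE)
  ex2 <- pbs2[k] - stats::median(pbs2, na.rm = TRUE)
  ex3 <- pbs3[k] - stats::median(pbs3, na.rm = TRUE)
  expect_gt(ex1, 0.15)              # a1's branch carries the excess drift
  expect_lt(abs(ex2), ex1 / 2)      # the other branches do not
  expect_lt(abs(ex3), ex1 / 2)
})

test_that("mean r2 matches pair enumeration and respects the MAF filter", {
  # deterministic search for a fixture with all MAF comfortably above 0.1
  for (seed in 31:200) {
    hs <- random_hap_set(seed, n_sites = 5, n_hap = 20)
    hs$pos <- c(1000L, 2000L, 3000L, 4000L, 5000L)
    if (all(pmin(hs$freq, 1 - hs$freq) > 0.12)) break
  }
  vm_stub <- structure(list(scaffold = "s1", pos = 1L), class = "variant_matrix")
  wi <- list(windows = data.frame(scaffold = "s1", win = 0L, start = 0,
                                  end = 50000, short = FALSE, row = 1L,
                                  n_callable = 50000),
             site_window = 1L, window_size = 50000)
  class(wi) <- "window_index"
  r2 <- window_r2(list(hs), wi, maf_min = 0.1)
  expect_equal(r2$mean_r2[1], oracle_mean_r2(hs$haps), tolerance = 1e-10)
  expect_equal(r2$n_snps[1], 5L)

  # two SNPs in perfect coupling -> r2 = 1
  hs2 <- hs
  hs2$haps <- rbind(hs$haps[1, ], hs$haps[1, ])
  hs2$pos <- c(1000L, 2000L)
  hs2$freq <- rowMeans(hs2$haps)
  expect_equal(window_r2(list(hs2), wi)$mean_r2[1], 1)

  # a SNP below the MAF threshold is excluded from pairs
  hs3 <- hs
  hs3$haps[1, ] <- c(1L, rep(0L, 19))  # MAF 0.05
  hs3$freq <- rowMeans(hs3$haps)
  expect_equal(window_r2(list(hs3), wi)$n_snps[1], 4L)
})

test_that("Patterson's D arithmetic and oracle equivalence", {
  # direct counts: 30 ABBA, 10 BABA -> D = 0.5
  p1 <- c(rep(0, 30), rep(1, 10))
  p2 <- 1 - p1
  p3 <- rep(1, 40)
  expect_equal(oracle_d_stat(p1, p2, p3), 0.5)
  # symmetric counts -> 0
  expect_equal(oracle_d_stat(c(0, 1), c(1, 0), c(1, 1)), 0)

  # implementation against the frequency oracle on a simulated trio
  cfg <- tiny_config(seed = 33)
  sim <- simulate_dataset(cfg, haplotypes = "none")
  vm <- sim_variant_matrix(sim)
  wi <- sim_window_index(sim)
  res <- abba_baba(vm, "cnx3", "cnx4", "ori1", wi, block_size = 10,
                   mode = "frequency")
  ac1 <- pop_allele_counts(vm, "cnx3")
  ac2 <- pop_allele_counts(vm, "cnx4")
  ac3 <- pop_allele_counts(vm, "ori1")
  expect_equal(res$d, oracle_d_stat(ac1$derived / ac1$called,
                                    ac2$derived / ac2$called,
                                    ac3$derived / ac3$called),
               tolerance = 1e-10)
  expect_true(res$defined)
})

test_that("gene flow shifts D positive while the no-flow null stays calibrated", {
  ds <- zs0 <- numeric(0)
  for (s in 1:10) {
    cfg <- sim_config(seed = 50 + s, n_scaffolds = 5L,
                      windows_per_scaffold = 60L,
                      contact_zones = NULL, sweeps = NULL, mask_fraction = 0,
                      gene_flow = data.frame(source = "ori1", sink = "cnx4",
                                             m = 0.1))
    sim <- simulate_dataset(cfg, haplotypes = "none")
    ds <- c(ds, abba_baba(sim_variant_matrix(sim), "cnx3", "cnx4", "ori1",
                          sim_window_index(sim), block_size = 30,
                          mode = "frequency")$d)
    cfg0 <- sim_config(seed = 150 + s, n_scaffolds = 5L,
                       windows_per_scaffold = 60L,
                       contact_zones = NULL, sweeps = NULL, gene_flow = NULL,
                       mask_fraction = 0)
    sim0 <- simulate_dataset(cfg0, haplotypes = "none")
    zs0 <- c(zs0, abba_baba(sim_variant_matrix(sim0), "cnx3", "cnx4", "ori1",
                            sim_window_index(sim0), block_size = 30,
                            mode = "frequency")$z)
  }
  expect_gt(mean(ds), 0)
  expect_gte(mean(abs(zs0) < 3), 0.9)
})
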