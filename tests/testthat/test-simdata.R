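test_that("linked-selection landscape is monotone in its covariates", {
  cfg <- tiny_config(seed = 2)
  nw <- cfg$n_scaffolds * cfg$windows_per_scaffold

  # no heterogeneity in, none out
  flat <- data.frame(rho = rep(1, nw), gene_density = rep(0.3, nw),
                     ds = rep(0.08, nw))
  b_flat <- build_linked_selection_landscape(cfg, flat)
  expect_true(all(b_flat == b_flat[1]))

  set.seed(9)
  cov <- data.frame(rho = runif(nw, 0.5, 2), gene_density = runif(nw),
                    ds = rep(0.08, nw))
  b <- build_linked_selection_landscape(cfg, cov)
  expect_true(all(b > 0 & b <= 1))
  # global minimum exactly where rho minimal and gene density maximal
  cov2 <- cov
  cov2$rho[5] <- min(cov$rho) - 0.1
  cov2$gene_density[5] <- max(cov$gene_density) + 0.01
  b2 <- build_linked_selection_landscape(cfg, cov2)
  expect_equal(which.min(b2), 5L)
  expect_equal(min(b2), cfg$b_min)
  # monotone: raising rho at one window cannot lower its B
  cov3 <- cov
  cov3$rho[7] <- cov3$rho[7] + 0.2
  b3 <- build_linked_selection_landscape(cfg, cov3)
  expect_gte(b3[7], b[7] - 1e-12)
})

test_that("generated landscape is autocorrelated at the configured length", {
  cfg <- sim_config(seed = 4, n_scaffolds = 1L, windows_per_scaffold = 1000L,
                    b_autocorr_length = 5, contact_zones = NULL, sweeps = NULL,
                    gene_flow = NULL, mask_fraction = 0)
  set.seed(cfg$seed)
  cov <- sim_covariates(cfg)
  b <- build_linked_selection_landscape(cfg, cov)
  lag1 <- stats::cor(b[-1], b[-length(b)])
  expect_gt(lag1, 0.5)
})

test_that("zero-length branches copy the ancestral frequency exactly", {
  cfg <- tiny_config(seed = 3)
  tree0 <- cfg$tree
  tree0$length <- 0
  cfg$tree <- tree0
  set.seed(cfg$seed)
  cov <- sim_covariates(cfg)
  b <- build_linked_selection_landscape(cfg, cov)
  sites <- sim_sites(cfg, b)
  fr <- simulate_frequencies(cfg, b, sites)
  for (p in cfg$populations$label) {
    expect_equal(unname(fr$freq[, p]), fr$p_anc)
  }
})

test_that("a planted divergence boost elevates pair F_ST above the genome median", {
  cfg <- sim_config(seed = 8, n_scaffolds = 2L, windows_per_scaffold = 30L,
                    sweeps = NULL, gene_flow = NULL, mask_fraction = 0,
                    contact_zones = data.frame(popA = "cor2", popB = "cnx1",
                                               n_divergent_windows = 4L,
                                               divergence_boost = 0.85))
  sim <- simulate_dataset(cfg, haplotypes = "none")
  vm <- sim_variant_matrix(sim)
  wi <- sim_window_index(sim)
  wf <- window_fst(wc_fst_per_site(vm, "cor2", "cnx1"), wi)$fst
  planted <- sim$truth$contact_windows$window
  expect_gt(mean(wf[planted]), stats::median(wf, na.rm = TRUE))
})

test_that("full admixture at zero depth gives the parental midpoint", {
  cfg <- tiny_config(seed = 5)
  tree0 <- cfg$tree
  tree0$length <- 0
  cfg$tree <- tree0
  cfg$gene_flow <- data.frame(source = "ori1", sink = "cnx1", m = 0.5)
  set.seed(cfg$seed)
  cov <- sim_covariates(cfg)
  b <- build_linked_selection_landscape(cfg, cov)
  sites <- sim_sites(cfg, b)
  fr <- simulate_frequencies(cfg, b, sites)
  expect_equal(unname(fr$freq[, "cnx1"]),
               unname(0.5 * fr$p_anc + 0.5 * fr$freq[, "ori1"]))
})

test_that("simulation output is deterministic given seed and config", {
  cfg <- tiny_config(seed = 11, mask_fraction = 0.1)
  s1 <- simulate_dataset(cfg, haplotypes = c("cnx1"))
  s2 <- simulate_dataset(cfg, haplotypes = c("cnx1"))
  expect_identical(s1$geno, s2$geno)
  expect_identical(s1$haplotypes, s2$haplotypes)
  expect_identical(s1$truth, s2$truth)
  d1 <- tempfile(); d2 <- tempfile()
  write_sim(s1, d1); write_sim(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("genotypes are haplotype sums and fixed sites emit correctly", {
  cfg <- tiny_config(seed = 13)
  sim <- simulate_dataset(cfg, haplotypes = "all")
  p <- cfg$populations$label[1]
  hp <- sim$haplotypes[[p]]
  g <- sim$geno[, sim$popmap$population == p]
  expect_identical(hp[, seq(1, ncol(hp), 2)] + hp[, seq(2, ncol(hp), 2)],
                   unname(g))
  # derived-fixed frequency -> everyone homozygous derived
  idx <- which(sim$freq[, p] == 1)
  if (length(idx)) expect_true(all(g[idx, ] == 2L))
  # mask fraction 0 -> empty BED
  d <- tempfile()
  write_sim(sim, d)
  expect_identical(readLines(file.path(d, "mask.bed")), character(0))
  unlink(d, recursive = TRUE)
})

test_that("sweep carriers share a haplotype tract; non-carriers do not", {
  cfg <- sweep_scan_config(seed = 21)
  sim <- simulate_dataset(cfg, haplotypes = "cnx1")
  sw <- sim$truth$sweeps
  idx <- which(sim$sites$scaffold == sw$scaffold &
                 abs(sim$sites$pos - sw$pos) <= cfg$sweep_tract_bp / 2)
  hp <- sim$haplotypes[["cnx1"]][idx, ]
  core <- which(sim$sites$scaffold == sw$scaffold & sim$sites$pos == sw$pos)
  carriers <- which(sim$haplotypes[["cnx1"]][core, ] == 1L)
  others <- setdiff(seq_len(ncol(hp)), carriers)
  pair_identity <- function(cols) {
    cmb <- utils::combn(cols, 2)
    mean(apply(cmb, 2, function(ij) mean(hp[, ij[1]] == hp[, ij[2]])))
  }
  expect_gt(pair_identity(carriers), pair_identity(others))
  expect_equal(pair_identity(carriers), 1)  # hard sweep: identical tract
})

test_that("mean pair F_ST matches the Balding-Nichols expectation", {
  cfg <- sim_config(seed = 17, n_scaffolds = 6L, windows_per_scaffold = 100L,
                    contact_zones = NULL, sweeps = NULL, gene_flow = NULL,
                    mask_fraction = 0)
  sim <- simulate_dataset(cfg, haplotypes = "none")
  vm <- sim_variant_matrix(sim)
  wi <- sim_window_index(sim)
  for (pr in list(c("cor1", "ori1"), c("cor2", "cnx1"), c("cnx2", "pec1"))) {
    wf <- window_fst(wc_fst_per_site(vm, pr[1], pr[2]), wi)$fst
    pred <- mean(bn_pair_expectation(cfg, sim$b, pr[1], pr[2]))
    se <- stats::sd(wf, na.rm = TRUE) / sqrt(sum(!is.na(wf)))
    expect_lt(abs(mean(wf, na.rm = TRUE) - pred), 3 * se)
  }
})
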