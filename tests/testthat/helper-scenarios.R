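# Shared scenario constructors for the test suite. Sizes are desk-scale
# versions of the default scenario; the defaults themselves are exercised in
# the acceptance suite.

tiny_config <- function(seed = 1L, mask_fraction = 0, ...) {
  sim_config(seed = seed, n_scaffolds = 2L, windows_per_scaffold = 20L,
             contact_zones = NULL, sweeps = NULL, gene_flow = NULL,
             mask_fraction = mask_fraction, ...)
}

# three independent clades splitting at the root: isolates the effect of the
# shared linked-selection landscape from shared ancestry
star_populations <- function(n = 10L) {
  data.frame(label = c("a1", "a2", "b1", "b2", "c1", "c2"), n = as.integer(n),
             lat = c(40, 42, 50, 52, 60, 62), lon = c(0, 5, 40, 45, 80, 85),
             phenotype = "x", stringsAsFactors = FALSE)
}

star_tree <- function(tip = 0.02) {
  data.frame(
    node = c("A", "B", "C", "a1", "a2", "b1", "b2", "c1", "c2"),
    parent = c("root", "root", "root", "A", "A", "B", "B", "C", "C"),
    length = c(1e-6, 1e-6, 1e-6, rep(tip, 6)),
    stringsAsFactors = FALSE)
}

star_config <- function(seed, b_min = 0.25, b_max = 1, tip = 0.02, ...) {
  # 80 SNPs per window: dense enough that within-stratum composition noise
  # (which scales as 1/k^2) is negligible against per-population noise (1/k)
  sim_config(seed = seed, n_scaffolds = 5L, windows_per_scaffold = 80L,
             snps_per_window = 80,
             populations = star_populations(), tree = star_tree(tip),
             contact_zones = NULL, sweeps = NULL, gene_flow = NULL,
             b_min = b_min, b_max = b_max, mask_fraction = 0, ...)
}

sweep_scan_config <- function(seed) {
  # scan genome large enough that the sweep tract is a small fraction of
  # scored sites
  sim_config(seed = seed, n_scaffolds = 3L, windows_per_scaffold = 40L,
             contact_zones = NULL, gene_flow = NULL, mask_fraction = 0,
             sweeps = data.frame(population = "cnx1", scaffold = 2L,
                                 window = 20L, sweep_strength = 1))
}

# small phased haplotype fixture with moderate LD
random_hap_set <- function(seed, n_sites = 40, n_hap = 12, scaffold = "s1") {
  set.seed(seed)
  pos <- sort(sample.int(200000, n_sites))
  haps <- matrix(0L, n_sites, n_hap)
  p <- stats::runif(n_sites, 0.1, 0.9)
  u <- stats::runif(n_hap)
  for (s in seq_len(n_sites)) {
    refresh <- stats::runif(n_hap) < 0.3
    u[refresh] <- stats::runif(sum(refresh))
    haps[s, ] <- as.integer(u < p[s])
  }
  structure(list(scaffold = scaffold, pos = pos, haps = haps,
                 freq = rowMeans(haps)), class = "hap_set")
}

# per-replicate correlation sets of the four panel quantities for a star
# scenario; pool across replicates before taking medians
panel_correlations <- function(cfg) {
  sim <- simulate_dataset(cfg, haplotypes = "none")
  vm <- sim_variant_matrix(sim)
  wi <- sim_window_index(sim)
  pops <- cfg$populations$label
  pi_m <- vapply(pops, function(p) diversity_stats(vm, p, wi)$pi,
                 numeric(nrow(wi$windows)))
  prs <- list(c("a1", "a2"), c("b1", "b2"), c("c1", "c2"))
  fst_m <- vapply(prs, function(pr)
    window_fst(wc_fst_per_site(vm, pr[1], pr[2]), wi)$fst,
    numeric(nrow(wi$windows)))
  dxy_m <- vapply(prs, function(pr) dxy(vm, pr[1], pr[2], wi)$dxy,
                  numeric(nrow(wi$windows)))
  cc <- function(x, y) stats::cor(x, y, use = "complete.obs")
  cmb <- utils::combn(length(pops), 2)
  list(
    pi_pi = apply(cmb, 2, function(ij) cc(pi_m[, ij[1]], pi_m[, ij[2]])),
    fst_pi = as.vector(outer(1:3, seq_along(pops),
      Vectorize(function(i, j) cc(fst_m[, i], pi_m[, j])))),
    fst_fst = apply(utils::combn(3, 2), 2,
      function(ij) cc(fst_m[, ij[1]], fst_m[, ij[2]])),
    fst_dxy = vapply(1:3, function(i) cc(fst_m[, i], dxy_m[, i]), numeric(1))
  )
}

# medians over correlation sets pooled across replicate simulations
panel_medians <- function(seeds, b_min, b_max) {
  reps <- lapply(seeds, function(s)
    panel_correlations(star_config(seed = s, b_min = b_min, b_max = b_max)))
  lapply(stats::setNames(nm = names(reps[[1]])), function(nm)
    stats::median(unlist(lapply(reps, `[[`, nm))))
}
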