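#' Simulate phased haplotypes for one population on one scaffold
#'
#' Haplotypes follow a lag-1 copying chain: each haplotype carries a latent
#' uniform that persists from the previous site with probability
#' exp(-d / ld_scale_bp) (d = physical distance) and is refreshed otherwise;
#' the allele at a site is 1 (derived) iff the latent uniform falls below the
#' site's population derived-allele frequency. Marginally every site is
#' Bernoulli(p); adjacent sites that share a latent value are in perfect
#' coupling, which yields a tunable r2 decay and realistic EHH behaviour.
#'
#' @param p per-site derived-allele frequencies (sorted by position)
#' @param pos 1-based positions
#' @param n_hap number of haplotypes (2 x diploids)
#' @param ld_scale_bp background LD scale
#' @return integer matrix sites x n_hap of 0/1 alleles
#' @keywords internal
sim_haplotypes_scaffold <- function(p, pos, n_hap, ld_scale_bp) {
  s <- length(p)
  if (s == 0) return(matrix(integer(0), 0, n_hap))
  persist <- c(0, exp(-diff(pos) / ld_scale_bp))
  refresh <- matrix(stats::runif(s * n_hap) >= rep(persist, n_hap), s, n_hap)
  refresh[1, ] <- TRUE
  fresh <- matrix(stats::runif(s * n_hap), s, n_hap)
  # index of the most recent refresh row, per haplotype column
  start_row <- apply(refresh * seq_len(s), 2, cummax)
  u <- matrix(fresh[cbind(as.vector(start_row), rep(seq_len(n_hap), each = s))],
              s, n_hap)
  (u < p) * 1L
}

#' Plant a selective sweep into a haplotype matrix
#'
#' The derived allele at the core site is placed on a single extended core
#' haplotype: half the haplotypes become carriers, and within the sweep tract
#' (sweep_strength * sweep_tract_bp centred on the core) all carriers copy
#' one template haplotype, so EHH on the derived background decays slowly.
#'
#' @keywords internal
plant_sweep <- function(haps, pos, core_idx, strength, sweep_tract_bp) {
  n_hap <- ncol(haps)
  k <- max(4L, round(n_hap / 2))
  carriers <- seq_len(k)
  tract <- abs(pos - pos[core_idx]) <= strength * sweep_tract_bp / 2
  template <- haps[tract, carriers[1]]
  haps[tract, carriers] <- template
  haps[core_idx, ] <- 0L
  haps[core_idx, carriers] <- 1L
  haps
}

#' Simulate a complete synthetic dataset
#'
#' Runs the full generator: covariates, linked-selection landscape B, site
#' layout, hierarchical Balding-Nichols population frequencies with planted
#' contact-zone windows and gene flow, phased haplotypes via the copying
#' chain, planted sweeps, genotypes (haplotype sums, hence marginally
#' Binomial(2, p)), an exclusion mask, and the truth tables.
#'
#' @param cfg sim_config
#' @param haplotypes which populations get phased haplotypes: "all", "none",
#'   or a character vector of labels. Genotypes of populations without
#'   haplotypes are drawn directly as Binomial(2, p).
#' @return object of class `crow_sim`: list with config, covariates, b,
#'   sites, freq, haplotypes (named list of sites x 2n matrices), geno
#'   (sites x individuals matrix of derived-allele counts), popmap,
#'   mask (data.frame scaffold/start/end, 0-based half-open), truth
#' @export
simulate_dataset <- function(cfg, haplotypes = "all") {
  set.seed(cfg$seed)
  covariates <- cfg$covariates %||% sim_covariates(cfg)
  b <- build_linked_selection_landscape(cfg, covariates)
  sites <- sim_sites(cfg, b)
  fr <- simulate_frequencies(cfg, b, sites)

  pops <- cfg$populations$label
  hap_pops <- if (identical(haplotypes, "all")) pops
              else if (identical(haplotypes, "none")) character(0)
              else intersect(pops, haplotypes)
  # sweeps require haplotypes in their population
  if (!is.null(cfg$sweeps) && nrow(cfg$sweeps)) {
    hap_pops <- union(hap_pops, intersect(cfg$sweeps$population, pops))
  }

  scafs <- unique(sites$scaffold)
  haps <- list()
  geno_cols <- list()
  sweep_truth <- list()
  for (pi in seq_along(pops)) {
    p_lab <- pops[pi]
    n_dip <- cfg$populations$n[pi]
    pcol <- fr$freq[, p_lab]
    if (p_lab %in% hap_pops) {
      hp <- matrix(integer(0), 0, 2L * n_dip)
      hp <- do.call(rbind, lapply(scafs, function(sc) {
        idx <- sites$scaffold == sc
        h <- sim_haplotypes_scaffold(pcol[idx], sites$pos[idx], 2L * n_dip,
                                     cfg$ld_scale_bp)
        h
      }))
      # plant sweeps for this population
      if (!is.null(cfg$sweeps) && nrow(cfg$sweeps)) {
        my_sw <- cfg$sweeps[cfg$sweeps$population == p_lab, , drop = FALSE]
        for (si in seq_len(nrow(my_sw))) {
          sw <- my_sw[si, ]
          sc <- paste0("scaffold_", sw$scaffold)
          gwin <- (sw$scaffold - 1L) * cfg$windows_per_scaffold + sw$window
          idx <- which(sites$scaffold == sc)
          if (!length(idx)) next
          centre <- (sw$window - 0.5) * cfg$window_size
          core_local <- which.min(abs(sites$pos[idx] - centre))
          core_global <- idx[core_local]
          hp[idx, ] <- plant_sweep(hp[idx, , drop = FALSE],
                                   sites$pos[idx], core_local,
                                   sw$sweep_strength, cfg$sweep_tract_bp)
          sweep_truth[[length(sweep_truth) + 1L]] <- data.frame(
            population = p_lab, scaffold = sc, pos = sites$pos[core_global],
            window = gwin, sweep_strength = sw$sweep_strength)
        }
      }
      haps[[p_lab]] <- hp
      g <- hp[, seq(1, 2 * n_dip, by = 2), drop = FALSE] +
           hp[, seq(2, 2 * n_dip, by = 2), drop = FALSE]
    } else {
      g <- matrix(stats::rbinom(length(pcol) * n_dip, 2, rep(pcol, n_dip)),
                  ncol = n_dip)
    }
    colnames(g) <- paste0(p_lab, "_", seq_len(n_dip))
    geno_cols[[p_lab]] <- g
  }
  geno <- do.call(cbind, geno_cols)

  # exclusion mask: a fraction of windows, drawn outside planted features
  wt <- sim_window_table(cfg)
  n_mask <- round(cfg$mask_fraction * nrow(wt))
  planted <- unique(c(fr$contact_windows$window,
                      vapply(sweep_truth, function(x) x$window, integer(1))))
  mask_pool <- setdiff(wt$window, planted)
  mask_windows <- if (n_mask > 0) sort(sample(mask_pool, n_mask)) else integer(0)
  mask <- wt[wt$window %in% mask_windows, c("scaffold", "start", "end")]
  rownames(mask) <- NULL

  # ancestral/derived base pair per site, with random REF/ALT polarity
  anc_base <- sample(c("A", "C", "G", "T"), nrow(sites), replace = TRUE)
  der_base <- vapply(anc_base, function(a)
    sample(setdiff(c("A", "C", "G", "T"), a), 1), character(1))
  ref_is_ancestral <- stats::runif(nrow(sites)) >= 0.3

  popmap <- data.frame(
    individual = colnames(geno),
    population = rep(pops, times = cfg$populations$n),
    lat = rep(cfg$populations$lat %||% rep(NA_real_, length(pops)),
              times = cfg$populations$n),
    lon = rep(cfg$populations$lon %||% rep(NA_real_, length(pops)),
              times = cfg$populations$n),
    stringsAsFactors = FALSE
  )

  truth <- list(
    b_landscape = cbind(wt, covariates[c("rho", "gene_density", "ds")],
                        b = b),
    drift = fr$drift,
    contact_windows = fr$contact_windows,
    sweeps = if (length(sweep_truth)) do.call(rbind, sweep_truth)
             else data.frame(population = character(0), scaffold = character(0),
                             pos = integer(0), window = integer(0),
                             sweep_strength = numeric(0)),
    gene_flow = cfg$gene_flow %||% data.frame(source = character(0),
                                              sink = character(0),
                                              m = numeric(0)),
    mask_windows = mask_windows
  )

  structure(list(
    config = cfg, covariates = covariates, b = b, sites = sites,
    freq = fr$freq, p_anc = fr$p_anc, haplotypes = haps, geno = geno,
    popmap = popmap, mask = mask,
    anc_base = anc_base, der_base = der_base,
    ref_is_ancestral = ref_is_ancestral,
    truth = truth
  ), class = "crow_sim")
}

#' @export
print.crow_sim <- function(x, ...) {
  cat("Synthetic multi-population dataset\n")
  cat(sprintf("  %d sites on %d scaffolds (%d windows of %d bp)\n",
              nrow(x$sites), x$config$n_scaffolds,
              nrow(x$truth$b_landscape), x$config$window_size))
  cat(sprintf("  %d populations, %d individuals, %d with phased haplotypes\n",
              nrow(x$config$populations), ncol(x$geno), length(x$haplotypes)))
  cat(sprintf("  planted: %d contact-zone windows, %d sweeps, %d masked windows\n",
              nrow(x$truth$contact_windows), nrow(x$truth$sweeps),
              length(x$truth$mask_windows)))
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits a VCF 4.2 with the ancestral allele in the `AA=` INFO tag (phased
#' genotypes where haplotypes exist, unphased otherwise), a 0-based half-open
#' exclusion-mask BED, a population map TSV (individual, population, lat,
#' lon), truth tables as TSV, the covariate track TSV, and a YAML echo of the
#' resolved configuration.
#'
#' @param sim crow_sim object
#' @param dir output directory (created if missing)
#' @return invisibly, a named character vector of the written paths
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    vcf = file.path(dir, "variants.vcf"),
    mask = file.path(dir, "mask.bed"),
    popmap = file.path(dir, "popmap.tsv"),
    b_landscape = file.path(dir, "truth_b_landscape.tsv"),
    drift = file.path(dir, "truth_drift.tsv"),
    contact = file.path(dir, "truth_contact_windows.tsv"),
    sweeps = file.path(dir, "truth_sweeps.tsv"),
    gene_flow = file.path(dir, "truth_gene_flow.tsv"),
    covariates = file.path(dir, "covariates.tsv"),
    config = file.path(dir, "config.yaml")
  )

  write_sim_vcf(sim, paths["vcf"])

  # BED: 0-based half-open; empty mask -> empty file
  mask_lines <- if (nrow(sim$mask))
    sprintf("%s\t%d\t%d", sim$mask$scaffold, sim$mask$start, sim$mask$end)
  else character(0)
  writeLines(mask_lines, paths["mask"])

  write_tsv_plain(sim$popmap, paths["popmap"])
  write_tsv_plain(sim$truth$b_landscape, paths["b_landscape"])
  drift_df <- data.frame(window = seq_len(nrow(sim$truth$drift)),
                         sim$truth$drift, check.names = FALSE)
  write_tsv_plain(drift_df, paths["drift"])
  write_tsv_plain(sim$truth$contact_windows, paths["contact"])
  write_tsv_plain(sim$truth$sweeps, paths["sweeps"])
  write_tsv_plain(sim$truth$gene_flow, paths["gene_flow"])
  write_tsv_plain(sim$covariates, paths["covariates"])

  cfg_echo <- sim$config
  cfg_echo$populations <- as.list(cfg_echo$populations)
  cfg_echo$tree <- as.list(cfg_echo$tree)
  for (nm in c("contact_zones", "sweeps", "gene_flow", "covariates")) {
    if (is.data.frame(cfg_echo[[nm]])) cfg_echo[[nm]] <- as.list(cfg_echo[[nm]])
  }
  yaml::write_yaml(unclass(cfg_echo), paths["config"])

  invisible(paths)
}

#' @keywords internal
write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write the VCF for a simulated dataset
#' @keywords internal
write_sim_vcf <- function(sim, path) {
  sites <- sim$sites
  n_sites <- nrow(sites)
  pops <- sim$config$populations$label
  n_per_pop <- sim$config$populations$n

  ref <- ifelse(sim$ref_is_ancestral, sim$anc_base, sim$der_base)
  alt <- ifelse(sim$ref_is_ancestral, sim$der_base, sim$anc_base)

  # genotype strings, phased (a|b) where haplotypes exist
  gt_cols <- vector("list", length(pops))
  for (pi in seq_along(pops)) {
    p_lab <- pops[pi]
    n_dip <- n_per_pop[pi]
    if (!is.null(sim$haplotypes[[p_lab]])) {
      hp <- sim$haplotypes[[p_lab]]  # derived coding
      # recode to ALT dosage: if REF is ancestral, ALT is derived (keep);
      # else swap
      swap <- !sim$ref_is_ancestral
      a1 <- hp[, seq(1, 2 * n_dip, 2), drop = FALSE]
      a2 <- hp[, seq(2, 2 * n_dip, 2), drop = FALSE]
      a1[swap, ] <- 1L - a1[swap, , drop = FALSE]
      a2[swap, ] <- 1L - a2[swap, , drop = FALSE]
      gt <- matrix(paste(a1, a2, sep = "|"), n_sites, n_dip)
    } else {
      g <- sim$geno[, sim$popmap$population == p_lab, drop = FALSE]
      swap <- !sim$ref_is_ancestral
      g[swap, ] <- 2L - g[swap, , drop = FALSE]
      gt <- matrix(c("0/0", "0/1", "1/1")[g + 1L], n_sites, n_dip)
    }
    gt_cols[[pi]] <- gt
  }
  gt_all <- do.call(cbind, gt_cols)

  header <- c(
    "##fileformat=VCFv4.2",
    "##source=crowscape_simulate",
    '##INFO=<ID=AA,Number=1,Type=String,Description="Ancestral allele">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(sim$geno)), collapse = "\t")
  )
  gt_glued <- do.call(paste, c(asplit(gt_all, 2), list(sep = "\t")))
  body <- paste(sites$scaffold, sites$pos, ".", ref, alt, ".", "PASS",
                paste0("AA=", sim$anc_base), "GT", gt_glued,
                sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
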