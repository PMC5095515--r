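#' Default population table for the synthetic crow-complex scenario
#'
#' Ten populations mirroring a Palearctic species complex: two western all-black
#' populations (cor1, cor2), a recent radiation of four hooded populations
#' (cnx1-cnx4), three eastern all-black populations (ori1-ori3) and one
#' collared population (pec1). Coordinates are plausible sampling locations
#' used by the isolation-by-distance analysis.
#'
#' @param n_diploid diploid sample size per population
#' @return data.frame with columns label, n, lat, lon, phenotype
#' @export
default_populations <- function(n_diploid = 10L) {
  data.frame(
    label = c("cor1", "cor2", "cnx1", "cnx2", "cnx3", "cnx4",
              "ori1", "ori2", "ori3", "pec1"),
    n = as.integer(n_diploid),
    lat = c(42, 48, 52, 60, 55, 56, 48, 52, 43, 30),
    lon = c(-5, 11, 14, 17, 37, 61, 135, 113, 132, 114),
    phenotype = c("black", "black", "pied", "pied", "pied", "pied",
                  "black", "black", "black", "pied"),
    stringsAsFactors = FALSE
  )
}

#' Default population tree for the synthetic scenario
#'
#' Rooted tree in drift units (branch lengths are the scaled divergence time
#' t of each node from its parent). The structure mirrors the study system:
#' population structure dominated by one deeply diverged refugial black
#' population (cor1) and a deep eastern black clade (ori1-ori3), while the
#' hybrid-zone pair (cor2, cnx1) is among the shallowest comparisons and the
#' hooded clade (cnx1-cnx4) is a very recent radiation off a shared
#' ancestor, as expected after postglacial expansion. Genome-wide pairwise
#' F_ST under the default linked-selection landscape spans roughly
#' 0.02-0.25.
#'
#' @return data.frame with columns node, parent, length; the root has parent NA
#' @export
default_tree <- function() {
  data.frame(
    node = c("anc1", "cor1", "anc2", "orianc", "ori1", "ori2", "ori3",
             "anc3", "pec1", "anc4", "coranc", "cor2",
             "cnxanc", "cnx1", "cnx2", "cnx3", "cnx4"),
    parent = c("root", "anc1", "anc1", "anc2", "orianc", "orianc", "orianc",
               "anc2", "anc3", "anc3", "anc4", "coranc",
               "anc4", "cnxanc", "cnxanc", "cnxanc", "cnxanc"),
    length = c(0.02, 0.10, 0.01, 0.05, 0.02, 0.02, 0.02,
               0.01, 0.08, 0.005, 0.005, 0.005,
               0.005, 0.003, 0.003, 0.003, 0.003),
    stringsAsFactors = FALSE
  )
}

#' Default focal and control comparisons
#'
#' One focal pair spanning the western contact zone (cor2-cnx1) and five
#' allopatric, phenotype-matched control pairs spanning a range of
#' genome-wide differentiation. The controls form the empirical null for
#' shared heterogeneity in differentiation.
#'
#' @return list with elements `focal` and `controls`, each a list of
#'   2-element character vectors of population labels
#' @export
default_comparisons <- function() {
  list(
    focal = list(c("cor2", "cnx1")),
    controls = list(
      c("cor1", "ori1"),
      c("cor1", "ori2"),
      c("cor2", "ori3"),
      c("cnx2", "pec1"),
      c("cnx3", "pec1")
    )
  )
}

#' Build a simulation configuration
#'
#' Assembles and validates the full configuration of the synthetic
#' multi-population generator. Defaults define the standard scenario used
#' throughout: 20 scaffolds x 100 windows of 50 kb (2,000 windows), ten
#' populations on a tree with one recent radiation, a shared linked-selection
#' landscape built from smooth recombination and gene-density covariates,
#' one contact zone with 20 planted divergent windows, three planted sweeps,
#' and weak gene flow across the contact zone.
#'
#' @param seed integer RNG seed; identical seed + config gives identical output
#' @param n_scaffolds,windows_per_scaffold,window_size genome dimensions
#' @param snps_per_window expected segregating sites per window (Poisson mean)
#' @param populations data.frame(label, n[, lat, lon]) of diploid sample sizes
#' @param tree data.frame(node, parent, length) rooted population tree with
#'   branch lengths in drift units
#' @param b_autocorr_length autocorrelation length (windows) of the generated
#'   covariate fields, hence the smoothness of the linked-selection factor B
#' @param b_min,b_max range of the linked-selection factor B, in (0, 1]
#' @param covariates optional data.frame(rho, gene_density, ds) with one row
#'   per window; generated internally when NULL
#' @param contact_zones data.frame(popA, popB, n_divergent_windows,
#'   divergence_boost); the boost is added to the drift parameter of popB
#'   (exactly one member of the pair) at the planted windows
#' @param sweeps data.frame(population, scaffold, window, sweep_strength)
#' @param gene_flow data.frame(source, sink, m) admixture edges applied after
#'   divergence, with m in [0, 0.5]
#' @param ld_scale_bp background LD scale of the haplotype copying chain
#' @param sweep_tract_bp extent of the shared core haplotype at
#'   sweep_strength = 1 (scaled linearly by sweep_strength)
#' @param mask_fraction fraction of windows covered by the exclusion mask
#' @param ancestral_2n support parameter 2N of the neutral ancestral
#'   frequency density (proportional to 1/x on (1/2N, 1 - 1/2N)); must be
#'   much larger than the sampled allele count for the sample SFS to stay
#'   neutral (the truncation removes rare variants otherwise)
#' @return object of class `sim_config`
#' @export
sim_config <- function(seed = 1L,
                       n_scaffolds = 20L,
                       windows_per_scaffold = 100L,
                       window_size = 50000L,
                       snps_per_window = 40,
                       populations = default_populations(),
                       tree = default_tree(),
                       b_autocorr_length = 10,
                       b_min = 0.25,
                       b_max = 1,
                       covariates = NULL,
                       contact_zones = data.frame(
                         popA = "cor2", popB = "cnx1",
                         n_divergent_windows = 20L,
                         divergence_boost = 0.85,
                         stringsAsFactors = FALSE
                       ),
                       sweeps = data.frame(
                         population = c("cnx1", "ori1", "cor2"),
                         scaffold = c(2L, 7L, 13L),
                         window = c(50L, 25L, 75L),
                         sweep_strength = 1,
                         stringsAsFactors = FALSE
                       ),
                       gene_flow = data.frame(
                         source = "cnx1", sink = "cor2", m = 0.05,
                         stringsAsFactors = FALSE
                       ),
                       ld_scale_bp = 10000,
                       sweep_tract_bp = 400000,
                       mask_fraction = 0.05,
                       ancestral_2n = 2000L) {
  cfg <- list(
    seed = as.integer(seed),
    n_scaffolds = as.integer(n_scaffolds),
    windows_per_scaffold = as.integer(windows_per_scaffold),
    window_size = as.integer(window_size),
    snps_per_window = snps_per_window,
    populations = populations,
    tree = tree,
    b_autocorr_length = b_autocorr_length,
    b_min = b_min,
    b_max = b_max,
    covariates = covariates,
    contact_zones = contact_zones,
    sweeps = sweeps,
    gene_flow = gene_flow,
    ld_scale_bp = ld_scale_bp,
    sweep_tract_bp = sweep_tract_bp,
    mask_fraction = mask_fraction,
    ancestral_2n = as.integer(ancestral_2n)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @keywords internal
validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_scaffolds >= 1, cfg$windows_per_scaffold >= 1, cfg$window_size >= 1,
    cfg$snps_per_window > 0,
    is.data.frame(cfg$populations),
    all(c("label", "n") %in% names(cfg$populations)),
    is.data.frame(cfg$tree),
    all(c("node", "parent", "length") %in% names(cfg$tree)),
    cfg$b_min > 0, cfg$b_min <= cfg$b_max, cfg$b_max <= 1,
    cfg$b_autocorr_length > 0,
    cfg$mask_fraction >= 0, cfg$mask_fraction < 1,
    cfg$ancestral_2n >= 4
  )
  if (any(cfg$populations$n < 2)) {
    stop("every population needs at least 2 diploid individuals")
  }
  if (anyDuplicated(cfg$populations$label)) {
    stop("duplicated population labels")
  }
  # every population must be a tip of the tree
  missing_tips <- setdiff(cfg$populations$label, cfg$tree$node)
  if (length(missing_tips)) {
    stop("populations absent from tree: ", paste(missing_tips, collapse = ", "))
  }
  if (any(cfg$tree$length < 0)) stop("negative branch lengths")
  if (!is.null(cfg$contact_zones) && nrow(cfg$contact_zones)) {
    cz <- cfg$contact_zones
    stopifnot(all(c("popA", "popB", "n_divergent_windows",
                    "divergence_boost") %in% names(cz)))
    if (any(cz$divergence_boost <= 0)) stop("divergence_boost must be > 0")
    bad <- setdiff(c(cz$popA, cz$popB), cfg$populations$label)
    if (length(bad)) stop("unknown contact-zone population: ",
                          paste(bad, collapse = ", "))
  }
  if (!is.null(cfg$gene_flow) && nrow(cfg$gene_flow)) {
    gf <- cfg$gene_flow
    if (any(gf$m < 0 | gf$m > 0.5)) stop("admixture fraction m must lie in [0, 0.5]")
    bad <- setdiff(c(gf$source, gf$sink), cfg$populations$label)
    if (length(bad)) stop("unknown gene-flow population: ",
                          paste(bad, collapse = ", "))
  }
  if (!is.null(cfg$sweeps) && nrow(cfg$sweeps)) {
    sw <- cfg$sweeps
    bad <- setdiff(sw$population, cfg$populations$label)
    if (length(bad)) stop("unknown sweep population: ", paste(bad, collapse = ", "))
    if (any(sw$scaffold < 1 | sw$scaffold > cfg$n_scaffolds) ||
        any(sw$window < 1 | sw$window > cfg$windows_per_scaffold)) {
      stop("sweep coordinates outside the simulated genome")
    }
    if (any(sw$sweep_strength <= 0 | sw$sweep_strength > 1)) {
      stop("sweep_strength must lie in (0, 1]")
    }
  }
  invisible(cfg)
}

#' Window coordinate table for a configuration
#'
#' @param cfg sim_config
#' @return data.frame(window, scaffold, win_in_scaffold, start, end) with
#'   0-based half-open coordinates; `window` is a 1-based genome-wide index
#' @export
sim_window_table <- function(cfg) {
  n_win <- cfg$n_scaffolds * cfg$windows_per_scaffold
  scaf <- rep(seq_len(cfg$n_scaffolds), each = cfg$windows_per_scaffold)
  wis <- rep(seq_len(cfg$windows_per_scaffold), times = cfg$n_scaffolds)
  data.frame(
    window = seq_len(n_win),
    scaffold = paste0("scaffold_", scaf),
    win_in_scaffold = wis,
    start = (wis - 1L) * cfg$window_size,
    end = wis * cfg$window_size
  )
}
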