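#' Ancestral allele frequencies from the neutral-SFS density, stratified
#' per window
#'
#' Ancestral derived-allele frequencies follow the density proportional to
#' 1/x on (1/2N, 1 - 1/2N), the neutral site-frequency expectation, so that
#' unfolded-SFS statistics computed downstream are meaningful. Sampling is
#' stratified within each window (one uniform jitter per equal-probability
#' stratum of the density, randomly assigned to positions): each site's
#' marginal distribution, and hence every SFS functional, is exactly that
#' of the 1/x density, while between-window variation in ancestral
#' frequency composition is suppressed, so between-window diversity
#' heterogeneity is attributable to the linked-selection landscape rather
#' than to shared catalogue noise.
#'
#' @param window_of window id per site
#' @param two_n density support parameter 2N
#' @return numeric vector of ancestral derived-allele frequencies per site
#' @keywords internal
stratified_ancestral_freqs <- function(window_of, two_n) {
  a <- 1 / two_n
  b <- 1 - 1 / two_n
  q <- function(u) a * (b / a)^u  # quantile function of density c/x
  out <- numeric(length(window_of))
  for (idx in split(seq_along(window_of), window_of)) {
    k <- length(idx)
    u <- (seq_len(k) - stats::runif(k)) / k
    out[idx] <- sample(q(u))
  }
  out
}

#' Balding-Nichols draw of daughter frequencies
#'
#' Daughter frequency ~ Beta(p (1-F)/F, (1-p)(1-F)/F) around the parent
#' frequency p with drift parameter F. F ~ 0 copies the parent; monomorphic
#' parents stay fixed.
#' @keywords internal
bn_draw <- function(p, f) {
  out <- p
  live <- f > 1e-12 & p > 0 & p < 1
  if (any(live)) {
    fl <- f[live]
    pl <- p[live]
    out[live] <- stats::rbeta(sum(live),
                              pl * (1 - fl) / fl,
                              (1 - pl) * (1 - fl) / fl)
  }
  out
}

#' Simulate per-site population allele frequencies on the tree
#'
#' Hierarchical Balding-Nichols model standing in for the coalescent history:
#' an ancestral frequency per site from the neutral 1/x density evolves down
#' the population tree; on each branch of drift-length t the frequency is
#' drawn from a Balding-Nichols beta around the parent's frequency with
#' drift parameter F = 1 - exp(-t / B_w), so drift is amplified in windows
#' where the linked-selection factor B_w is small. Planted contact-zone
#' windows add `divergence_boost` to F on the tip branch of exactly one
#' member of the focal pair (popB). Gene-flow edges then mix sink
#' frequencies as (1 - m) p_sink + m p_source.
#'
#' @param cfg sim_config
#' @param b per-window linked-selection factor from
#'   [build_linked_selection_landscape()]
#' @param sites data.frame(scaffold, pos, window) of segregating-site
#'   coordinates (see [sim_sites()])
#' @return list with elements `freq` (matrix sites x populations), `p_anc`,
#'   `drift` (matrix windows x populations of tip-path drift F incl. boost),
#'   and `contact_windows` (data.frame of planted windows)
#' @export
simulate_frequencies <- function(cfg, b, sites) {
  n_sites <- nrow(sites)
  win <- sites$window
  p_anc <- stratified_ancestral_freqs(win, cfg$ancestral_2n)

  tree <- cfg$tree
  # topological order: parents before children, starting from "root"
  ord <- character(0)
  frontier <- "root"
  while (length(frontier)) {
    kids <- tree$node[tree$parent %in% frontier]
    ord <- c(ord, kids)
    frontier <- kids
  }
  if (!setequal(ord, tree$node)) stop("tree is not a connected rooted tree")

  freqs <- list(root = p_anc)
  f_branch <- list()  # per-node drift F vector over sites
  for (nd in ord) {
    t_len <- tree$length[tree$node == nd]
    parent <- tree$parent[tree$node == nd]
    f <- 1 - exp(-t_len / b[win])
    f_branch[[nd]] <- f
    freqs[[nd]] <- bn_draw(freqs[[parent]], f)
  }

  # planted contact-zone windows: redraw popB's tip branch with boosted F
  contact_windows <- data.frame(popA = character(0), popB = character(0),
                                window = integer(0), boost = numeric(0))
  if (!is.null(cfg$contact_zones) && nrow(cfg$contact_zones)) {
    n_win <- cfg$n_scaffolds * cfg$windows_per_scaffold
    avoid <- unique(c(
      if (!is.null(cfg$sweeps) && nrow(cfg$sweeps))
        (cfg$sweeps$scaffold - 1L) * cfg$windows_per_scaffold + cfg$sweeps$window
    ))
    for (i in seq_len(nrow(cfg$contact_zones))) {
      cz <- cfg$contact_zones[i, ]
      pool <- setdiff(seq_len(n_win), c(avoid, contact_windows$window))
      planted <- sort(sample(pool, cz$n_divergent_windows))
      pop <- cz$popB
      t_len <- tree$length[tree$node == pop]
      parent <- tree$parent[tree$node == pop]
      idx <- win %in% planted
      f_boost <- pmin(1 - exp(-t_len / b[win[idx]]) + cz$divergence_boost,
                      0.999)
      f_branch[[pop]][idx] <- f_boost
      freqs[[pop]][idx] <- bn_draw(freqs[[parent]][idx], f_boost)
      contact_windows <- rbind(contact_windows, data.frame(
        popA = cz$popA, popB = cz$popB, window = planted,
        boost = cz$divergence_boost))
    }
  }

  # gene flow: mix sink frequencies after divergence
  if (!is.null(cfg$gene_flow) && nrow(cfg$gene_flow)) {
    for (i in seq_len(nrow(cfg$gene_flow))) {
      gf <- cfg$gene_flow[i, ]
      freqs[[gf$sink]] <- (1 - gf$m) * freqs[[gf$sink]] + gf$m * freqs[[gf$source]]
    }
  }

  pops <- cfg$populations$label
  fr <- do.call(cbind, freqs[pops])
  colnames(fr) <- pops
  if (any(fr < 0 | fr > 1)) {
    stop("simulated frequency outside [0, 1]; this is a bug")
  }

  # per-window per-population drift along the path root -> tip:
  # F_total = 1 - prod(1 - F_branch)
  n_win <- cfg$n_scaffolds * cfg$windows_per_scaffold
  drift <- matrix(0, n_win, length(pops), dimnames = list(NULL, pops))
  path_to_root <- function(nd) {
    path <- character(0)
    while (nd != "root") {
      path <- c(path, nd)
      nd <- tree$parent[tree$node == nd]
    }
    path
  }
  first_site_in_win <- match(seq_len(n_win), win)  # NA for empty windows
  for (p in pops) {
    surv <- rep(1, n_sites)
    for (nd in path_to_root(p)) surv <- surv * (1 - f_branch[[nd]])
    fw <- (1 - surv)[first_site_in_win]
    drift[, p] <- fw
  }

  list(freq = fr, p_anc = p_anc, drift = drift,
       contact_windows = contact_windows)
}

#' Balding-Nichols expectation of pairwise F_ST
#'
#' For two populations with Balding-Nichols drift along the tree, only
#' drift accumulated below the pair's most recent common ancestor
#' differentiates them; the expected Weir-Cockerham F_ST per window is the
#' mean of the two tip drift parameters measured from the MRCA:
#' F_tip = 1 - prod(1 - F_branch) over branches MRCA -> tip, with
#' F_branch = 1 - exp(-t / B_w).
#'
#' @param cfg sim_config
#' @param b per-window linked-selection factor
#' @param popA,popB population labels
#' @return numeric vector, expected F_ST per window
#' @export
bn_pair_expectation <- function(cfg, b, popA, popB) {
  tree <- cfg$tree
  path_nodes <- function(nd) {
    path <- character(0)
    while (nd != "root") {
      path <- c(path, nd)
      nd <- tree$parent[tree$node == nd]
    }
    path
  }
  pa <- path_nodes(popA)
  pb <- path_nodes(popB)
  shared <- intersect(pa, pb)
  f_below <- function(path) {
    below <- setdiff(path, shared)
    surv <- rep(1, length(b))
    for (nd in below) {
      t_len <- tree$length[tree$node == nd]
      surv <- surv * exp(-t_len / b)
    }
    1 - surv
  }
  (f_below(pa) + f_below(pb)) / 2
}

#' Lay out segregating-site positions
#'
#' Site counts per window equal snps_per_window scaled by the relative
#' linked-selection factor B_w / mean(B) (rounded): linked selection thins
#' polymorphism already in the ancestral population, so windows under
#' strong background selection carry fewer segregating sites in every
#' descendant population (the shared-architecture signal behind the
#' negative F_ST vs pi and F_ST vs D_xy correlations). Counts are
#' deterministic given B so that, with a flat landscape, no shared
#' catalogue noise couples the populations. Positions are uniform within
#' the window, unique and sorted.
#'
#' @param cfg sim_config
#' @param b per-window linked-selection factor; NULL for uniform density
#' @return data.frame(scaffold, pos (1-based), window (genome-wide 1-based))
#' @export
sim_sites <- function(cfg, b = NULL) {
  wt <- sim_window_table(cfg)
  lambda <- if (is.null(b)) rep(cfg$snps_per_window, nrow(wt))
            else cfg$snps_per_window * b / mean(b)
  n_per_win <- round(lambda)
  n_per_win <- pmin(n_per_win, cfg$window_size)  # cannot exceed positions
  rows <- vector("list", nrow(wt))
  for (i in seq_len(nrow(wt))) {
    k <- n_per_win[i]
    if (k == 0) next
    pos <- sort(sample.int(cfg$window_size, k)) + wt$start[i]
    rows[[i]] <- data.frame(scaffold = wt$scaffold[i], pos = pos,
                            window = wt$window[i])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
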