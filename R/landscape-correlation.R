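#' Moran's I along genomic windows
#'
#' Spatial autocorrelation of a window track with lag-1 adjacency weights
#' along each scaffold (binary neighbours, row-normalized). Scaffold values
#' are combined genome-wide as the weight-sum-weighted average. Adjacency is
#' defined between consecutive windows that are both non-missing.
#'
#' @param values numeric window track
#' @param windows window_index
#' @return list(genome = scalar I, per_scaffold = data.frame(scaffold, i, n,
#'   w_sum))
#' @export
morans_i <- function(values, windows) {
  wt <- windows$windows
  stopifnot(length(values) == nrow(wt))
  per <- lapply(unique(wt$scaffold), function(sc) {
    x <- values[wt$scaffold == sc]
    ok <- !is.na(x)
    x <- x[ok]
    n <- length(x)
    if (n < 3) return(NULL)
    if (stats::sd(x) == 0) {
      return(data.frame(scaffold = sc, i = NA_real_, n = n, w_sum = NA_real_))
    }
    xc <- x - mean(x)
    # row-normalized lag-1 weights: interior rows have two neighbours at 1/2,
    # edge rows one neighbour at 1
    wrow <- c(1, rep(0.5, max(0, n - 2)), 1)
    cross <- numeric(n)
    cross[1] <- xc[2]
    cross[n] <- xc[n - 1]
    if (n > 2) cross[2:(n - 1)] <- 0.5 * (xc[1:(n - 2)] + xc[3:n])
    # cross already carries the row weights for interior rows
    num <- sum(xc * cross)
    w_sum <- n  # rows sum to 1 each
    i_val <- (n / w_sum) * num / sum(xc^2)
    data.frame(scaffold = sc, i = i_val, n = n, w_sum = w_sum)
  })
  per <- do.call(rbind, per)
  if (is.null(per) || all(is.na(per$i))) {
    return(list(genome = NA_real_, per_scaffold = per))
  }
  ok <- !is.na(per$i)
  genome <- sum(per$i[ok] * per$w_sum[ok]) / sum(per$w_sum[ok])
  list(genome = genome, per_scaffold = per)
}

#' Pearson correlation panels for window tracks
#'
#' Reproduces the four correlation panels used to demonstrate shared linked
#' selection:
#' (a) each intra-population statistic correlated between population pairs;
#' (b) pairs of statistics within populations;
#' (c) intra-population vs inter-population (differentiation) statistics;
#' (d) inter-population statistics between pairs of comparisons, excluding
#'     pseudo-replicated pairs-of-pairs that share a population.
#'
#' @param intra named list: statistic -> matrix windows x populations
#' @param inter named list: statistic -> matrix windows x comparisons, with
#'   comparison columns named "popA.popB"
#' @param partial_on optional per-window covariate; when supplied, panel (a)
#'   correlations are also computed as partial correlations controlling for
#'   it (column `r_partial`)
#' @param min_windows minimum overlapping windows for a stable r
#' @return data.frame(panel, stat1, unit1, stat2, unit2, r, n[, r_partial])
#' @export
correlation_panels <- function(intra, inter, partial_on = NULL,
                               min_windows = 10) {
  rows <- list()
  add <- function(panel, stat1, unit1, stat2, unit2, x, y) {
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    r <- if (n >= min_windows) stats::cor(x[ok], y[ok]) else NA_real_
    row <- data.frame(panel = panel, stat1 = stat1, unit1 = unit1,
                      stat2 = stat2, unit2 = unit2, r = r, n = n,
                      unstable = n < min_windows,
                      stringsAsFactors = FALSE)
    if (!is.null(partial_on) && panel == "a") {
      okp <- ok & !is.na(partial_on)
      row$r_partial <- if (sum(okp) >= min_windows) {
        rx <- stats::resid(stats::lm(x[okp] ~ partial_on[okp]))
        ry <- stats::resid(stats::lm(y[okp] ~ partial_on[okp]))
        stats::cor(rx, ry)
      } else NA_real_
    } else if (!is.null(partial_on)) {
      row$r_partial <- NA_real_
    }
    rows[[length(rows) + 1L]] <<- row
  }

  # (a) same intra-population statistic between populations
  for (st in names(intra)) {
    m <- intra[[st]]
    pops <- colnames(m)
    if (length(pops) >= 2) {
      for (i in seq_len(length(pops) - 1)) for (j in (i + 1):length(pops)) {
        add("a", st, pops[i], st, pops[j], m[, i], m[, j])
      }
    }
  }
  # (b) pairs of statistics within populations
  stats_n <- names(intra)
  if (length(stats_n) >= 2) {
    for (si in seq_len(length(stats_n) - 1)) for (sj in (si + 1):length(stats_n)) {
      common <- intersect(colnames(intra[[stats_n[si]]]),
                          colnames(intra[[stats_n[sj]]]))
      for (p in common) {
        add("b", stats_n[si], p, stats_n[sj], p,
            intra[[stats_n[si]]][, p], intra[[stats_n[sj]]][, p])
      }
    }
  }
  # (c) intra vs inter: each population statistic against each comparison
  # statistic involving that population
  for (st in names(intra)) {
    for (ist in names(inter)) {
      m <- inter[[ist]]
      for (cmp in colnames(m)) {
        members <- strsplit(cmp, ".", fixed = TRUE)[[1]]
        for (p in intersect(members, colnames(intra[[st]]))) {
          add("c", st, p, ist, cmp, intra[[st]][, p], m[, cmp])
        }
      }
    }
  }
  # (d) inter-population statistic between disjoint comparisons
  for (ist in names(inter)) {
    m <- inter[[ist]]
    cmps <- colnames(m)
    if (length(cmps) >= 2) {
      for (i in seq_len(length(cmps) - 1)) for (j in (i + 1):length(cmps)) {
        mi <- strsplit(cmps[i], ".", fixed = TRUE)[[1]]
        mj <- strsplit(cmps[j], ".", fixed = TRUE)[[1]]
        if (length(intersect(mi, mj))) next  # pseudo-replicated, excluded
        add("d", ist, cmps[i], ist, cmps[j], m[, i], m[, j])
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Recombination-by-gene-density interaction model for diversity
#'
#' Ordinary least squares of per-window nucleotide diversity on the
#' population recombination proxy, gene density and their interaction, with
#' standardized predictors: pi ~ rho + g + rho:g. A positive, significant
#' interaction (the gene-density effect weakening as recombination rises)
#' is the background-selection signature.
#'
#' @param pi_track,rho_track,gene_density_track aligned window tracks
#' @return list(coefficients, interaction, interaction_p, r_squared, n,
#'   collinear, fit)
#' @export
interaction_model <- function(pi_track, rho_track, gene_density_track) {
  ok <- !is.na(pi_track) & !is.na(rho_track) & !is.na(gene_density_track)
  if (sum(ok) < 30) stop("need at least 30 aligned non-missing windows")
  z <- function(x) {
    s <- stats::sd(x)
    if (s == 0) return(rep(0, length(x)))
    (x - mean(x)) / s
  }
  rho <- z(rho_track[ok])
  g <- z(gene_density_track[ok])
  y <- pi_track[ok]
  collinear <- stats::sd(rho) == 0 || stats::sd(g) == 0 ||
    abs(suppressWarnings(stats::cor(rho, g))) > 0.999
  if (collinear) {
    return(list(coefficients = NULL, interaction = NA_real_,
                interaction_p = NA_real_, r_squared = NA_real_,
                n = sum(ok), collinear = TRUE, fit = NULL))
  }
  fit <- stats::lm(y ~ rho * g)
  sm <- summary(fit)
  co <- sm$coefficients
  list(coefficients = co,
       interaction = co["rho:g", "Estimate"],
       interaction_p = co["rho:g", "Pr(>|t|)"],
       r_squared = sm$r.squared,
       n = sum(ok), collinear = FALSE, fit = fit)
}
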