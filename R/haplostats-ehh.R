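#' Extended haplotype homozygosity decay curve
#'
#' EHH at distance x from the core site is the probability that two distinct
#' haplotypes carrying the core allele are identical over all sites between
#' the core and x. EHH(0) = 1 and the curve is non-increasing away from the
#' core.
#'
#' @param hs hap_set (single scaffold)
#' @param core site index of the core SNP within the hap_set
#' @param allele core allele defining the carrier set (1 = derived,
#'   0 = ancestral), or NULL to use all haplotypes with the core site itself
#'   included in the homozygosity (the XP-EHH convention)
#' @param direction "right" (increasing position) or "left"
#' @return data.frame(idx, pos, ehh) starting at the core
#' @export
ehh <- function(hs, core, allele = 1L, direction = c("right", "left")) {
  direction <- match.arg(direction)
  if (is.null(allele)) {
    carriers <- seq_len(ncol(hs$haps))
    group <- match(hs$haps[core, carriers], unique(hs$haps[core, carriers]))
  } else {
    carriers <- which(hs$haps[core, ] == allele)
    if (length(carriers) < 2) stop("fewer than 2 carriers of the core allele")
    group <- rep(1L, length(carriers))
  }
  k <- length(carriers)
  pairs_total <- k * (k - 1) / 2
  steps <- if (direction == "right") seq(core, nrow(hs$haps))
           else seq(core, 1L)
  out_idx <- integer(length(steps))
  out_ehh <- numeric(length(steps))
  for (i in seq_along(steps)) {
    j <- steps[i]
    if (j != core) {
      key <- group * 2L + hs$haps[j, carriers]
      group <- match(key, unique(key))
    }
    tab <- tabulate(group)
    out_idx[i] <- j
    out_ehh[i] <- sum(tab * (tab - 1) / 2) / pairs_total
  }
  data.frame(idx = out_idx, pos = hs$pos[out_idx], ehh = out_ehh)
}

#' Integrated EHH in one direction
#'
#' Trapezoid integral of the EHH curve against distance (physical bp, or
#' number of segregating sites for nSL-type lengths), truncated at the first
#' site where EHH drops below `min_ehh` (the segment down to that site is
#' included). Returns NA when the curve never decays below the threshold
#' before the scaffold end (no extrapolation) or when a gap between adjacent
#' sites exceeds `max_gap` before truncation.
#'
#' @keywords internal
ihh_one_side <- function(hs, core, allele, direction, min_ehh = 0.05,
                         metric = c("bp", "sites"), max_gap = Inf) {
  metric <- match.arg(metric)
  n_sites <- nrow(hs$haps)
  if (is.null(allele)) {
    carriers <- seq_len(ncol(hs$haps))
    group <- match(hs$haps[core, ], unique(hs$haps[core, ]))
  } else {
    carriers <- which(hs$haps[core, ] == allele)
    if (length(carriers) < 2) stop("fewer than 2 carriers of the core allele")
    group <- rep(1L, length(carriers))
  }
  k <- length(carriers)
  pairs_total <- k * (k - 1) / 2
  tab <- tabulate(group)
  ehh_prev <- sum(tab * (tab - 1) / 2) / pairs_total
  steps <- if (direction == "right") seq(core, n_sites) else seq(core, 1L)
  total <- 0
  x_prev <- 0
  for (i in seq_along(steps)[-1]) {
    j <- steps[i]
    key <- group * 2L + hs$haps[j, carriers]
    group <- match(key, unique(key))
    tab <- tabulate(group)
    ehh_j <- sum(tab * (tab - 1) / 2) / pairs_total
    x_j <- if (metric == "bp") abs(hs$pos[j] - hs$pos[core]) else i - 1
    if (metric == "bp" && (x_j - x_prev) > max_gap) return(NA_real_)
    total <- total + (x_j - x_prev) * (ehh_prev + ehh_j) / 2
    if (ehh_j < min_ehh) return(total)
    ehh_prev <- ehh_j
    x_prev <- x_j
  }
  NA_real_  # EHH never decayed below threshold before the scaffold end
}

#' Integrated EHH for one allele at one core site (both directions)
#' @keywords internal
ihh_site <- function(hs, core, allele, min_ehh = 0.05,
                     metric = "bp", max_gap = Inf) {
  l <- ihh_one_side(hs, core, allele, "left", min_ehh, metric, max_gap)
  r <- ihh_one_side(hs, core, allele, "right", min_ehh, metric, max_gap)
  l + r
}

#' Unstandardized iHS / nSL scan over a set of scaffolds
#'
#' For every core site with both alleles carried by at least two haplotypes
#' and derived-allele frequency within [maf_min, 1 - maf_min], computes
#' integrated EHH on the ancestral and derived backgrounds and the
#' unstandardized statistic ln(iHH_ancestral / iHH_derived), so sweeps on
#' the derived background give negative values. `metric = "bp"` is iHS;
#' `metric = "sites"` (haplotype length counted in segregating sites) is nSL.
#'
#' @param hapsets list of hap_set objects
#' @param min_ehh truncation threshold for the EHH integral
#' @param maf_min minimum minor (derived or ancestral) frequency of scored
#'   cores
#' @param metric "bp" (iHS) or "sites" (nSL)
#' @param max_gap flag sites whose integral would span a physical gap larger
#'   than this (bp metric only)
#' @return data.frame(scaffold, pos, freq, ihh_a, ihh_d, raw)
#' @export
ihs_scan <- function(hapsets, min_ehh = 0.05, maf_min = 0.05,
                     metric = c("bp", "sites"), max_gap = 200000) {
  metric <- match.arg(metric)
  res <- lapply(hapsets, function(hs) {
    n_hap <- ncol(hs$haps)
    cnt <- round(hs$freq * n_hap)
    score <- which(hs$freq >= maf_min & hs$freq <= 1 - maf_min &
                     cnt >= 2 & (n_hap - cnt) >= 2)
    if (!length(score)) return(NULL)
    ihh_a <- ihh_d <- rep(NA_real_, length(score))
    for (i in seq_along(score)) {
      ihh_a[i] <- ihh_site(hs, score[i], 0L, min_ehh, metric, max_gap)
      ihh_d[i] <- ihh_site(hs, score[i], 1L, min_ehh, metric, max_gap)
    }
    data.frame(scaffold = hs$scaffold, pos = hs$pos[score],
               freq = hs$freq[score], ihh_a = ihh_a, ihh_d = ihh_d,
               raw = log(ihh_a / ihh_d))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Cross-population EHH (XP-EHH) scan
#'
#' At every site shared between the two phased populations, integrates the
#' all-haplotype EHH (homozygosity including the core site) in each
#' population and returns ln(iHH_A / iHH_B), standardized genome-wide to
#' mean 0 and s.d. 1. Positive extremes indicate longer haplotypes (a
#' sweep) in population A.
#'
#' @param hapsets_a,hapsets_b lists of hap_set objects for the two
#'   populations (matched scaffolds)
#' @param min_ehh truncation threshold
#' @param max_gap physical gap flag
#' @return data.frame(scaffold, pos, raw, std)
#' @export
xpehh_scan <- function(hapsets_a, hapsets_b, min_ehh = 0.05,
                       max_gap = 200000) {
  names_a <- vapply(hapsets_a, `[[`, character(1), "scaffold")
  names_b <- vapply(hapsets_b, `[[`, character(1), "scaffold")
  res <- lapply(intersect(names_a, names_b), function(sc) {
    ha <- hapsets_a[[match(sc, names_a)]]
    hb <- hapsets_b[[match(sc, names_b)]]
    shared <- intersect(ha$pos, hb$pos)
    if (length(shared) < 2) return(NULL)
    ia <- match(shared, ha$pos)
    ib <- match(shared, hb$pos)
    hsa <- structure(list(scaffold = sc, pos = shared,
                          haps = ha$haps[ia, , drop = FALSE],
                          freq = ha$freq[ia]), class = "hap_set")
    hsb <- structure(list(scaffold = sc, pos = shared,
                          haps = hb$haps[ib, , drop = FALSE],
                          freq = hb$freq[ib]), class = "hap_set")
    raw <- rep(NA_real_, length(shared))
    for (i in seq_along(shared)) {
      ihh_a <- ihh_site(hsa, i, NULL, min_ehh, "bp", max_gap)
      ihh_b <- ihh_site(hsb, i, NULL, min_ehh, "bp", max_gap)
      raw[i] <- log(ihh_a / ihh_b)
    }
    data.frame(scaffold = sc, pos = shared, raw = raw)
  })
  out <- do.call(rbind, res)
  if (is.null(out) || !nrow(out)) return(out)
  rownames(out) <- NULL
  mu <- mean(out$raw, na.rm = TRUE)
  sg <- stats::sd(out$raw, na.rm = TRUE)
  out$std <- (out$raw - mu) / sg
  out
}
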