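#' Mantel test of isolation by distance
#'
#' Genetic distance between populations is F_ST / (1 - F_ST); geographic
#' distance is the great-circle distance between population coordinates on a
#' spherical Earth (radius 6,371 km). Pooled sampling locations should be
#' summarized beforehand with [pooled_coordinates()]. Significance comes
#' from a Mantel test permuting population labels; residuals from the
#' least-squares line of genetic on geographic distance are returned per
#' pair (strongly negative residuals flag pairs genetically more similar
#' than their distance predicts).
#'
#' @param fst_matrix square symmetric matrix of pairwise genome-wide F_ST
#'   with population labels as dimnames
#' @param coordinates data.frame(population, lat, lon)
#' @param n_perm Mantel permutations
#' @param seed optional RNG seed
#' @return list(r, p_value, residuals = data.frame(popA, popB, gen_dist,
#'   geo_dist_km, residual), gen_dist, geo_dist)
#' @export
ibd_mantel <- function(fst_matrix, coordinates, n_perm = 9999, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pops <- rownames(fst_matrix)
  stopifnot(!is.null(pops), all(pops == colnames(fst_matrix)))
  idx <- match(pops, coordinates$population)
  if (anyNA(idx)) stop("coordinates missing for some populations")
  ll <- coordinates[idx, ]

  if (any(fst_matrix[upper.tri(fst_matrix)] >= 1)) {
    warning("F_ST = 1 gives infinite genetic distance")
  }
  gen <- fst_matrix / (1 - fst_matrix)
  geo <- matrix(0, length(pops), length(pops), dimnames = dimnames(fst_matrix))
  for (i in seq_along(pops)) for (j in seq_along(pops)) {
    if (i < j) {
      d <- geosphere::distHaversine(c(ll$lon[i], ll$lat[i]),
                                    c(ll$lon[j], ll$lat[j]),
                                    r = 6371)
      geo[i, j] <- geo[j, i] <- d
    }
  }

  mt <- vegan::mantel(stats::as.dist(gen), stats::as.dist(geo),
                      method = "pearson", permutations = n_perm)

  gv <- gen[upper.tri(gen)]
  dv <- geo[upper.tri(geo)]
  fit <- stats::lm(gv ~ dv)
  ut <- which(upper.tri(gen), arr.ind = TRUE)
  residuals <- data.frame(
    popA = pops[ut[, 1]], popB = pops[ut[, 2]],
    gen_dist = gv, geo_dist_km = dv,
    residual = stats::resid(fit)
  )
  list(r = unname(mt$statistic), p_value = mt$signif,
       residuals = residuals, gen_dist = gen, geo_dist = geo)
}

#' Tension-zone selection scaling with hybrid-zone width
#'
#' Under the tension-zone model the selection coefficient maintaining a
#' hybrid zone of width w with dispersal sigma scales as s ~ (sigma / w)^2.
#' For two zones with equal dispersal, the fold-reduction in s in the wider
#' zone is the squared width ratio: a threefold wider zone implies 9-fold
#' weaker selection.
#'
#' @param width_ratio w_wide / w_narrow, > 0
#' @return fold-change in s (width_ratio^2)
#' @export
selection_width_scaling <- function(width_ratio) {
  if (any(width_ratio <= 0)) stop("width ratio must be positive")
  width_ratio^2
}
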