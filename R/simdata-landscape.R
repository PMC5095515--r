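#' Generate per-window covariate tracks
#'
#' Produces smooth per-window tracks of the population recombination rate
#' proxy rho, coding (gene) density, and synonymous substitution rate dS.
#' rho and gene density are monotone transforms of stationary AR(1) Gaussian
#' fields with autocorrelation length `b_autocorr_length` windows, simulated
#' independently per scaffold; dS is a weakly autocorrelated mutation-rate
#' proxy centred on 0.08. These tracks drive the shared linked-selection
#' factor and are also emitted as covariates for the downstream
#' interaction/correlation analyses.
#'
#' @param cfg sim_config
#' @return data.frame(window, scaffold, start, end, rho, gene_density, ds)
#' @export
sim_covariates <- function(cfg) {
  wt <- sim_window_table(cfg)
  nw <- cfg$windows_per_scaffold
  one_scaffold <- function() {
    z_rho <- ar1_field(nw, cfg$b_autocorr_length)
    z_g <- ar1_field(nw, cfg$b_autocorr_length)
    z_ds <- ar1_field(nw, max(2, cfg$b_autocorr_length / 3))
    data.frame(
      rho = exp(0.6 * z_rho),                 # lognormal, mean ~ 1.2
      gene_density = stats::plogis(z_g - 1),  # in (0, 1), mean ~ 0.3
      ds = 0.08 * exp(0.25 * z_ds)            # around the genome-wide dS
    )
  }
  cov <- do.call(rbind, replicate(cfg$n_scaffolds, one_scaffold(),
                                  simplify = FALSE))
  cbind(wt[c("window", "scaffold", "start", "end")], cov)
}

#' Construct the shared linked-selection landscape B
#'
#' The per-window factor B_w in (0, 1] scales local effective population size
#' under linked (background) selection: diversity and drift-time are reduced
#' where recombination is low and the density of selective targets is high.
#' B is a deterministic, monotone function of the two covariates --
#' increasing in rho, decreasing in gene density -- built so that the effect
#' of gene density is strongest where recombination is lowest (a positive
#' rho x gene-density interaction, the hallmark of background selection).
#' Smoothness at the configured autocorrelation length is inherited from the
#' covariate fields. With u = scaled rho and v = scaled gene density, both in
#' [0, 1]:
#'
#'   B = b_min + (b_max - b_min) * (u + (1 - v * (1 - u))) / 2
#'
#' which attains its global minimum b_min exactly where rho is minimal and
#' gene density maximal, and b_max where rho is maximal.
#'
#' @param cfg sim_config
#' @param covariates data.frame with columns rho and gene_density, one row per
#'   window; defaults to `cfg$covariates`
#' @return numeric vector of B values, one per window, in (0, 1]
#' @export
build_linked_selection_landscape <- function(cfg, covariates = cfg$covariates) {
  if (is.null(covariates)) {
    stop("covariate tracks (rho, gene_density) must be defined for all windows")
  }
  n_win <- cfg$n_scaffolds * cfg$windows_per_scaffold
  if (n_win <= 0) stop("non-positive window count")
  if (nrow(covariates) != n_win) {
    stop("covariates must have one row per window (", n_win, ")")
  }
  u <- rescale01(covariates$rho)
  v <- rescale01(covariates$gene_density)
  score <- (u + (1 - v * (1 - u))) / 2
  b <- cfg$b_min + (cfg$b_max - cfg$b_min) * score
  stopifnot(all(b > 0), all(b <= 1))
  b
}
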