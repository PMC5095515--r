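#' Window index matching a simulated dataset
#'
#' Builds the window_index for the exact genome of a `crow_sim` (all
#' scaffolds fully tiled), with callable-site totals accounting for the
#' exclusion mask, and the site-to-window map aligned with
#' [sim_variant_matrix()].
#'
#' @param sim crow_sim
#' @param apply_mask must match the `sim_variant_matrix()` call
#' @return window_index; row order equals the genome-wide window order of
#'   the generator's truth tables
#' @export
sim_window_index <- function(sim, apply_mask = TRUE) {
  cfg <- sim$config
  wt <- sim_window_table(cfg)
  windows <- data.frame(
    scaffold = wt$scaffold, win = wt$win_in_scaffold - 1L,
    start = wt$start, end = wt$end, short = FALSE,
    row = wt$window,
    n_callable = rep(cfg$window_size, nrow(wt))
  )
  if (length(sim$truth$mask_windows)) {
    windows$n_callable[sim$truth$mask_windows] <- 0L
  }
  keep <- rep(TRUE, nrow(sim$sites))
  if (apply_mask && length(sim$truth$mask_windows)) {
    keep <- !(sim$sites$window %in% sim$truth$mask_windows)
  }
  structure(list(windows = windows,
                 site_window = sim$sites$window[keep],
                 window_size = cfg$window_size),
            class = "window_index")
}

#' F_ST' / Delta F_ST' landscape decomposition
#'
#' The core comparative screen: window Weir-Cockerham F_ST for the focal
#' pair and every allopatric control pair, z-standardization per comparison
#' (F_ST'), net differentiation Delta F_ST' = focal F_ST' minus the
#' per-window control maximum, 99th-percentile outlier calls for both
#' statistics, and outlier-peak merging with shared / contact_zone
#' classification.
#'
#' @param vm variant_matrix
#' @param windows window_index
#' @param focal 2-element character vector (the contact-zone pair)
#' @param controls list of 2-element character vectors (allopatric,
#'   phenotype-matched pairs)
#' @param percentile outlier percentile (default 99)
#' @param max_gap peak merging gap tolerance in windows (default 0)
#' @return list(fst_focal, fst_prime_focal, fst_prime_controls (matrix),
#'   delta, fst_flags, delta_flags, peaks, windows)
#' @export
decompose_landscape <- function(vm, windows, focal, controls,
                                percentile = 99, max_gap = 0) {
  if (!length(controls)) stop("at least one control pair is required")
  wfst <- function(pair) {
    comp <- wc_fst_per_site(vm, pair[1], pair[2])
    window_fst(comp, windows)$fst
  }
  fst_focal <- wfst(focal)
  fst_prime_focal <- zscore_fst(fst_focal)
  ctrl <- vapply(controls, wfst, numeric(nrow(windows$windows)))
  colnames(ctrl) <- vapply(controls, paste, character(1), collapse = ".")
  ctrl_prime <- apply(ctrl, 2, zscore_fst)
  delta <- delta_fst(fst_prime_focal, ctrl_prime)

  fst_flags <- call_outlier_windows(fst_prime_focal, percentile)
  delta_flags <- call_outlier_windows(delta, percentile)
  peaks <- classify_peaks(fst_flags, delta_flags, windows, max_gap = max_gap,
                          fst_prime = fst_prime_focal, delta = delta)
  list(fst_focal = fst_focal, fst_prime_focal = fst_prime_focal,
       fst_prime_controls = ctrl_prime, delta = delta,
       fst_flags = fst_flags, delta_flags = delta_flags,
       peaks = peaks, windows = windows)
}

#' Score decomposition recovery against the generator's truth
#'
#' Sensitivity: fraction of planted contact-zone windows lying inside peaks
#' classified `contact_zone`. False classification: fraction of unplanted
#' F_ST'-outlier windows that end up inside `contact_zone` peaks.
#'
#' @param decomp output of [decompose_landscape()]
#' @param truth_windows integer vector of planted window rows
#' @return list(sensitivity, false_contact_rate, n_outlier, n_planted)
#' @export
evaluate_recovery <- function(decomp, truth_windows) {
  peaks <- decomp$peaks
  cz_members <- if (nrow(peaks)) {
    unlist(peaks$members[peaks$class == "contact_zone"])
  } else integer(0)
  sens <- if (length(truth_windows)) {
    mean(truth_windows %in% cz_members)
  } else NA_real_
  outliers <- which(decomp$fst_flags)
  unplanted <- setdiff(outliers, truth_windows)
  fcr <- if (length(unplanted)) mean(unplanted %in% cz_members) else 0
  list(sensitivity = sens, false_contact_rate = fcr,
       n_outlier = length(outliers), n_planted = length(truth_windows))
}

#' Write peaks as BED plus a TSV report
#'
#' BED (0-based half-open) with the class in the name column and the peak
#' maximum F_ST' as score; the TSV carries the full table.
#' @param peaks output of [classify_peaks()]
#' @param bed_path,tsv_path output paths
#' @export
write_peaks <- function(peaks, bed_path, tsv_path) {
  lines <- if (nrow(peaks)) {
    sprintf("%s\t%d\t%d\t%s\t%.3f", peaks$scaffold,
            as.integer(peaks$start), as.integer(peaks$end), peaks$class,
            ifelse(is.na(peaks$max_fst_prime), 0, peaks$max_fst_prime))
  } else character(0)
  writeLines(lines, bed_path)
  tab <- peaks
  tab$members <- vapply(tab$members, paste, character(1), collapse = ",")
  write_tsv_plain(tab, tsv_path)
  invisible(NULL)
}
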