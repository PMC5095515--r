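#' Merge outlier windows into peaks and classify them
#'
#' Maximal runs of strictly adjacent F_ST'-outlier windows on one scaffold
#' are merged into peaks. A peak is classified `contact_zone` when at least
#' one member window is also a Delta F_ST' outlier (differentiation
#' exceeding the shared linked-selection background), and `shared`
#' otherwise. Classes are mutually exclusive and every F_ST'-outlier window
#' belongs to exactly one peak.
#'
#' @param fst_prime_flags logical vector of F_ST' outlier windows
#' @param delta_flags logical vector of Delta F_ST' outlier windows on the
#'   same index
#' @param windows window_index
#' @param max_gap number of non-outlier windows tolerated inside a peak
#'   (default 0: strict adjacency)
#' @param fst_prime,delta optional numeric tracks for amplitude summaries
#' @return data.frame, one row per peak: scaffold, start, end, n_windows,
#'   class, max_fst_prime, max_delta, member windows as a list column
#'   `members`; attribute `summary` holds per-class peak count and mean/max
#'   span in kb
#' @export
classify_peaks <- function(fst_prime_flags, delta_flags, windows,
                           max_gap = 0, fst_prime = NULL, delta = NULL) {
  wt <- windows$windows
  stopifnot(length(fst_prime_flags) == nrow(wt),
            length(delta_flags) == nrow(wt))
  peaks <- list()
  for (sc in unique(wt$scaffold)) {
    rows <- which(wt$scaffold == sc)
    flags <- fst_prime_flags[rows]
    if (max_gap > 0 && any(flags)) {
      # close gaps of up to max_gap non-outlier windows between outliers
      r <- rle(flags)
      ends <- cumsum(r$lengths)
      for (k in seq_along(r$values)) {
        if (!r$values[k] && r$lengths[k] <= max_gap &&
            k > 1 && k < length(r$values)) {
          flags[(ends[k] - r$lengths[k] + 1):ends[k]] <- TRUE
        }
      }
    }
    runs <- true_runs(flags)
    if (!nrow(runs)) next
    for (k in seq_len(nrow(runs))) {
      members <- rows[runs$start[k]:runs$end[k]]
      peaks[[length(peaks) + 1L]] <- data.frame(
        scaffold = sc,
        start = wt$start[members[1]],
        end = wt$end[members[length(members)]],
        n_windows = length(members),
        class = if (any(delta_flags[members])) "contact_zone" else "shared",
        max_fst_prime = if (!is.null(fst_prime))
          max(fst_prime[members], na.rm = TRUE) else NA_real_,
        max_delta = if (!is.null(delta)) {
          dm <- delta[members]
          if (all(is.na(dm))) NA_real_ else max(dm, na.rm = TRUE)
        } else NA_real_,
        stringsAsFactors = FALSE
      )
      peaks[[length(peaks)]]$members <- I(list(members))
    }
  }
  out <- if (length(peaks)) do.call(rbind, peaks)
         else data.frame(scaffold = character(0), start = numeric(0),
                         end = numeric(0), n_windows = integer(0),
                         class = character(0), max_fst_prime = numeric(0),
                         max_delta = numeric(0))
  if (nrow(out)) {
    span_kb <- (out$end - out$start) / 1000
    attr(out, "summary") <- do.call(rbind, lapply(
      split(span_kb, out$class), function(s)
        data.frame(n_peaks = length(s), mean_span_kb = mean(s),
                   max_span_kb = max(s))))
  }
  out
}

#' Permutation test for clustering of outlier windows
#'
#' Statistic: mean run length of consecutive flagged windows along
#' scaffolds. The null keeps the per-scaffold outlier count fixed and
#' shuffles flag positions uniformly within each scaffold (outlier windows
#' exchangeable within scaffolds), so clustered flags give a large observed
#' mean run length relative to the null;
#' p = (1 + #{null >= observed}) / (n_perm + 1).
#'
#' @param flags logical vector of outlier windows
#' @param windows window_index
#' @param n_perm number of permutations
#' @param seed optional RNG seed
#' @return list(observed, p_value, null = permuted statistics)
#' @export
clustering_test <- function(flags, windows, n_perm = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  wt <- windows$windows
  stopifnot(length(flags) == nrow(wt))
  if (!any(flags)) stop("no flagged windows")
  if (all(flags)) {
    warning("all windows flagged; clustering test is degenerate")
    return(list(observed = sum(flags), p_value = 1, null = numeric(0)))
  }
  scaffold_rows <- split(seq_len(nrow(wt)), wt$scaffold)
  mean_run <- function(f) {
    runs <- unlist(lapply(scaffold_rows, function(rows) true_runs(f[rows])$length))
    if (!length(runs)) return(0)
    mean(runs)
  }
  observed <- mean_run(flags)
  null <- vapply(seq_len(n_perm), function(i) {
    f <- flags
    for (rows in scaffold_rows) {
      f[rows] <- f[rows][sample.int(length(rows))]
    }
    mean_run(f)
  }, numeric(1))
  p <- (1 + sum(null >= observed)) / (n_perm + 1)
  list(observed = observed, p_value = p, null = null)
}
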