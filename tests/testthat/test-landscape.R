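stub_windows <- function(n, scaffold = "s1", size = 50000) {
  wt <- data.frame(scaffold = scaffold, win = seq_len(n) - 1L,
                   start = (seq_len(n) - 1) * size, end = seq_len(n) * size,
                   short = FALSE, row = seq_len(n), n_callable = size)
  structure(list(windows = wt, site_window = integer(0), window_size = size),
            class = "window_index")
}

test_that("F_ST' standardization is exact and guards degenerate input", {
  set.seed(61)
  x <- rnorm(100, 0.1, 0.05)
  z <- zscore_fst(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(stats::sd(z), 1, tolerance = 1e-12)
  expect_equal(z, (x - mean(x)) / stats::sd(x))
  expect_error(zscore_fst(rep(0.2, 50)), "variance")
  x[3] <- NA
  z2 <- zscore_fst(x)
  expect_true(is.na(z2[3]))
  expect_equal(mean(z2, na.rm = TRUE), 0, tolerance = 1e-12)
})

test_that("net differentiation subtracts the per-window control maximum", {
  expect_equal(as.numeric(delta_fst(5.0, list(1.2, 0.7))), 3.8)
  focal <- c(2, NA, 1, 0)
  ctrl <- cbind(c(1, 1, NA, 2), c(0.5, 2, NA, -1))
  d <- delta_fst(focal, list(ctrl[, 1], ctrl[, 2]))
  # loop oracle
  manual <- vapply(1:4, function(w) {
    cm <- suppressWarnings(max(ctrl[w, ], na.rm = TRUE))
    if (is.na(focal[w]) || !is.finite(cm)) NA_real_ else focal[w] - cm
  }, numeric(1))
  expect_equal(as.numeric(d), manual)
  expect_true(is.na(d[2]) && is.na(d[3]))
  # definitional identity: delta <= focal wherever the control max >= 0
  expect_true(all(d <= focal, na.rm = TRUE))
  expect_error(delta_fst(focal, list()), "control")
})

test_that("outlier windows are those strictly above the empirical percentile", {
  x <- seq_len(1000) / 1000
  fl <- call_outlier_windows(x, 99)
  expect_equal(sum(fl), 10L)
  expect_equal(which(fl), 991:1000)
  expect_warning(call_outlier_windows(rep(1, 50)), "unstable|percentile")
  fl2 <- suppressWarnings(call_outlier_windows(rep(1, 200)))
  expect_false(any(fl2))  # all equal: nothing strictly above
  # sort-based oracle on random data
  set.seed(62)
  y <- rnorm(500)
  fl3 <- call_outlier_windows(y, 99)
  expect_equal(which(fl3), which(y > stats::quantile(y, 0.99)))
})

test_that("peaks merge adjacent outlier windows and classify by delta membership", {
  wi <- stub_windows(20)
  fst_flags <- rep(FALSE, 20)
  fst_flags[4:6] <- TRUE      # one 150 kb peak
  fst_flags[10] <- TRUE       # singleton peak
  delta_flags <- rep(FALSE, 20)
  delta_flags[5] <- TRUE
  peaks <- classify_peaks(fst_flags, delta_flags, wi)
  expect_equal(nrow(peaks), 2L)
  expect_equal(peaks$end[1] - peaks$start[1], 150000)
  expect_equal(peaks$class, c("contact_zone", "shared"))
  expect_equal(peaks$n_windows, c(3L, 1L))
  # every outlier window in exactly one peak
  members <- unlist(peaks$members)
  expect_setequal(members, which(fst_flags))
  expect_equal(anyDuplicated(members), 0L)
  # peaks never span scaffolds
  wi2 <- stub_windows(20, scaffold = rep(c("s1", "s2"), each = 10))
  fl <- rep(FALSE, 20); fl[9:12] <- TRUE
  p2 <- classify_peaks(fl, rep(FALSE, 20), wi2)
  expect_equal(nrow(p2), 2L)
  # gap tolerance merges across a single non-outlier window
  fl3 <- rep(FALSE, 20); fl3[c(4, 6)] <- TRUE
  expect_equal(nrow(classify_peaks(fl3, rep(FALSE, 20), wi, max_gap = 1)), 1L)
})

test_that("clustering test separates clustered from scattered flags", {
  wi <- stub_windows(1000)
  flags <- rep(FALSE, 1000)
  flags[101:110] <- TRUE
  res <- clustering_test(flags, wi, n_perm = 1000, seed = 63)
  expect_equal(res$observed, 10)
  expect_lte(res$p_value, 0.01)
  # single flagged window: observed statistic 1
  f1 <- rep(FALSE, 1000); f1[5] <- TRUE
  expect_equal(clustering_test(f1, wi, n_perm = 10, seed = 1)$observed, 1)
  expect_error(clustering_test(rep(FALSE, 10), stub_windows(10)), "no flagged")
})

test_that("Moran's I matches its closed-form anchors and null mean", {
  wi <- stub_windows(100)
  alternating <- rep(c(1, -1), 50)
  expect_equal(morans_i(alternating, wi)$genome, -1, tolerance = 1e-12)
  ramp <- seq_len(100)
  expect_gte(morans_i(ramp, wi)$genome, 0.9)
  # permutation null: E[I] = -1/(n-1)
  set.seed(64)
  x <- rnorm(100)
  perm_i <- replicate(200, morans_i(sample(x), wi)$genome)
  expect_lt(abs(mean(perm_i) - (-1 / 99)),
            3 * stats::sd(perm_i) / sqrt(200))
  # constant track undefined
  expect_true(is.na(morans_i(rep(1, 100), wi)$genome))
})

test_that("Moran's I of F_ST landscapes grows with divergence time", {
  # deeper divergence exposes the autocorrelated linked-selection landscape
  # over iid sampling noise
  i_at <- vapply(c(0.25, 1, 4), function(scale) {
    cfg <- star_config(seed = 77, tip = 0.02 * scale)
    sim <- simulate_dataset(cfg, haplotypes = "none")
    vm <- sim_variant_matrix(sim)
    wi <- sim_window_index(sim)
    fst <- window_fst(wc_fst_per_site(vm, "a1", "a2"), wi)$fst
    morans_i(fst, wi)$genome
  }, numeric(1))
  expect_true(all(diff(i_at) > 0))
})

test_that("Moran's I agrees with an independent implementation", {
  skip_if_not_installed("ape")
  wi <- stub_windows(80)
  set.seed(65)
  x <- cumsum(rnorm(80))
  w <- matrix(0, 80, 80)
  for (i in 1:79) { w[i, i + 1] <- 1; w[i + 1, i] <- 1 }
  w <- w / rowSums(w)
  ref <- ape::Moran.I(x, w, scaled = FALSE)
  expect_equal(morans_i(x, wi)$genome, ref$observed, tolerance = 1e-10)
})

test_that("correlation panels compute r by panel and exclude shared-population pairs", {
  set.seed(66)
  n <- 200
  pi_m <- cbind(A = rnorm(n), B = rnorm(n), C = rnorm(n))
  fst_m <- cbind("A.B" = rnorm(n), "A.C" = rnorm(n), "B.C" = rnorm(n))
  pan <- correlation_panels(list(pi = pi_m), list(fst = fst_m))
  # panel a: a track against itself would give r = 1; check via duplicate
  pan_self <- correlation_panels(list(pi = cbind(A = pi_m[, 1],
                                                 B = pi_m[, 1])), list())
  expect_equal(pan_self$r[pan_self$panel == "a"], 1)
  # panel d: all pairs of comparisons share a population here -> excluded
  expect_equal(sum(pan$panel == "d"), 0L)
  fst_m2 <- cbind(fst_m, "D.E" = rnorm(n))
  pan2 <- correlation_panels(list(pi = pi_m), list(fst = fst_m2))
  expect_setequal(paste(pan2$unit1[pan2$panel == "d"],
                        pan2$unit2[pan2$panel == "d"]),
                  c("A.B D.E", "A.C D.E", "B.C D.E"))
  # partial correlation with an independent covariate barely changes r
  z <- rnorm(n)
  x <- rnorm(n); y <- 0.5 * x + rnorm(n)
  pan3 <- correlation_panels(list(pi = cbind(P = x, Q = y)), list(),
                             partial_on = z)
  row <- pan3[pan3$panel == "a", ]
  expect_lt(abs(row$r - row$r_partial), 0.02)
})

test_that("interaction model recovers a planted rho x gene-density effect", {
  set.seed(67)
  hits <- 0
  for (i in 1:20) {
    rho <- rnorm(500); g <- rnorm(500)
    pi_t <- 1 + 0.5 * rho * g + rnorm(500, sd = 0.5)
    fit <- interaction_model(pi_t, rho, g)
    if (fit$interaction > 0 && fit$interaction_p < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 18)  # >= 90% power at this effect size
  # null calibration: uniform p-values
  set.seed(68)
  pvals <- replicate(100, {
    interaction_model(rnorm(200), rnorm(200), rnorm(200))$interaction_p
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
  # constant gene density flags collinearity
  fit <- interaction_model(rnorm(100), rnorm(100), rep(1, 100))
  expect_true(fit$collinear)
})

test_that("isolation by distance: transformation, perfect fit, and null", {
  # F_ST = 0.2 -> genetic distance 0.25
  fst <- matrix(0.2, 2, 2); diag(fst) <- 0
  dimnames(fst) <- list(c("p1", "p2"), c("p1", "p2"))
  expect_equal((fst / (1 - fst))[1, 2], 0.25)

  # genetic distance exactly proportional to geographic -> r = 1
  coords <- data.frame(population = paste0("p", 1:6),
                       lat = c(40, 45, 50, 55, 60, 65), lon = rep(10, 6))
  geo <- geosphere::distHaversine(cbind(10, coords$lat[1]),
                                  cbind(10, coords$lat), r = 6371)
  gd <- outer(geo, geo, function(a, b) abs(a - b)) / 20000
  fstm <- gd / (1 + gd)  # inverts to gen dist = gd
  dimnames(fstm) <- list(coords$population, coords$population)
  res <- ibd_mantel(fstm, coords, n_perm = 99, seed = 69)
  expect_equal(res$r, 1, tolerance = 1e-10)
  expect_lt(res$p_value, 0.05)
  expect_equal(unname(res$gen_dist[1, 2]), gd[1, 2], tolerance = 1e-12)
  # residuals come from the least-squares line
  fit <- stats::lm(res$residuals$gen_dist ~ res$residuals$geo_dist_km)
  expect_equal(res$residuals$residual, unname(stats::resid(fit)),
               tolerance = 1e-10)
})

test_that("tension-zone scaling is the squared width ratio", {
  expect_identical(selection_width_scaling(3), 9)
  expect_identical(selection_width_scaling(1), 1)
  expect_identical(selection_width_scaling(7), 49)
  expect_error(selection_width_scaling(0), "positive")
})
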