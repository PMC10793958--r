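test_that("CCH bins lags under the (low, high] convention", {
  cch <- compute_cch(c(0), c(0.002), 0.0005, 0.03)
  expect_equal(sum(cch$counts), 1)
  hit <- which(cch$counts == 1)
  # the bin containing 2.0 ms is (1.5, 2.0]
  expect_equal(cch$lags[hit] + cch$bin_width_s / 2, 0.002)
  expect_equal(cch$n_bins, 120)
  # conditional-rate scaling: count / (n_ref * bin width)
  expect_equal(cch$rate[hit], 1 / 0.0005)
  expect_error(compute_cch(numeric(0), c(1)), "empty reference")
})

test_that("CCH matches the brute-force pair count oracle and conserves pairs", {
  set.seed(5)
  a <- poisson_times(8, 30)
  b <- poisson_times(12, 30)
  cch <- compute_cch(a, b, 0.001, 0.02)
  expect_equal(cch$counts, brute_cch_counts(a, b, 0.001, 0.02))
  # mirror symmetry: cch(a,b)[tau] vs cch(b,a)[-tau]
  rev_cch <- compute_cch(b, a, 0.001, 0.02)
  expect_equal(cch$counts, rev(rev_cch$counts))
})

test_that("ACH excludes self-pairs and matches the oracle", {
  set.seed(6)
  a <- sort(poisson_times(10, 20))
  tr <- spike_train("u", a)
  ach <- compute_cch(tr, tr, 0.001, 0.02)
  expect_equal(ach$kind, "ach")
  expect_equal(ach$counts,
               brute_cch_counts(a, a, 0.001, 0.02, exclude_self = TRUE))
  # symmetric about zero
  expect_equal(ach$counts, rev(ach$counts))
})

test_that("independent Poisson trains give the product-rate CCH level", {
  set.seed(7)
  a <- poisson_times(5, 3600)
  b <- poisson_times(10, 3600)
  cch <- compute_cch(a, b, 0.0005, 0.03)
  # expected count per 0.5-ms bin = r1 * r2 * T * bin = 90
  expect_equal(mean(cch$counts), 90, tolerance = 0.05)
})

test_that("PSTH is flat for independent spiking and localizes locked spiking", {
  set.seed(8)
  onsets <- seq(10, 580, by = 0.5)
  tr <- poisson_times(20, 600)
  ps <- psth(tr, onsets)
  expect_equal(mean(ps$rate), 20, tolerance = 0.05)
  # every event preceded by a spike exactly 3 ms earlier
  ev <- seq(1, 100, by = 0.5)
  locked <- psth(ev - 0.003, ev)
  expect_equal(sum(locked$counts), length(ev))
  hit <- which(locked$counts > 0)
  # all mass in the bin(s) containing -3 ms
  expect_true(all(abs(locked$lags[hit] + 0.003) <= 0.00051))
})

test_that("hollowed median matches its definition and the brute-force oracle", {
  # constant histogram -> constant baseline
  expect_equal(hollowed_median_baseline(rep(4, 50), 0.005, 0.001), rep(4, 50))
  # single peak on zero background is hollowed out
  x <- numeric(21); x[11] <- 100
  expect_equal(hollowed_median_baseline(x, 0.005, 0.001), numeric(21))
  # documented example: window of +/-2 bins around the middle of 1..5
  expect_equal(hollowed_median_baseline(c(1, 2, 3, 4, 5), 0.002, 0.001)[3], 3)
  set.seed(9)
  for (h in c(3L, 10L)) {
    x <- rpois(80, 20)
    expect_equal(hollowed_median_baseline(x, h * 0.001, 0.001),
                 brute_hollowed_median(x, h))
  }
  expect_error(hollowed_median_baseline(1:10, 0, 0.001), "3 bins")
})

test_that("poisson_excess_test matches closed forms and direct summation", {
  expect_equal(as.numeric(poisson_excess_test(0, 1)), 1 - 0.5 * exp(-1),
               tolerance = 1e-12)
  # direct tail summation oracle, continuity corrected
  direct <- function(n, lam) sum(dpois(n:(n + 400), lam)) - 0.5 * dpois(n, lam)
  for (lam in c(0.5, 1, 7, 50)) {
    for (n in c(0, 1, 5, 60)) {
      expect_equal(as.numeric(poisson_excess_test(n, lam)),
                   min(max(direct(n, lam), 1e-300), 1 - 1e-16),
                   tolerance = 1e-12)
    }
  }
  expect_equal(as.numeric(poisson_excess_test(5, 1)), 0.00213,
               tolerance = 2e-3)
  # strictly decreasing in the observed count at fixed expectation
  p <- as.numeric(poisson_excess_test(0:20, 3))
  expect_true(all(diff(p) < 0))
  expect_warning(poisson_excess_test(3, 0), "zero expected")
})

test_that("deconvolution is the identity for a flat reference ACH", {
  # constructed exactly flat ACH: the curve must equal the scaled
  # baseline-subtracted CCH up to the Tikhonov ridge
  set.seed(10)
  pre <- poisson_times(5, 1200)
  tr <- spike_train("p", pre)
  ach <- compute_cch(tr, tr, 0.0005, 0.03)
  ach$counts <- rep(30, ach$n_bins)
  cch <- ach
  cch$kind <- "cch"
  cch$counts <- rpois(cch$n_bins, 40)
  cch$counts[62:67] <- cch$counts[62:67] + 25
  curve <- deconvolve_transmission(cch, ach, 0.010)
  flat <- (cch$counts - hollowed_median_baseline(cch, 0.010)) /
    (cch$n_ref * cch$bin_width_s)
  rel <- sqrt(mean((curve$rate - flat)^2)) / sqrt(mean(flat^2))
  expect_lt(rel, 0.01)
})

test_that("deconvolution recovers a kernel forward-convolved with a bursty ACH", {
  set.seed(11)
  pre <- poisson_times(5, 1200)
  tr <- spike_train("p", pre)
  ach <- compute_cch(tr, tr, 0.0005, 0.03)
  nb <- ach$n_bins
  zb <- spiketrans:::.zero_bin(ach)
  # doublet-firing reference: strong ACH satellites near +/-3 ms
  ach$counts <- rep(40, nb)
  ach$counts[zb + c(-6, 7)] <- 3000
  kern <- spiketrans:::.ach_kernel(ach, 0.010)
  kv <- numeric(2 * nb - 1)
  kv[kern$d_offsets + nb] <- kern$kernel_norm
  K <- matrix(kv[outer(seq_len(nb), seq_len(nb), `-`) + nb], nb, nb)
  true_curve <- numeric(nb)
  true_curve[(zb + 2):(zb + 7)] <- c(1, 3, 5, 5, 3, 1) / 18 * 0.05
  cch <- ach
  cch$kind <- "cch"
  cch$counts <- as.numeric(ach$n_ref * K %*% true_curve) + 500
  rec <- deconvolve_transmission(cch, ach, 0.010)
  rel <- sqrt(mean((rec$excess_per_spike - true_curve)^2)) /
    sqrt(mean(true_curve^2))
  expect_lt(rel, 0.05)
  # the forward CCH has a satellite peak; the recovered curve must not
  sat <- zb + 7 + 6
  expect_gt(cch$counts[sat] - 500, 10)
  expect_lt(rec$excess_per_spike[sat], 0.2 * max(rec$excess_per_spike))
})

test_that("zero-coupling pairs give a transmission curve centred on zero", {
  set.seed(12)
  pre <- spike_train("p", poisson_times(4, 900), "PYR")
  post <- spike_train("q", poisson_times(12, 900), "PV")
  cch <- compute_cch(pre, post)
  ach <- compute_cch(pre, pre)
  curve <- deconvolve_transmission(cch, ach, 0.010)
  roi <- spiketrans:::.roi_bins(cch, 0.005)
  # |mean| of ROI curve within 3 SE of zero
  se <- sd(curve$excess_per_spike) / sqrt(length(roi))
  expect_lt(abs(mean(curve$excess_per_spike[roi])), 3 * se)
})

test_that("correlograms serialize to a lag/count/rate table", {
  cch <- compute_cch(c(0, 1), c(0.002, 1.001), 0.0005, 0.01)
  df <- as.data.frame(cch)
  expect_named(df, c("lag_center_s", "count", "rate_spk_s"))
  expect_equal(nrow(df), cch$n_bins)
  expect_equal(sum(df$count), 2)
})
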