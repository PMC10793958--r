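test_that("zscore_vector standardizes, is idempotent and flags constants", {
  z <- zscore_vector(c(1, 2, 3))
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
  expect_equal(zscore_vector(z), z)
  set.seed(91)
  v <- rnorm(40, 5, 3)
  expect_equal(zscore_vector(v), as.numeric(scale(v)))
  expect_warning(out <- zscore_vector(rep(2, 5)), "constant")
  expect_true(all(is.na(out)))
})

test_that("shuffle_bins permutes reproducibly and preserves the multiset", {
  v <- c(5, 1, 4, 2, 2)
  s1 <- shuffle_bins(v, seed = 92)
  expect_equal(sort(s1), sort(v))
  expect_identical(shuffle_bins(v, seed = 92), s1)
  expect_identical(shuffle_bins(7), 7)
})

test_that("SVR learns a learnable target and not an independent one", {
  set.seed(93)
  x <- matrix(rnorm(60 * 3), 60, 3)
  r2 <- crossval_svr(x, x[, 1], repeats = 5, seed = 94)
  expect_gt(mean(r2), 0.8)
  r2_null <- crossval_svr(x, rnorm(60), repeats = 5, seed = 95)
  expect_lt(mean(r2_null), 0.2)
  expect_error(crossval_svr(x, rep(1, 60), repeats = 2), "degenerate")
})

test_that("linear SVM classifies a separable signal and calibrates on shuffles", {
  set.seed(96)
  x <- matrix(rnorm(80 * 4), 80, 4)
  y <- factor(ifelse(x[, 2] > 0, "up", "down"))
  auc <- crossval_svm_auc(x, y, repeats = 5, seed = 97)
  expect_gt(mean(auc), 0.9)
  auc_null <- crossval_svm_auc(x, sample(y), repeats = 10, seed = 98)
  expect_true(all(auc_null > 0.25 & auc_null < 0.75))
  expect_error(crossval_svm_auc(x, factor(rep("a", 80)), repeats = 2),
               "two classes")
})

test_that("the AUC helper agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(99)
  sc <- rnorm(60)
  lab <- rbinom(60, 1, 0.5) == 1
  ours <- spiketrans:::.auc(sc, lab)
  ref <- as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("entire-assembly folds never split an assembly", {
  set.seed(100)
  asm <- rep(sprintf("A%02d", 1:12), each = 4)
  for (i in 1:5) {
    fold <- spiketrans:::.assembly_folds(asm, 5)
    expect_true(all(vapply(split(fold, asm),
                           function(f) length(unique(f)) == 1L, logical(1))))
  }
  # scheme runs end to end with assembly-coherent labels
  f <- simulate_assembly_features(24, "latency", seed = 101)
  x <- rbind(slice_lags(f$features), slice_lags(f$features))
  y <- factor(c(as.character(f$labels), as.character(f$labels)))
  aucs <- crossval_svm_auc(x, y, repeats = 3, seed = 102,
                           scheme = "entire_assembly",
                           assembly_ids = rep(sprintf("A%02d", 1:24), 2))
  expect_true(all(is.finite(aucs)))
})

test_that("subsampling scheme yields one prediction stream per pair", {
  f <- simulate_assembly_features(30, "latency", seed = 103)
  x <- slice_lags(f$features)
  asm <- rep(sprintf("A%02d", 1:15), each = 2)   # two pairs per assembly
  aucs <- crossval_svm_auc(x, f$labels, repeats = 5, seed = 104,
                           scheme = "subsample_one_per_assembly",
                           assembly_ids = asm)
  expect_length(aucs, 5)
  expect_true(all(aucs > 0.5))
})

test_that("window_scan slices centred and offset windows correctly", {
  f <- simulate_assembly_features(60, "latency", seed = 105)
  res <- window_scan(f$features, f$lags_s, f$labels,
                     half_widths_s = c(0, 0.010), offsets_s = c(0, 0.030),
                     repeats = 3, seed = 106)
  expect_equal(res$n_bins[res$setting == "half_width"], c(1L, 21L))
  expect_equal(res$n_bins[res$setting == "offset"], c(21L, 21L))
  # the window covering the injected +/-3 ms signature beats a remote offset
  expect_gt(res$mean_auc[res$setting == "half_width" & res$value_s == 0.010],
            res$mean_auc[res$setting == "offset" & res$value_s == 0.030])
  expect_error(window_scan(f$features, f$lags_s, f$labels,
                           offsets_s = 0.2), "outside")
})

test_that("virtual closed loop realizes the drawn CLE on a control session", {
  cfg <- sim_config(n_assemblies = 2, presyn_per_assembly = 2,
                    presyn_rate_range = c(1, 2), detection_prob = 0,
                    epoch_durations_s = c(Before = 60, Experience = 900,
                                          After = 60))
  g <- generate_session(cfg, seed = 107)
  expect_length(g$session$events$onsets, 0)
  asm <- build_assemblies(data.frame(
    pre_id = g$ground_truth$pairs$pre_id,
    post_id = g$ground_truth$pairs$post_id))
  # fixed CLE = 1 with sparse spiking: one event per spike (minus blanking)
  ev <- virtual_closed_loop(g$session, asm, cle_distribution = function(n) 1,
                            seed = 108)
  ex <- epoch_bounds(g$session$epochs, "Experience")
  for (u in attr(ev, "trigger_ids")) {
    n_sp <- length(restrict(g$session$trains[[u]]$times, ex))
    realized <- sum(ev$trigger_unit == u) / n_sp
    expect_gt(realized, 0.85)
  }
  # realized CLE tracks a drawn intermediate value
  ev2 <- virtual_closed_loop(g$session, asm,
                             cle_distribution = function(n) 0.3, seed = 109)
  u <- attr(ev2, "trigger_ids")[1]
  n_sp <- length(restrict(g$session$trains[[u]]$times, ex))
  expect_equal(sum(ev2$trigger_unit == u) / n_sp, 0.3, tolerance = 0.15)
  # reproducible and refused on stimulated sessions
  expect_identical(virtual_closed_loop(g$session, asm,
                                       cle_distribution = function(n) 0.3,
                                       seed = 109)$onsets, ev2$onsets)
  g2 <- generate_session(sim_config(
    n_assemblies = 1, presyn_per_assembly = 1, detection_prob = 1,
    epoch_durations_s = c(Before = 60, Experience = 120, After = 60)),
    seed = 110)
  expect_error(virtual_closed_loop(g2$session, asm), "without real events")
})

test_that("the CLE sampler matches the target quantiles", {
  set.seed(111)
  draws <- rlnorm_cle(2e5)
  expect_equal(median(draws), 0.054, tolerance = 0.05)
  expect_equal(unname(quantile(draws, 0.25)), 0.013, tolerance = 0.1)
  expect_true(all(draws <= 1))
})
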