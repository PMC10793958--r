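test_that("presynaptic trains honor rate and refractoriness", {
  cfg <- sim_config(n_assemblies = 1L, presyn_per_assembly = 2L,
                    presyn_rate_range = c(2, 2),
                    epoch_durations_s = c(Before = 1800, Experience = 900,
                                          After = 900))
  trains <- simulate_presyn_trains(cfg, seed = 41)
  for (tr in trains) {
    # Poisson expectation lambda * T = 7200, within sampling error
    expect_equal(length(tr$times), 2 * 3600, tolerance = 0.05)
    expect_true(all(diff(tr$times) >= 0.002))
  }
  # different seeds give different trains with the same statistics
  trains2 <- simulate_presyn_trains(cfg, seed = 42)
  expect_false(identical(trains[[1]]$times, trains2[[1]]$times))
  expect_equal(length(trains2[[1]]$times), length(trains[[1]]$times),
               tolerance = 0.1)
  expect_error(spiketrans:::.sim_refractory_poisson(600, 10, 0.002),
               "unrealizable")
})

test_that("closed loop emits one delayed event per detected spike with blanking", {
  cfg <- sim_config(detection_prob = 1)
  # spikes >= 53 ms apart: no collisions, event at spike + 3 ms
  tr <- list(a = spike_train("a", seq(1, 5, by = 0.06), "PYR"))
  ev <- run_closed_loop(tr, "a", cfg, seed = 43)
  expect_equal(ev$onsets, tr$a$times + 0.003)
  expect_equal(unique(ev$trigger_unit), "a")
  # two trigger spikes 10 ms apart: the second is blanked
  tr2 <- list(a = spike_train("a", c(1, 1.010), "PYR"))
  ev2 <- run_closed_loop(tr2, "a", cfg, seed = 43)
  expect_equal(ev2$onsets, 1.003)
  # detection probability thins events binomially
  cfg5 <- sim_config(detection_prob = 0.5)
  tr3 <- list(a = spike_train("a", seq(1, by = 0.06, length.out = 1000), "PYR"))
  ev3 <- run_closed_loop(tr3, "a", cfg5, seed = 44)
  expect_equal(length(ev3$onsets), 500, tolerance = 0.1)
})

test_that("postsynaptic trains decouple when p = 0 and g = 1", {
  cfg <- sim_config(light_gain = 1,
                    epoch_durations_s = c(Before = 300, Experience = 60,
                                          After = 300))
  ep <- make_epochs(300, 60, 300)
  set.seed(45)
  pre <- spike_train("p", poisson_times(4, 660), "PYR")
  post <- simulate_postsyn_train(list(pre), list(p_before = 0, p_after = 0),
                                 stim_events(numeric(0)), cfg, 10, ep,
                                 seed = 46)
  expect_equal(length(post$times), 10 * 660, tolerance = 0.1)
  # no causal excess: compare counts just after presyn spikes with a
  # shifted-train control
  n_near <- sum(vapply(pre$times, function(t) {
    sum(post$times > t & post$times <= t + 0.005)
  }, numeric(1)))
  n_ctrl <- sum(vapply(pre$times + 0.5, function(t) {
    sum(post$times > t & post$times <= t + 0.005)
  }, numeric(1)))
  expect_lt(abs(n_near - n_ctrl), 4 * sqrt(n_ctrl + 1))
})

test_that("postsynaptic excess spiking matches the injected probability", {
  cfg <- sim_config(epoch_durations_s = c(Before = 1800, Experience = 60,
                                          After = 60))
  ep <- make_epochs(1800, 60, 60)
  set.seed(47)
  pre <- spike_train("p", poisson_times(3, 1920), "PYR")
  post <- simulate_postsyn_train(list(pre),
                                 list(p_before = 0.1, p_after = 0.1),
                                 stim_events(numeric(0)), cfg, 8, ep,
                                 seed = 48)
  n_near <- sum(vapply(pre$times, function(t) {
    sum(post$times > t & post$times <= t + 0.005)
  }, numeric(1)))
  n_ctrl <- sum(vapply(pre$times + 0.5, function(t) {
    sum(post$times > t & post$times <= t + 0.005)
  }, numeric(1)))
  expect_equal((n_near - n_ctrl) / length(pre$times), 0.1, tolerance = 0.12)
})

test_that("light gain multiplies the postsynaptic rate inside stimuli", {
  cfg <- sim_config(light_gain = 2,
                    epoch_durations_s = c(Before = 60, Experience = 1200,
                                          After = 60))
  ep <- make_epochs(60, 1200, 60)
  onsets <- seq(61, 1250, by = 0.5)
  ev <- stim_events(onsets)
  post <- simulate_postsyn_train(list(), list(p_before = numeric(0),
                                              p_after = numeric(0)),
                                 ev, cfg, 10, ep, seed = 49)
  stim_int <- cbind(onsets, onsets + 0.03)
  r_in <- length(restrict(post$times, stim_int)) / (nrow(stim_int) * 0.03)
  btw <- interval_complement(stim_int, c(61, 1250))
  r_out <- length(restrict(post$times, btw)) / interval_total(btw)
  expect_equal(r_in / r_out, 2, tolerance = 0.1)
})

test_that("generated sessions carry coherent ground truth and reproduce exactly", {
  cfg <- sim_config(n_assemblies = 2, presyn_per_assembly = 2,
                    plasticity_factors = c(1, 0.5),
                    epoch_durations_s = c(Before = 120, Experience = 120,
                                          After = 120))
  g <- generate_session(cfg, seed = 50)
  gt <- g$ground_truth$pairs
  expect_equal(gt$true_stg_change[gt$assembly == 1], c(0, 0))
  expect_equal(gt$true_stg_change[gt$assembly == 2], c(-1, -1))
  # events confined to the Experience epoch
  ex <- epoch_bounds(g$session$epochs, "Experience")
  expect_true(all(g$session$events$onsets >= ex[1]))
  expect_true(all(g$session$events$onsets + 0.03 <= ex[2]))
  # one trigger per assembly, with a realized CLE
  expect_equal(sum(g$ground_truth$units$is_trigger), 2)
  expect_true(all(is.finite(
    g$ground_truth$units$realized_cle[g$ground_truth$units$is_trigger])))
  # byte-identical reproduction through serialized files
  g2 <- generate_session(cfg, seed = 50)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_session(g$session, d1)
  write_session(g2$session, d2)
  for (f in c("spikes.tsv", "events.tsv", "epochs.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("assembly feature cohorts separate rate from timing information", {
  fg <- simulate_assembly_features(60, "gain_only", seed = 51)
  fl <- simulate_assembly_features(60, "latency", seed = 52)
  expect_equal(dim(fg$features), c(60, 101))
  expect_equal(table(fg$labels)[["increase"]], 30)
  # gain-only: class difference lives in the vector mean
  m_up <- rowMeans(fg$features)[fg$labels == "increase"]
  m_dn <- rowMeans(fg$features)[fg$labels == "decrease"]
  expect_gt(mean(m_up), mean(m_dn) + 1)
  # latency: no class difference in the mean, but localized structure
  m_up2 <- rowMeans(fl$features)[fl$labels == "increase"]
  m_dn2 <- rowMeans(fl$features)[fl$labels == "decrease"]
  expect_lt(abs(mean(m_up2) - mean(m_dn2)), 0.2)
  lag <- as.numeric(sub("lag_", "", colnames(fl$features)))
  bump_up <- colMeans(fl$features[fl$labels == "increase", lag == 3, drop = FALSE])
  expect_gt(bump_up, 1)
})
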