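make_pairs_df <- function() {
  data.frame(pre_id = sprintf("P%02d", 1:5),
             post_id = c("V1", "V1", "V1", "V2", "V2"),
             stringsAsFactors = FALSE)
}

test_that("assemblies partition eligible pairs by postsynaptic unit", {
  df <- make_pairs_df()
  asm <- build_assemblies(df)
  expect_length(asm, 2)
  expect_equal(lengths(lapply(asm, `[[`, "pair_ids")), c(V1 = 3L, V2 = 2L))
  # the union of members equals the pair set (partition)
  expect_setequal(unlist(lapply(asm, `[[`, "pair_ids")),
                  paste(df$pre_id, df$post_id, sep = ":"))
  # eligibility filter applies when present
  df$eligible <- c(TRUE, TRUE, FALSE, TRUE, TRUE)
  expect_equal(lengths(lapply(build_assemblies(df), `[[`, "pair_ids")),
               c(V1 = 2L, V2 = 2L))
  # singleton assemblies are allowed
  one <- build_assemblies(data.frame(pre_id = "a", post_id = "z"))
  expect_length(one[["z"]]$pair_ids, 1)
})

test_that("peer and non-peer means follow their definitions and the oracle", {
  asm <- build_assemblies(make_pairs_df())
  v <- c("P01:V1" = 1, "P02:V1" = 2, "P03:V1" = 3, "P04:V2" = 10,
         "P05:V2" = 20)
  pn <- peer_nonpeer_means("P01:V1", asm, v)
  expect_equal(pn[["mean_peer"]], 2.5)
  expect_equal(pn[["mean_nonpeer"]], 15)
  # no other assemblies -> non-peer mean undefined
  asm1 <- build_assemblies(data.frame(pre_id = c("a", "b"), post_id = "z"))
  v1 <- c("a:z" = 1, "b:z" = 5)
  pn1 <- peer_nonpeer_means("a:z", asm1, v1)
  expect_equal(pn1[["mean_peer"]], 5)
  expect_true(is.na(pn1[["mean_nonpeer"]]))
  expect_error(peer_nonpeer_means("missing:pair", asm, v), "not found")
  # brute-force oracle on random partitions
  set.seed(81)
  for (rep in 1:5) {
    post <- sample(sprintf("V%d", 1:3), 12, replace = TRUE)
    df <- data.frame(pre_id = sprintf("P%02d", 1:12), post_id = post)
    a2 <- build_assemblies(df)
    pid <- paste(df$pre_id, df$post_id, sep = ":")
    vals <- stats::setNames(rnorm(12), pid)
    i <- sample(12, 1)
    pn2 <- peer_nonpeer_means(pid[i], a2, vals)
    same <- post == post[i]
    peer_oracle <- mean(vals[same & pid != pid[i]])
    non_oracle <- mean(vals[!same])
    if (sum(same) > 1) expect_equal(pn2[["mean_peer"]], peer_oracle)
    if (any(!same)) expect_equal(pn2[["mean_nonpeer"]], non_oracle)
  }
})

test_that("CCH difference vanishes without a light effect and shows a pure gain offset", {
  # stimuli much longer than the CCH window, so a pure rate gain appears as
  # a flat offset of about (g - 1) x baseline rate
  ep <- epoch_set(c("Before", "Experience", "After"),
                  c(0, 60, 2060), c(60, 2060, 2120))
  ex <- epoch_bounds(ep, "Experience")
  ev <- stim_events(seq(61, 2050, by = 2), duration_s = 0.5)
  run_case <- function(gain, seed) {
    cfg <- sim_config(light_gain = gain, stim_duration_s = 0.5,
                      epoch_durations_s = c(Before = 60, Experience = 2000,
                                            After = 60))
    set.seed(seed)
    pre <- spike_train("p", sort(runif(3 * 2120, 0, 2120)), "PYR")
    post <- simulate_postsyn_train(list(),
                                   list(p_before = numeric(0),
                                        p_after = numeric(0)),
                                   ev, cfg, 15, ep, seed = seed + 1)
    cch_difference(pre, post, ev, ex)
  }
  null_case <- run_case(1, 82)
  expect_false(null_case$missing)
  expect_length(null_case$difference, 101)   # centered 1-ms grid
  expect_lt(abs(mean(null_case$difference)), 1)
  gain_case <- run_case(2, 83)
  mid <- abs(gain_case$lags) <= 0.020
  expect_equal(mean(gain_case$difference[mid]), 15, tolerance = 0.15)
})

test_that("assembly CCH-difference aggregation is additive and order-invariant", {
  lags <- (-5):5 / 1000
  mk <- function(id, v) {
    structure(list(pair_id = id, lags = lags, stim_rate = v,
                   between_rate = 0 * v, difference = v, missing = FALSE),
              class = "cch_difference")
  }
  set.seed(84)
  diffs <- list("a:z" = mk("a:z", rnorm(11)), "b:z" = mk("b:z", rnorm(11)),
                "c:z" = mk("c:z", rnorm(11)))
  asm <- build_assemblies(data.frame(pre_id = c("a", "b", "c"), post_id = "z"))
  whole <- aggregate_cch_difference(asm$z, diffs, "whole_assembly")
  # brute-force summation oracle
  expect_equal(whole, diffs[["a:z"]]$difference + diffs[["b:z"]]$difference +
                 diffs[["c:z"]]$difference)
  peers <- aggregate_cch_difference(asm$z, diffs, "peers_of", pair_id = "a:z")
  expect_equal(peers + diffs[["a:z"]]$difference, whole)
  # member order does not matter
  expect_equal(aggregate_cch_difference(asm$z, rev(diffs), "whole_assembly"),
               whole)
  # single-pair assembly: whole-assembly sum is that pair's difference
  asm1 <- build_assemblies(data.frame(pre_id = "a", post_id = "z"))
  expect_equal(aggregate_cch_difference(asm1$z, diffs, "whole_assembly"),
               diffs[["a:z"]]$difference)
  expect_error(aggregate_cch_difference(asm1$z, diffs, "peers_of",
                                        pair_id = "a:z"), "no usable")
})

test_that("sham assemblies preserve the size multiset and reproduce by seed", {
  ids <- sprintf("p%02d:v", 1:10)
  sh <- sham_assemblies(ids, c(4, 3, 3), seed = 85)
  expect_equal(unname(sort(lengths(lapply(sh, `[[`, "pair_ids")))), c(3, 3, 4))
  expect_setequal(unlist(lapply(sh, `[[`, "pair_ids")), ids)
  expect_identical(sham_assemblies(ids, c(4, 3, 3), seed = 85), sh)
  expect_error(sham_assemblies(ids, c(5, 3)), "sum")
})

test_that("sham reallocation shrinks assembly-mean spread under coherent values", {
  set.seed(86)
  # coherent per-assembly values: shared level + small pair noise
  sizes <- rep(4, 6)
  levels_ <- rnorm(6, sd = 1)
  vals <- stats::setNames(rep(levels_, times = sizes) + rnorm(24, sd = 0.2),
                          sprintf("p%02d:v%d", 1:24, rep(1:6, times = sizes)))
  true_asm <- build_assemblies(data.frame(
    pre_id = sprintf("p%02d", 1:24), post_id = sprintf("v%d", rep(1:6, times = sizes))))
  true_sd <- sd(vapply(true_asm, function(a) mean(vals[a$pair_ids]),
                       numeric(1)))
  sham_sd <- mean(replicate(50, {
    sh <- sham_assemblies(names(vals), sizes)
    sd(vapply(sh, function(a) mean(vals[a$pair_ids]), numeric(1)))
  }))
  expect_gt(true_sd, sham_sd)
})

test_that("spearman_permutation matches the rank-correlation oracle", {
  set.seed(87)
  x <- rnorm(30)
  # monotone relation: cc = 1 and the minimal attainable p
  r <- spearman_permutation(x, exp(x), n_perm = 400, seed = 88)
  expect_equal(r$cc, 1)
  expect_equal(r$p, 1 / 401)
  # oracle: Pearson correlation of the rank vectors
  y <- rnorm(30)
  r2 <- spearman_permutation(x, y, n_perm = 200, seed = 89)
  expect_equal(r2$cc, cor(rank(x), rank(y)), tolerance = 1e-12)
  expect_gt(r2$p, 1 / 201)
  expect_warning(spearman_permutation(rep(1, 10), rnorm(10), n_perm = 50),
                 "constant")
  expect_error(spearman_permutation(1:2, 1:2), "at least 3")
})
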