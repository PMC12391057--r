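test_that("the default configuration matches the validation-population design", {
  sim <- simulate_population(sim_config(seed = 51))
  expect_identical(sim$recording$n_neurons, 180L)
  expect_identical(sim$recording$n_windows, 30L)
  expect_identical(sim$recording$duration, 1)
  expect_identical(unname(c(table(sim$truth$subnetwork))), rep(60L, 3))
  expect_identical(unname(c(table(sim$truth$scheme))), rep(60L, 3))
  expect_identical(unname(c(table(sim$recording$windows$label))), rep(10L, 3))
})

test_that("the simulator is deterministic for a fixed seed and validates config", {
  s1 <- simulate_population(sim_config(neurons_per_scheme = 2,
                                       trials_per_condition = 4, seed = 52))
  s2 <- simulate_population(sim_config(neurons_per_scheme = 2,
                                       trials_per_condition = 4, seed = 52))
  expect_identical(s1$recording$trains, s2$recording$trains)
  expect_error(sim_config(baseline_rate_hz = 0), "baseline_rate_hz")
  expect_error(sim_config(duration_s = -1, noise_prob = 2),
               "duration_s, noise_prob")
})

test_that("rate coders elevate spike counts on preferred trials", {
  sim <- simulate_population(sim_config(seed = 53))
  rate_ids <- sim$truth$neuron_id[sim$truth$scheme == "rate"]
  cond <- as.integer(sub("C", "", sim$recording$windows$label))
  pref <- nonpref <- numeric(0)
  for (nid in rate_ids) {
    sn <- sim$truth$subnetwork[sim$truth$neuron_id == nid]
    n <- lengths(sim$recording$trains[[nid]])
    pref <- c(pref, n[cond == sn])
    nonpref <- c(nonpref, n[cond != sn])
  }
  expect_lt(t.test(pref, nonpref, alternative = "greater")$p.value, 1e-10)
})

test_that("temporal coders carry timing, not rate, information", {
  sim <- simulate_population(sim_config(seed = 54))
  temp_ids <- sim$truth$neuron_id[sim$truth$scheme == "temporal"]
  cond <- as.integer(sub("C", "", sim$recording$windows$label))
  # count difference between preferred and non-preferred trials: none
  dmeans <- vapply(temp_ids, function(nid) {
    sn <- sim$truth$subnetwork[sim$truth$neuron_id == nid]
    n <- lengths(sim$recording$trains[[nid]])
    mean(n[cond == sn]) - mean(n[cond != sn])
  }, 0)
  expect_gt(t.test(dmeans)$p.value, 0.01)
  # but fine-timescale fingerprints show preferred-block structure
  ut_lt <- function(s) upper.tri(matrix(0, s, s))
  ok <- vapply(temp_ids[1:20], function(nid) {
    sn <- sim$truth$subnetwork[sim$truth$neuron_id == nid]
    m <- vp_distance_matrix(sim$recording$trains[[nid]], q = 200)
    ip <- cond == sn
    ut <- upper.tri(m)
    within_pref <- m[ut & outer(ip, ip, "&")]
    cross <- m[ut & (outer(ip, !ip, "&") | outer(!ip, ip, "&"))]
    mean(within_pref) < mean(cross)
  }, TRUE)
  expect_true(all(ok))
})

test_that("results do not depend on window ordering", {
  sim <- simulate_population(sim_config(neurons_per_scheme = 3,
                                        trials_per_condition = 5, seed = 55))
  rec <- sim$recording
  set.seed(1)
  perm <- sample(rec$n_windows)
  rec_p <- ensemble_recording(lapply(rec$trains, function(tr) tr[perm]),
                              duration = rec$duration,
                              windows = rec$windows[perm, , drop = FALSE])
  expect_equal(cs_matrix(compute_ssims(rec, q = 10))$values,
               cs_matrix(compute_ssims(rec_p, q = 10))$values,
               tolerance = 1e-12)
  # shuffle_windows permutes the condition layout, still 10 per condition
  simsh <- simulate_population(sim_config(shuffle_windows = TRUE, seed = 55))
  expect_identical(unname(c(table(simsh$recording$windows$label))),
                   rep(10L, 3))
  expect_false(identical(simsh$recording$windows$label,
                         sort(simsh$recording$windows$label)))
})

test_that("tuned-Poisson demo neurons behave as their tuning dictates", {
  sim <- simulate_tuned_poisson(n_neurons = 4, trials = 8, seed = 56)
  rec <- sim$recording
  expect_identical(rec$n_windows, 48L)
  ori <- as.numeric(sub("ori", "", rec$windows$label))
  pref <- sim$truth$preferred_deg[1]
  ip <- abs(ori - pref) < 1e-9
  m <- vp_distance_matrix(rec$trains[[1]], q = 10)
  ut <- upper.tri(m)
  cross_mask <- ut & (outer(ip, !ip, "&") | outer(!ip, ip, "&"))
  expect_lt(mean(m[ut & outer(ip, ip, "&")]), mean(m[cross_mask]))
  # untuned neuron: within/between ratio near 1
  flat <- simulate_tuned_poisson(n_neurons = 4, trials = 8, tuning_depth = 0,
                                 seed = 57)
  mf <- vp_distance_matrix(flat$recording$trains[[1]], q = 10)
  ratio <- mean(mf[ut & outer(ip, ip, "&")]) / mean(mf[cross_mask])
  expect_lt(abs(ratio - 1), 0.35)
  # determinism
  again <- simulate_tuned_poisson(n_neurons = 4, trials = 8, seed = 56)
  expect_identical(again$recording$trains, sim$recording$trains)
})
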