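test_that("compute_theta: forced-arithmetic cases", {
  d <- toy_trial()
  wu <- uniform_weights(d)
  th <- compute_theta(d, wu, comparison = c("A", "B"))
  # uniform weights -> plain arithmetic means
  expect_equal(th$arm_means$cost, c(mean(d$cost[1:4]), mean(d$cost[5:8])))
  expect_equal(th$arm_means$qaly, c(mean(d$qaly[1:4]), mean(d$qaly[5:8])))
  # equal follow-up: theta = log ratio of mean event counts (1.5 vs 1)
  expect_equal(th$theta_e, log(1 / 1.5))
  expect_true(th$theta_valid)

  # point-mass weights -> that patient's values
  wp <- pointmass_weights(d, k = 2)
  thp <- compute_theta(d, wp, comparison = c("A", "B"))
  expect_equal(thp$arm_means$cost, c(200, 250))
  expect_equal(thp$theta_e, log((1 / 52) / (2 / 52)))

  # weighted mean events 2 vs 1 -> log 2
  w2 <- structure(list(A = c(0, 1, 0, 0), B = c(0, 0, 0, 1)),
                  scheme = "bayesian", class = "bootstrap_weights")
  expect_equal(compute_theta(d, w2, c("A", "B"))$theta_e, log(2 / 2))
  w3 <- structure(list(A = c(1, 0, 0, 0), B = c(0, 0, 0, 1)),
                  scheme = "bayesian", class = "bootstrap_weights")
  expect_equal(compute_theta(d, w3, c("A", "B"))$theta_e, log(2 / 1))

  # zero weighted event total -> invalid theta
  w0 <- pointmass_weights(d, k = 3)  # patient 3 of A has 0 events
  expect_false(compute_theta(d, w0, c("A", "B"))$theta_valid)
  expect_true(is.na(compute_theta(d, w0, c("A", "B"))$theta_e))

  expect_error(compute_theta(d, wu, c("A", "Z")), "not found")
})

test_that("unequal follow-up uses event rates, not mean counts", {
  d <- trial_data(data.frame(
    arm = rep(c("A", "B"), each = 2),
    cost = 1, qaly = 0.5,
    events = c(2, 2, 2, 2),
    followup = c(26, 26, 52, 52)))
  th <- compute_theta(d, uniform_weights(d), c("A", "B"))
  # same mean events but B observed twice as long -> rate ratio 1/2
  expect_equal(th$theta_e, log(0.5))
})

test_that("engine draws reproduce compute_theta on the reconstructed replicate", {
  d <- generate_trial(synth_trial_spec(arm_sizes = c(9, 7, 8)), seed = 4)
  s <- bootstrap_sample(d, M = 5, comparison = c("T1", "T3"), seed = 31)
  for (i in seq_len(5)) {
    set.seed(replicate_seed(31, s$draws$replicate[i]))
    w <- draw_replicate(d, "bayesian")
    th <- compute_theta(d, w, c("T1", "T3"))
    expect_equal(s$draws$cost_T1[i], th$arm_means$cost[1])
    expect_equal(s$draws$qaly_T3[i], th$arm_means$qaly[3])
    expect_equal(s$draws$theta_e[i], th$theta_e)
  }
})

test_that("flat evidence: rejection accepts everything and equals scheme none", {
  d <- generate_trial(synth_trial_spec(arm_sizes = c(25, 20, 30)), seed = 9)
  s0 <- bootstrap_sample(d, M = 300, comparison = c("T1", "T3"), seed = 17)
  sr <- rejection_sample(d, flat_evidence(), M = 300,
                         comparison = c("T1", "T3"), seed = 17)
  expect_equal(sr$acceptance_rate, 1.0)
  expect_equal(sr$draws, s0$draws, tolerance = 0)
  expect_equal(sr$normalized_weights, rep(1 / 300, 300))

  si <- importance_sample(d, flat_evidence(), M = 300,
                          comparison = c("T1", "T3"), seed = 17)
  expect_equal(si$normalized_weights, rep(1 / 300, 300))
  expect_equal(si$effective_sample_size, 300)
  expect_equal(si$draws, s0$draws, tolerance = 0)
})

test_that("importance weights normalize and ESS follows its formula", {
  d <- generate_trial(synth_trial_spec(arm_sizes = c(12, 12, 12)), seed = 21)
  ev <- normal_evidence(-0.4, 0.3)
  s <- importance_sample(d, ev, M = 400, comparison = c("T1", "T3"), seed = 2)
  rw <- s$draws$raw_weight
  expect_true(all(rw >= 0 & rw <= 1))
  expect_equal(sum(s$normalized_weights), 1, tolerance = 1e-10)
  expect_equal(s$normalized_weights, rw / sum(rw))
  expect_equal(s$effective_sample_size, sum(rw)^2 / sum(rw^2))
  expect_gt(s$effective_sample_size, 1)
  expect_lte(s$effective_sample_size, 400)
  # two-draw normalization example: raw 0.2 and 0.6 -> 0.25 and 0.75
  expect_equal(c(0.2, 0.6) / sum(c(0.2, 0.6)), c(0.25, 0.75))
})

test_that("prior-data conflict raises a diagnosable error", {
  d <- generate_trial(synth_trial_spec(arm_sizes = c(15, 15, 15)), seed = 6)
  ev <- normal_evidence(8, 0.001)  # unreachable by any resample
  expect_error(
    rejection_sample(d, ev, M = 10, comparison = c("T1", "T3"),
                     max_attempts = 200, seed = 1),
    class = "ceaboot_conflict_error")
  err <- tryCatch(
    rejection_sample(d, ev, M = 10, comparison = c("T1", "T3"),
                     max_attempts = 200, seed = 1),
    ceaboot_conflict_error = identity)
  expect_match(conditionMessage(err), "acceptance rate")
  expect_error(
    importance_sample(d, ev, M = 50, comparison = c("T1", "T3"), seed = 1),
    "degenerate")
})

test_that("evidence shifts the posterior toward mu (shrinkage direction)", {
  d <- generate_trial(synth_trial_spec(arm_sizes = c(60, 2, 60)), seed = 12)
  ev <- pool_evidence(0.38, 0.25, 0.57, 0.01783)
  s0 <- bootstrap_sample(d, M = 2000, comparison = c("T1", "T3"), seed = 8)
  si <- importance_sample(d, ev, M = 2000, comparison = c("T1", "T3"), seed = 8)
  m0 <- mean(s0$draws$theta_e)
  mi <- sum(si$normalized_weights * si$draws$theta_e)
  expect_true(mi > min(m0, ev$mu) && mi < max(m0, ev$mu))
  expect_true(abs(mi - ev$mu) < abs(m0 - ev$mu))
})

test_that("missing data are imputed inside each replicate", {
  d <- generate_trial(synth_trial_spec(arm_sizes = c(20, 20, 20)), seed = 14)
  dm <- generate_missingness(d, 0.1, seed = 15)
  s <- bootstrap_sample(dm, M = 50, comparison = c("T1", "T3"), seed = 3)
  expect_false(anyNA(s$draws$cost_T1))
  expect_false(anyNA(s$draws$theta_e))
  expect_identical(s$impute_method, "weighted_arm_mean")
  # hot_deck route also runs and is deterministic under the seed
  s1 <- bootstrap_sample(dm, M = 20, comparison = c("T1", "T3"), seed = 3,
                         impute_method = "hot_deck")
  s2 <- bootstrap_sample(dm, M = 20, comparison = c("T1", "T3"), seed = 3,
                         impute_method = "hot_deck")
  expect_equal(s1$draws, s2$draws, tolerance = 0)
  # imputation happens per replicate: draws differ from the complete-data run
  expect_false(isTRUE(all.equal(s$draws,
                                bootstrap_sample(d, M = 50,
                                                 comparison = c("T1", "T3"),
                                                 seed = 3)$draws)))
})
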