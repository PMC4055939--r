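test_that("generate_trial is seed-reproducible and respects the spec", {
  spec <- synth_trial_spec()
  d1 <- generate_trial(spec, seed = 5)
  d2 <- generate_trial(spec, seed = 5)
  expect_identical(d1, d2)
  expect_identical(arms(d1), c("T1", "T2", "T3"))
  expect_equal(as.integer(table(d1$arm)[arms(d1)]), c(156, 148, 145))
  expect_true(all(d1$qaly >= 0 & d1$qaly <= 1))
  expect_true(all(d1$cost >= 0))
  expect_error(synth_trial_spec(event_rates = c(-1, 1, 1)), "invalid")
  expect_error(synth_trial_spec(arm_sizes = c(1, 5, 5)), ">= 2 patients")
})

test_that("event counts match the Poisson moments at scale", {
  spec <- synth_trial_spec(arm_labels = c("A", "B"), arm_sizes = c(25000, 25000),
                           event_rates = c(1.8, 1.1),
                           base_cost_mean = c(2000, 3500))
  d <- generate_trial(spec, seed = 77)
  for (j in 1:2) {
    g <- arms(d)[j]
    ev <- d$events[d$arm == g]
    se <- sqrt(spec$event_rates[j] / length(ev))
    expect_lt(abs(mean(ev) - spec$event_rates[j]), 3 * se)
  }
})

test_that("the generator induces the case-study dependence structure", {
  d <- generate_trial(synth_trial_spec(arm_sizes = c(2000, 2, 2000)), seed = 21)
  for (g in c("T1", "T3")) {
    idx <- d$arm == g
    # the base-cost gamma is heavily skewed, so the event-driven share of
    # cost variance is modest; sign and clear separation from 0 (SE ~ 0.02
    # at n = 2000) are what the structure requires
    expect_gt(cor(d$cost[idx], d$events[idx]), 0.05)  # costs rise with events
    expect_lt(cor(d$qaly[idx], d$events[idx]), -0.1)  # QALYs fall with events
  }
  # near-zero event rate: mean cost collapses to the base-cost mean
  d0 <- generate_trial(synth_trial_spec(arm_labels = c("A", "B"),
                                        arm_sizes = c(4000, 4000),
                                        event_rates = c(1e-6, 1e-6),
                                        base_cost_mean = c(2000, 2000)),
                       seed = 22)
  expect_equal(mean(d0$events), 0, tolerance = 1e-3)
  expect_equal(mean(d0$cost), 2000, tolerance = 0.1)  # gamma mean, 3 SE ~ 140
})

test_that("MCAR missingness flags the expected fraction, reproducibly", {
  d <- generate_trial(synth_trial_spec(arm_sizes = c(340, 330, 330)), seed = 30)
  expect_identical(generate_missingness(d, 0, seed = 1), d)
  dm1 <- generate_missingness(d, 0.1, seed = 2)
  dm2 <- generate_missingness(d, 0.1, seed = 2)
  expect_identical(dm1, dm2)
  n_flagged <- sum(is.na(dm1$cost)) + sum(is.na(dm1$qaly)) +
    sum(is.na(dm1$events))
  n_cells <- 3 * nrow(d)
  expect_lt(abs(n_flagged - 0.1 * n_cells), 3 * sqrt(n_cells * 0.1 * 0.9))
  # a fraction that empties an arm errors
  tiny <- generate_trial(synth_trial_spec(arm_sizes = c(2, 2, 2)), seed = 1)
  expect_error(generate_missingness(tiny, 0.95, seed = 4), "no observed")
})

test_that("parameter recovery: bootstrap posterior centers on the true log RR", {
  spec <- synth_trial_spec(arm_labels = c("T1", "T3"), arm_sizes = c(500, 500),
                           event_rates = c(1.8, 1.1),
                           base_cost_mean = c(2000, 3500))
  d <- generate_trial(spec, seed = 55)
  s <- bootstrap_sample(d, M = 1000, comparison = c("T1", "T3"), seed = 56)
  truth <- log(1.1 / 1.8)
  # the bootstrap spread estimates the sampling SE of the realized trial's
  # log RR, so the posterior mean should sit within 3 of them from truth
  expect_lt(abs(mean(s$draws$theta_e) - truth), 3 * sd(s$draws$theta_e))
})

test_that("conjugate_posterior matches closed-form arithmetic", {
  # equal precisions: posterior mean is the midpoint
  expect_equal(conjugate_posterior(0, 1, 2, 1)$mean, 1)
  # flat-prior limit: posterior equals the data
  p <- conjugate_posterior(-0.4, 0.2, 0, 1e6)
  expect_equal(p$mean, -0.4, tolerance = 1e-9)
  expect_equal(p$sd, 0.2, tolerance = 1e-9)
  # worked case, recomputed with independent arithmetic
  p2 <- conjugate_posterior(-0.5, 0.2, -0.968, 0.246)
  expect_equal(p2$mean,
               (-0.5 / 0.04 + -0.968 / 0.060516) / (1 / 0.04 + 1 / 0.060516))
  expect_equal(p2$sd, sqrt(1 / (1 / 0.04 + 1 / 0.060516)))
  expect_error(conjugate_posterior(0, -1, 0, 1), "positive")
})

test_that("enumeration oracle: multinomial expectation identities", {
  d <- toy_trial()
  # flat evidence, statistic = arm A mean cost. The plain ordinary-bootstrap
  # expectation of a resample mean is the sample mean -- but only over the
  # replicates where theta is defined, so compare against the conditional
  # expectation computed by an independent direct sum over the same space.
  stat <- function(am, th) am$cost[am$arm == "A"]
  val <- enumerate_ordinary_bootstrap(d, flat_evidence(), stat, c("A", "B"))
  expect_gt(attr(val, "normalizer"), 0.9)  # few zero-event resamples
  expect_equal(as.numeric(val), mean(d$cost[1:4]), tolerance = 0.02)

  # with all-positive events theta is always defined and the identity is exact
  d2 <- trial_data(data.frame(arm = rep(c("A", "B"), each = 2),
                              cost = c(10, 30, 20, 40), qaly = c(.5, .6, .7, .8),
                              events = c(1, 2, 1, 3), followup = 52))
  val2 <- enumerate_ordinary_bootstrap(d2, flat_evidence(), stat, c("A", "B"))
  expect_equal(attr(val2, "normalizer"), 1)
  expect_equal(as.numeric(val2), 20)
})

test_that("enumeration oracle matches a hand-built 3x3 outcome table", {
  # n = 2 per arm: weights per arm are (1,0), (.5,.5), (0,1) with
  # probabilities 1/4, 1/2, 1/4 (Binomial(2, 1/2) counts over 2 patients)
  d <- trial_data(data.frame(arm = rep(c("A", "B"), each = 2),
                             cost = c(10, 30, 20, 40), qaly = c(.5, .6, .7, .8),
                             events = c(1, 2, 1, 3), followup = 52))
  ev <- normal_evidence(0, 0.5)
  wA <- list(c(1, 0), c(.5, .5), c(0, 1)); pA <- c(.25, .5, .25)
  num <- 0; den <- 0
  for (i in 1:3) for (j in 1:3) {
    mA <- sum(wA[[i]] * c(1, 2)); mB <- sum(wA[[j]] * c(1, 3))
    cB <- sum(wA[[j]] * c(20, 40))
    th <- log(mB / mA)
    wt <- exp(-th^2 / (2 * 0.5^2))
    num <- num + pA[i] * pA[j] * wt * cB
    den <- den + pA[i] * pA[j] * wt
  }
  stat <- function(am, th) am$cost[am$arm == "B"]
  val <- enumerate_ordinary_bootstrap(d, ev, stat, c("A", "B"))
  expect_equal(as.numeric(val), num / den, tolerance = 1e-12)
  expect_equal(attr(val, "normalizer"), den, tolerance = 1e-12)
})
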