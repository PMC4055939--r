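# Fixtures and small utilities shared across the suite. All data are
# generated in code; seeds are fixed a priori.

# tiny two-arm trial with hand-set values (complete)
toy_trial <- function() {
  trial_data(data.frame(
    patient_id = sprintf("p%d", 1:8),
    arm = rep(c("A", "B"), each = 4),
    cost = c(100, 200, 300, 400, 150, 250, 350, 450),
    qaly = c(0.9, 0.8, 0.7, 0.6, 0.85, 0.75, 0.65, 0.55),
    events = c(1, 2, 0, 3, 0, 1, 1, 2),
    followup = 52))
}

# uniform bootstrap_weights for a trial (deterministic)
uniform_weights <- function(data, scheme = "bayesian") {
  w <- lapply(arms(data), function(g) {
    n <- sum(data$arm == g)
    rep(1 / n, n)
  })
  names(w) <- arms(data)
  structure(w, scheme = scheme, class = "bootstrap_weights")
}

# point-mass weights: all mass on patient `k` of each arm
pointmass_weights <- function(data, k = 1) {
  w <- lapply(arms(data), function(g) {
    n <- sum(data$arm == g)
    v <- rep(0, n); v[k] <- 1; v
  })
  names(w) <- arms(data)
  structure(w, scheme = "bayesian", class = "bootstrap_weights")
}

# assemble a posterior_sample by hand (for output-module tests)
make_sample <- function(draws, weights, comparison = c("A", "B"),
                        arm_labels = c("A", "B"), scheme = "importance") {
  M <- nrow(draws)
  structure(list(draws = draws, arms = arm_labels, comparison = comparison,
                 scheme = scheme, bootstrap = "bayesian",
                 normalized_weights = weights / sum(weights),
                 attempts = M, acceptance_rate = NA_real_,
                 effective_sample_size = sum(weights)^2 / sum(weights^2),
                 n_invalid_theta = 0L, M = M, seed = 0,
                 evidence = flat_evidence()),
            class = "posterior_sample")
}

# Monte-Carlo SE of a weighted mean estimate from a posterior_sample
mcse_of <- function(sample, values) {
  w <- sample$normalized_weights
  m <- sum(w * values)
  sqrt(sum(w^2 * (values - m)^2))
}

dcol <- function(sample, what, arm) sample$draws[[paste0(what, "_", arm)]]

delta_of <- function(sample, what = "cost") {
  dcol(sample, what, sample$comparison[2]) - dcol(sample, what, sample$comparison[1])
}

# delta-method MC SE of an ICER = mean(dC)/mean(dE) estimate
icer_mcse <- function(sample) {
  w <- sample$normalized_weights
  dC <- delta_of(sample, "cost"); dE <- delta_of(sample, "qaly")
  mC <- sum(w * dC); mE <- sum(w * dE)
  vC <- sum(w^2 * (dC - mC)^2)
  vE <- sum(w^2 * (dE - mE)^2)
  cv <- sum(w^2 * (dC - mC) * (dE - mE))
  abs(mC / mE) * sqrt(vC / mC^2 + vE / mE^2 - 2 * cv / (mC * mE))
}
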