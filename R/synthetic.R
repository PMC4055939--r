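# Synthetic multi-arm trial generation with the dependence structure a
# trial-based CEA of an exacerbation-driven disease exhibits (right-skewed
# costs rising with events, QALYs falling with events), plus MCAR
# missingness, and two independent oracles used by the validation suite:
# the conjugate normal-normal posterior and exhaustive enumeration of the
# ordinary bootstrap on tiny instances.

#' Specification of a synthetic multi-arm trial
#'
#' Defaults describe a three-arm COPD-like pragmatic trial over a 52-week
#' window, sized as the motivating case study (156/148/145): annual
#' exacerbation rates 1.8 / 1.75 / 1.1 (the third arm is the effective,
#' costlier combination therapy), gamma-distributed base costs (shape 0.5,
#' strongly right-skewed) with means 2000 / 2900 / 3500 currency units
#' plus 450 per exacerbation, and QALYs 0.74 baseline minus 0.03 per
#' exacerbation with N(0, 0.075) noise, clamped to the attainable range
#' `[0, followup/52]`.
#'
#' @param arm_labels character vector of arm names.
#' @param arm_sizes integer vector of patients per arm (>= 2 each).
#' @param event_rates expected exacerbations per 52 weeks, per arm (> 0).
#' @param base_cost_mean mean event-independent cost per arm.
#' @param base_cost_shape gamma shape of the base cost (smaller = more
#'   skewed).
#' @param cost_per_event incremental cost of one exacerbation.
#' @param qaly_baseline event-free expected QALY over the window (annual
#'   scale).
#' @param qaly_decrement_per_event QALY loss per exacerbation.
#' @param qaly_noise_sd SD of the symmetric QALY noise.
#' @param followup follow-up length in weeks (constant across patients).
#' @return a `synth_trial_spec` object.
#' @export
synth_trial_spec <- function(arm_labels = c("T1", "T2", "T3"),
                             arm_sizes = c(156, 148, 145),
                             event_rates = c(1.8, 1.75, 1.1),
                             base_cost_mean = c(2000, 2900, 3500),
                             base_cost_shape = 0.5,
                             cost_per_event = 450,
                             qaly_baseline = 0.74,
                             qaly_decrement_per_event = 0.03,
                             qaly_noise_sd = 0.075,
                             followup = 52) {
  k <- length(arm_labels)
  if (k < 2) .stop_mod("synthetic_validation", "need at least 2 arms")
  arm_sizes <- rep_len(arm_sizes, k)
  event_rates <- rep_len(event_rates, k)
  base_cost_mean <- rep_len(base_cost_mean, k)
  if (any(arm_sizes < 2))
    .stop_mod("synthetic_validation", "every arm needs >= 2 patients")
  if (any(event_rates <= 0) || any(base_cost_mean <= 0) ||
      base_cost_shape <= 0 || cost_per_event < 0 || qaly_noise_sd < 0 ||
      followup <= 0)
    .stop_mod("synthetic_validation", "invalid synthetic trial spec")
  structure(list(arm_labels = arm_labels, arm_sizes = as.integer(arm_sizes),
                 event_rates = event_rates, base_cost_mean = base_cost_mean,
                 base_cost_shape = base_cost_shape,
                 cost_per_event = cost_per_event,
                 qaly_baseline = qaly_baseline,
                 qaly_decrement_per_event = qaly_decrement_per_event,
                 qaly_noise_sd = qaly_noise_sd, followup = followup),
            class = "synth_trial_spec")
}

#' Generate a synthetic trial
#'
#' Per patient in arm `a`: `events ~ Poisson(rate_a * followup / 52)`;
#' `cost = Gamma(shape, mean = base_a) + cost_per_event * events`;
#' `qaly = baseline - decrement * events + N(0, sd)`, clamped to
#' `[0, followup/52]`. This induces the positive cost-event and negative
#' QALY-event correlations the evidence-weighting mechanism relies on.
#'
#' @param spec a [synth_trial_spec()].
#' @param seed integer seed; a fixed seed gives an identical trial.
#' @return a [trial_data()] object.
#' @examples
#' d <- generate_trial(synth_trial_spec(), seed = 1)
#' d
#' @export
generate_trial <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "synth_trial_spec"))
  set.seed(seed)
  qmax <- spec$followup / 52
  recs <- lapply(seq_along(spec$arm_labels), function(j) {
    n <- spec$arm_sizes[j]
    events <- rpois(n, spec$event_rates[j] * spec$followup / 52)
    base <- rgamma(n, shape = spec$base_cost_shape,
                   rate = spec$base_cost_shape / spec$base_cost_mean[j])
    cost <- base + spec$cost_per_event * events
    qaly <- spec$qaly_baseline - spec$qaly_decrement_per_event * events +
      rnorm(n, 0, spec$qaly_noise_sd)
    qaly <- pmin(pmax(qaly, 0), qmax)
    data.frame(patient_id = sprintf("%s-%04d", spec$arm_labels[j], seq_len(n)),
               arm = spec$arm_labels[j], cost = cost, qaly = qaly,
               events = events, followup = spec$followup)
  })
  trial_data(do.call(rbind, recs), arms = spec$arm_labels)
}

#' Flag values missing completely at random
#'
#' Flags each `cost`, `qaly` and `events` cell missing independently with
#' probability `fraction` (MCAR). Errors if the draw would leave an arm
#' with no observed value for some field, which would make imputation
#' impossible.
#'
#' @param data a [trial_data()] object.
#' @param fraction per-cell missingness probability in `[0, 1)`.
#' @param seed integer seed for a reproducible mask.
#' @param fields which fields to perturb.
#' @return a `trial_data` copy with missing flags.
#' @export
generate_missingness <- function(data, fraction, seed = 1,
                                 fields = c("cost", "qaly", "events")) {
  stopifnot(inherits(data, "trial_data"), fraction >= 0, fraction < 1)
  set.seed(seed)
  out <- data
  for (f in fields) {
    mask <- runif(nrow(out)) < fraction
    out[[f]][mask] <- NA
  }
  for (g in arms(out)) for (f in fields) {
    if (all(is.na(out[[f]][out$arm == g])))
      .stop_mod("synthetic_validation",
                "fraction %.2f left arm '%s' with no observed '%s'",
                fraction, g, f)
  }
  out
}

#' Conjugate normal-normal posterior (closed-form oracle)
#'
#' Posterior of a scalar parameter under a normal likelihood
#' `N(data_mean, data_se)` and normal prior `N(prior_mean, prior_sd)`:
#' precision-weighted mean, posterior precision = prior precision + data
#' precision. When the bootstrap distribution of `theta_e` is close to
#' normal (large trials), the evidence-weighted posterior the samplers
#' target has this closed form, making it an independent oracle.
#'
#' @param data_mean,data_se mean and SE of the (approximately normal)
#'   no-evidence posterior.
#' @param prior_mean,prior_sd evidence likelihood mean and SD.
#' @return list with `mean` and `sd`.
#' @export
conjugate_posterior <- function(data_mean, data_se, prior_mean, prior_sd) {
  if (data_se <= 0 || prior_sd <= 0)
    .stop_mod("synthetic_validation", "scales must be positive")
  prec <- 1 / data_se^2 + 1 / prior_sd^2
  list(mean = (data_mean / data_se^2 + prior_mean / prior_sd^2) / prec,
       sd = sqrt(1 / prec))
}

# all vectors of `parts` non-negative integers summing to `total`
.compositions <- function(total, parts) {
  if (parts == 1) return(matrix(total, 1, 1))
  out <- vector("list", total + 1)
  for (k in 0:total) {
    sub <- .compositions(total - k, parts - 1)
    out[[k + 1]] <- cbind(k, sub, deparse.level = 0)
  }
  do.call(rbind, out)
}

#' Exhaustive ordinary-bootstrap expectation (brute-force oracle)
#'
#' For a tiny trial (total patients <= 8) the ordinary bootstrap has
#' finitely many weight vectors per arm, so the evidence-weighted
#' posterior expectation of any statistic can be computed exactly: sum
#' over all per-arm multinomial count vectors of
#' `statistic x multinomial probability x evidence weight`, normalized by
#' the total weighted probability. Replicates with an undefined
#' `theta_e` carry weight 0, matching the samplers.
#'
#' This oracle performs its own arithmetic on the count vectors (it does
#' not call the sampling engine), so it is an independent check of
#' [importance_sample()] and [rejection_sample()].
#'
#' @param data a complete [trial_data()] with at most 8 patients total.
#' @param evidence an `external_evidence` object.
#' @param statistic function of `(arm_means, theta_e)` returning a numeric
#'   scalar or named vector; `arm_means` is a data frame with columns
#'   `arm`, `cost`, `qaly`, `events`, `rate`.
#' @param comparison `c(reference, treatment)` arm labels.
#' @return the exact weighted expectation(s) of `statistic`, with the
#'   normalizing constant (the expected evidence weight) in attribute
#'   `"normalizer"`.
#' @export
enumerate_ordinary_bootstrap <- function(data, evidence, statistic, comparison) {
  stopifnot(inherits(data, "trial_data"), inherits(evidence, "external_evidence"),
            is.function(statistic))
  if (anyNA(data$cost) || anyNA(data$qaly) || anyNA(data$events))
    .stop_mod("synthetic_validation", "oracle requires complete data")
  if (nrow(data) > 8)
    .stop_mod("synthetic_validation",
              "instance too large for enumeration (%d > 8 patients)", nrow(data))
  a <- arms(data)
  if (length(comparison) != 2 || !all(comparison %in% a))
    .stop_mod("synthetic_validation", "comparison arms not found")
  per <- lapply(a, function(g) {
    idx <- which(data$arm == g)
    n <- length(idx)
    comps <- .compositions(n, n)
    probs <- apply(comps, 1, function(k) stats::dmultinom(k, prob = rep(1/n, n)))
    list(cost = data$cost[idx], qaly = data$qaly[idx],
         events = data$events[idx], followup = data$followup[idx],
         n = n, comps = comps, probs = probs)
  })
  names(per) <- a
  combo <- do.call(expand.grid, lapply(per, function(p) seq_len(nrow(p$comps))))
  num <- NULL
  den <- 0
  for (r in seq_len(nrow(combo))) {
    p_rep <- 1
    am <- do.call(rbind, lapply(seq_along(a), function(j) {
      p <- per[[j]]
      k <- p$comps[combo[r, j], ]
      data.frame(arm = a[j],
                 cost = sum(k * p$cost) / p$n,
                 qaly = sum(k * p$qaly) / p$n,
                 events = sum(k * p$events) / p$n,
                 rate = sum(k * p$events) / sum(k * p$followup))
    }))
    for (j in seq_along(a)) p_rep <- p_rep * per[[j]]$probs[combo[r, j]]
    er <- am$events[am$arm == comparison[1]]
    et <- am$events[am$arm == comparison[2]]
    if (et > 0 && er > 0) {
      th <- log(am$rate[am$arm == comparison[2]] /
                  am$rate[am$arm == comparison[1]])
      wt <- evidence_weight(th, evidence)
      s <- statistic(am, th)
      num <- if (is.null(num)) p_rep * wt * s else num + p_rep * wt * s
      den <- den + p_rep * wt
    }
  }
  if (den <= 0)
    .stop_mod("synthetic_validation", "all enumerated replicates have weight 0")
  structure(num / den, normalizer = den)
}
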