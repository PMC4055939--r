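# Converting bootstrap draws from P(theta|D) into a sample from
# P(theta|D, D_e): plain bootstrap (no evidence), rejection sampling, and
# importance sampling. All three run the same per-replicate recipe --
# (a) draw within-arm weights, (b) impute missing values under those
# weights, (c) compute arm means and the evidence parameter -- inside a
# dedicated RNG substream per replicate index, so runs that share a master
# seed share the identical replicate stream (common random numbers).

#' Arm-level parameters for one bootstrap replicate
#'
#' Computes the per-arm weighted means of cost, effectiveness and event
#' count under one replicate's probability vectors, plus the evidence
#' parameter `theta_e = log(rate(trt) / rate(ref))`, where
#' `rate(a) = sum(w_i events_i) / sum(w_i followup_i)` over arm `a`. With
#' constant follow-up this is the log ratio of weighted mean event counts.
#' If either arm's weighted event total is zero the log rate ratio is
#' undefined and `theta_valid` is `FALSE`.
#'
#' @param data a complete (post-imputation) [trial_data()] object.
#' @param weights a `bootstrap_weights` replicate from [draw_replicate()].
#' @param comparison character vector `c(reference, treatment)`; `theta_e`
#'   and the incremental summaries are treatment minus/over reference.
#' @return a list with `arm_means` (data frame: arm, cost, qaly, events,
#'   rate), `theta_e`, and `theta_valid`.
#' @export
compute_theta <- function(data, weights, comparison) {
  stopifnot(inherits(data, "trial_data"), inherits(weights, "bootstrap_weights"))
  a <- arms(data)
  if (length(comparison) != 2 || !all(comparison %in% a))
    .stop_mod("synthesis", "comparison arms (%s) not found in trial",
              paste(comparison, collapse = ", "))
  if (anyNA(data$cost) || anyNA(data$qaly) || anyNA(data$events))
    .stop_mod("synthesis", "data contain missing values; impute first")
  am <- do.call(rbind, lapply(a, function(g) {
    idx <- which(data$arm == g)
    w <- weights[[g]]
    data.frame(arm = g,
               cost = sum(w * data$cost[idx]),
               qaly = sum(w * data$qaly[idx]),
               events = sum(w * data$events[idx]),
               rate = sum(w * data$events[idx]) / sum(w * data$followup[idx]))
  }))
  er <- am$events[am$arm == comparison[1]]
  et <- am$events[am$arm == comparison[2]]
  valid <- et > 0 && er > 0
  theta <- if (valid) {
    log(am$rate[am$arm == comparison[2]] / am$rate[am$arm == comparison[1]])
  } else NA_real_
  list(arm_means = am, theta_e = theta, theta_valid = valid)
}

# Fast per-arm column cache used by the engine loop.
.prep_trial <- function(data) {
  a <- arms(data)
  per <- lapply(a, function(g) {
    idx <- which(data$arm == g)
    list(cost = data$cost[idx], qaly = data$qaly[idx],
         events = data$events[idx], followup = data$followup[idx],
         n = length(idx),
         miss = c(cost = anyNA(data$cost[idx]), qaly = anyNA(data$qaly[idx]),
                  events = anyNA(data$events[idx])))
  })
  names(per) <- a
  per
}

.sample_engine <- function(data, evidence, M, method, bootstrap, comparison,
                           seed, max_attempts, impute_method) {
  stopifnot(inherits(data, "trial_data"))
  if (is.null(evidence)) evidence <- flat_evidence()
  stopifnot(inherits(evidence, "external_evidence"))
  if (!is.numeric(M) || M < 1)
    .stop_mod("synthesis", "M must be >= 1")
  M <- as.integer(M)
  a <- arms(data)
  if (length(comparison) != 2 || !all(comparison %in% a))
    .stop_mod("synthesis", "comparison arms (%s) not found in trial",
              paste(comparison, collapse = ", "))
  per <- .prep_trial(data)
  A <- length(a)
  iref <- match(comparison[1], a)
  itrt <- match(comparison[2], a)
  any_missing <- any(vapply(per, function(p) any(p$miss), TRUE))

  ev_type <- evidence$type
  ev_mu <- evidence$mu
  ev_2s2 <- 2 * evidence$sigma^2
  ev_fn <- evidence$weight_fn

  cost_m <- matrix(NA_real_, M, A)
  qaly_m <- matrix(NA_real_, M, A)
  events_m <- matrix(NA_real_, M, A)
  rate_m <- matrix(NA_real_, M, A)
  theta_v <- numeric(M)
  raw_w <- numeric(M)
  rep_idx <- integer(M)

  bay <- bootstrap == "bayesian"
  k <- 0L
  i <- 0L
  n_invalid <- 0L
  repeat {
    i <- i + 1L
    if (method == "rejection" && i > max_attempts)
      stop(structure(class = c("ceaboot_conflict_error", "error", "condition"),
                     list(message = sprintf(
        paste0("[synthesis] rejection sampler exhausted max_attempts = %d with ",
               "%d/%d acceptances (running acceptance rate %.4f); the external ",
               "evidence and the trial data are likely in conflict"),
        max_attempts, k, M, k / (i - 1)), call = NULL)))
    set.seed(replicate_seed(seed, i))

    mc <- numeric(A); mq <- numeric(A); me <- numeric(A); mr <- numeric(A)
    for (j in seq_len(A)) {
      p <- per[[j]]
      w <- if (bay) { e <- rexp(p$n); e / sum(e) }
           else tabulate(sample.int(p$n, p$n, replace = TRUE), nbins = p$n) / p$n
      cost <- p$cost; qaly <- p$qaly; ev <- p$events
      if (any_missing) {
        if (p$miss[["cost"]]) cost <- .impute_vec(cost, w, impute_method)
        if (p$miss[["qaly"]]) qaly <- .impute_vec(qaly, w, impute_method)
        if (p$miss[["events"]])
          ev <- .impute_vec(ev, w, impute_method, integer_valued = TRUE)
      }
      mc[j] <- sum(w * cost)
      mq[j] <- sum(w * qaly)
      me[j] <- sum(w * ev)
      mr[j] <- me[j] / sum(w * p$followup)
    }

    valid <- me[itrt] > 0 && me[iref] > 0
    if (valid) {
      th <- log(mr[itrt] / mr[iref])
      rw <- switch(ev_type,
                   flat = 1,
                   normal = exp(-(th - ev_mu)^2 / ev_2s2),
                   custom = min(max(ev_fn(th), 0), 1))
    } else {
      n_invalid <- n_invalid + 1L
      th <- NA_real_
      rw <- 0
    }

    if (method == "rejection") {
      u <- runif(1)
      if (u > rw) next
    }
    k <- k + 1L
    cost_m[k, ] <- mc; qaly_m[k, ] <- mq; events_m[k, ] <- me; rate_m[k, ] <- mr
    theta_v[k] <- th; raw_w[k] <- rw; rep_idx[k] <- i
    if (k == M) break
  }

  draws <- data.frame(replicate = rep_idx)
  for (j in seq_len(A)) {
    draws[[paste0("cost_", a[j])]] <- cost_m[, j]
    draws[[paste0("qaly_", a[j])]] <- qaly_m[, j]
    draws[[paste0("events_", a[j])]] <- events_m[, j]
    draws[[paste0("rate_", a[j])]] <- rate_m[, j]
  }
  draws$theta_e <- theta_v
  draws$raw_weight <- raw_w

  if (method == "importance") {
    s <- sum(raw_w)
    if (s <= 0)
      .stop_mod("synthesis",
                "degenerate importance sample: all raw weights are zero")
    nw <- raw_w / s
    ess <- s^2 / sum(raw_w^2)
  } else {
    nw <- rep(1 / M, M)
    ess <- NA_real_
  }

  structure(list(
    draws = draws,
    arms = a,
    comparison = comparison,
    scheme = method,
    bootstrap = bootstrap,
    normalized_weights = nw,
    attempts = i,
    acceptance_rate = if (method == "rejection") M / i else NA_real_,
    effective_sample_size = ess,
    n_invalid_theta = n_invalid,
    M = M,
    seed = seed,
    evidence = evidence,
    impute_method = if (any_missing) impute_method else NA_character_
  ), class = "posterior_sample")
}

#' Plain bootstrap posterior sample (no external evidence)
#'
#' Draws `M` within-arm bootstrap replicates and stores the arm-level
#' parameters of each: a sample from the no-evidence posterior
#' `P(theta | D)`. This is the standard bootstrap CEA.
#'
#' @param data a [trial_data()] object (missing values are imputed within
#'   each replicate).
#' @param M number of draws (>= 1).
#' @param bootstrap `"bayesian"` (Dirichlet weights) or `"ordinary"`
#'   (resampling with replacement).
#' @param comparison `c(reference, treatment)` arm labels.
#' @param seed master seed; every replicate runs in the substream
#'   [replicate_seed()]`(seed, i)`.
#' @param impute_method passed to [impute_within_replicate()].
#' @return a `posterior_sample` object; see [rejection_sample()].
#' @export
bootstrap_sample <- function(data, M, bootstrap = c("bayesian", "ordinary"),
                             comparison, seed = 1,
                             impute_method = "weighted_arm_mean") {
  bootstrap <- match.arg(bootstrap)
  .sample_engine(data, flat_evidence(), M, "none", bootstrap, comparison,
                 seed, Inf, impute_method)
}

#' Rejection sampling against external evidence
#'
#' Runs the bootstrap replicate stream and accepts each replicate with
#' probability equal to its scaled evidence weight
#' `P* = P(D_e | theta_e*)`: draw `u ~ U(0,1)` and keep the replicate iff
#' `u <= P*`. Sampling continues until `M` replicates are accepted, so the
#' result is an unweighted sample of size `M` from
#' `P(theta | D, D_e)`. Replicates whose `theta_e` is undefined (a zero
#' weighted event total in either comparison arm) are always rejected.
#'
#' If `max_attempts` is exhausted first, an error of class
#' `ceaboot_conflict_error` reports the running acceptance rate: a very low
#' rate is the operational signature of prior-data conflict.
#'
#' @inheritParams bootstrap_sample
#' @param evidence an `external_evidence` object ([pool_evidence()],
#'   [normal_evidence()], [flat_evidence()], [custom_evidence()]).
#' @param max_attempts attempt budget before declaring conflict
#'   (default `100 * M`).
#' @return a `posterior_sample`: draws table (one row per retained
#'   replicate with per-arm means, `theta_e`, weight), uniform normalized
#'   weights, `attempts`, `acceptance_rate` and diagnostics.
#' @export
rejection_sample <- function(data, evidence, M,
                             bootstrap = c("bayesian", "ordinary"),
                             comparison, seed = 1, max_attempts = 100 * M,
                             impute_method = "weighted_arm_mean") {
  bootstrap <- match.arg(bootstrap)
  .sample_engine(data, evidence, M, "rejection", bootstrap, comparison,
                 seed, max_attempts, impute_method)
}

#' Importance sampling against external evidence
#'
#' Runs exactly `M` bootstrap replicates, keeps all of them, and attaches
#' the raw weight `P(D_e | theta_e*)` to each; normalized weights are the
#' raw weights divided by their sum, and all downstream summaries are
#' weighted. Replicates with undefined `theta_e` get weight 0. On a shared
#' master seed the replicate stream is identical to the rejection
#' sampler's attempt stream, enabling common-random-number comparisons.
#'
#' @inheritParams rejection_sample
#' @return a `posterior_sample` with `normalized_weights`, raw weights in
#'   the draws table, and `effective_sample_size = (sum w)^2 / sum(w^2)`.
#' @export
importance_sample <- function(data, evidence, M,
                              bootstrap = c("bayesian", "ordinary"),
                              comparison, seed = 1,
                              impute_method = "weighted_arm_mean") {
  bootstrap <- match.arg(bootstrap)
  .sample_engine(data, evidence, M, "importance", bootstrap, comparison,
                 seed, Inf, impute_method)
}

#' @export
print.posterior_sample <- function(x, ...) {
  cat(sprintf("posterior_sample: %d draws, scheme = %s, bootstrap = %s\n",
              x$M, x$scheme, x$bootstrap))
  cat(sprintf("comparison: %s vs %s\n", x$comparison[2], x$comparison[1]))
  if (x$scheme == "rejection")
    cat(sprintf("attempts = %d, acceptance rate = %.4f\n",
                x$attempts, x$acceptance_rate))
  if (x$scheme == "importance")
    cat(sprintf("effective sample size = %.1f (of %d)\n",
                x$effective_sample_size, x$M))
  if (x$n_invalid_theta > 0)
    cat(sprintf("replicates with undefined theta_e: %d\n", x$n_invalid_theta))
  invisible(x)
}
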