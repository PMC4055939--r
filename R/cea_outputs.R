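# CEA summaries of a posterior sample: weighted arm means and SDs,
# incremental cost and effectiveness, the ICER as a ratio of weighted
# means, weighted-percentile credible intervals, the cost-effectiveness
# plane export, and the CEAC.

#' Weighted percentile (inverse weighted empirical CDF)
#'
#' Returns the smallest value at which the weighted empirical CDF reaches
#' `q` (a step-CDF inverse, the weighted analogue of `quantile(type = 1)`).
#' With uniform weights and odd `n`, `q = 0.5` returns the middle order
#' statistic.
#'
#' @param values numeric vector.
#' @param weights non-negative weights, normalized internally.
#' @param q quantile(s) in `[0, 1]`.
#' @return numeric vector, one entry per `q`.
#' @examples
#' weighted_percentile(c(1, 2, 3), rep(1/3, 3), 0.5)  # 2
#' weighted_percentile(c(0, 10), c(0.9, 0.1), 0.5)    # 0
#' @export
weighted_percentile <- function(values, weights, q) {
  if (!length(values))
    .stop_mod("cea_outputs", "empty input to weighted_percentile")
  stopifnot(length(values) == length(weights), all(weights >= 0),
            sum(weights) > 0, all(q >= 0 & q <= 1))
  o <- order(values)
  v <- values[o]
  cw <- cumsum(weights[o]) / sum(weights)
  vapply(q, function(p) v[which(cw >= p - 1e-12)[1]], numeric(1))
}

#' Summarize a posterior sample as a CEA result
#'
#' Computes normalized-weight means and SDs of per-arm cost and
#' effectiveness, the incremental cost `dC` and effectiveness `dE`
#' (treatment minus reference), weighted-percentile credible intervals,
#' and the ICER as the ratio of the weighted mean `dC` over the weighted
#' mean `dE` (ratio of means -- per-draw ICERs are never averaged). If the
#' weighted mean `dE` is zero the ICER is undefined and reported as `NA`
#' with both numerator and denominator.
#'
#' @param sample a `posterior_sample` from one of the sampling engines.
#' @param level credible level in (0, 1); default 0.95.
#' @return a `cea_result` object.
#' @export
cea_summary <- function(sample, level = 0.95) {
  stopifnot(inherits(sample, "posterior_sample"), level > 0, level < 1)
  d <- sample$draws
  w <- sample$normalized_weights
  if (sample$scheme == "importance" && sample$effective_sample_size <= 1)
    .stop_mod("cea_outputs", "effective sample size <= 1; sample degenerate")
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  arm_tab <- do.call(rbind, lapply(sample$arms, function(g) {
    cost <- d[[paste0("cost_", g)]]
    qaly <- d[[paste0("qaly_", g)]]
    ev <- d[[paste0("events_", g)]]
    data.frame(arm = g,
               cost_mean = .wmean(cost, w), cost_sd = .wsd(cost, w),
               qaly_mean = .wmean(qaly, w), qaly_sd = .wsd(qaly, w),
               events_mean = .wmean(ev, w))
  }))
  ref <- sample$comparison[1]; trt <- sample$comparison[2]
  dC <- d[[paste0("cost_", trt)]] - d[[paste0("cost_", ref)]]
  dE <- d[[paste0("qaly_", trt)]] - d[[paste0("qaly_", ref)]]
  ci_dC <- weighted_percentile(dC, w, qs)
  ci_dE <- weighted_percentile(dE, w, qs)
  mdC <- .wmean(dC, w)
  mdE <- .wmean(dE, w)
  icer <- if (mdE == 0) NA_real_ else mdC / mdE
  structure(list(
    arms = arm_tab,
    delta = data.frame(quantity = c("cost", "qaly"),
                       mean = c(mdC, mdE),
                       sd = c(.wsd(dC, w), .wsd(dE, w)),
                       lower = c(ci_dC[1], ci_dE[1]),
                       upper = c(ci_dC[2], ci_dE[2])),
    icer = list(estimate = icer, delta_cost = mdC, delta_qaly = mdE,
                defined = mdE != 0),
    level = level,
    interval_method = "weighted_percentile",
    comparison = sample$comparison,
    scheme = sample$scheme,
    bootstrap = sample$bootstrap,
    diagnostics = list(attempts = sample$attempts,
                       acceptance_rate = sample$acceptance_rate,
                       effective_sample_size = sample$effective_sample_size,
                       n_invalid_theta = sample$n_invalid_theta)
  ), class = "cea_result")
}

#' @export
summary.posterior_sample <- function(object, level = 0.95, ...) {
  cea_summary(object, level = level)
}

#' @export
print.cea_result <- function(x, ...) {
  cat(sprintf("CEA summary (%s bootstrap, scheme = %s), %s vs %s\n",
              x$bootstrap, x$scheme, x$comparison[2], x$comparison[1]))
  at <- x$arms
  for (i in seq_len(nrow(at)))
    cat(sprintf("  %-4s cost %8.0f (%.0f)   QALY %.4f (%.4f)\n",
                at$arm[i], at$cost_mean[i], at$cost_sd[i],
                at$qaly_mean[i], at$qaly_sd[i]))
  dl <- x$delta
  cat(sprintf("  dC = %.0f (%.0f) [%0.f, %.0f]   dE = %.4f (%.4f) [%.4f, %.4f]\n",
              dl$mean[1], dl$sd[1], dl$lower[1], dl$upper[1],
              dl$mean[2], dl$sd[2], dl$lower[2], dl$upper[2]))
  if (x$icer$defined)
    cat(sprintf("  ICER = %.0f per QALY\n", x$icer$estimate))
  else
    cat(sprintf("  ICER undefined (dC = %.2f, dE = 0)\n", x$icer$delta_cost))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value `lambda`, the weighted probability
#' that the treatment is cost-effective versus the reference: the
#' normalized-weight mass of draws with positive net monetary benefit
#' `lambda * dE - dC > 0`. At `lambda = 0` this is the weighted
#' `P(dC < 0)`; for large `lambda` it converges to the weighted
#' `P(dE > 0)`.
#'
#' @inheritParams cea_summary
#' @param lambda_grid non-negative willingness-to-pay grid (currency per
#'   QALY). The default spans 0 to 500,000 in steps of 5,000.
#' @return a `ceac_curve` data frame with columns `lambda`, `probability`.
#' @export
ceac <- function(sample, lambda_grid = seq(0, 500000, by = 5000)) {
  stopifnot(inherits(sample, "posterior_sample"))
  if (any(lambda_grid < 0))
    .stop_mod("cea_outputs", "lambda grid must be non-negative")
  d <- sample$draws
  w <- sample$normalized_weights
  ref <- sample$comparison[1]; trt <- sample$comparison[2]
  dC <- d[[paste0("cost_", trt)]] - d[[paste0("cost_", ref)]]
  dE <- d[[paste0("qaly_", trt)]] - d[[paste0("qaly_", ref)]]
  prob <- vapply(lambda_grid, function(l) sum(w[l * dE - dC > 0]), numeric(1))
  structure(data.frame(lambda = lambda_grid, probability = prob),
            comparison = sample$comparison,
            class = c("ceac_curve", "data.frame"))
}

#' Willingness-to-pay at which a CEAC crosses a probability threshold
#'
#' The smallest grid `lambda` whose acceptability probability reaches
#' `threshold`, or `NA` if the curve never does within the grid.
#'
#' @param curve a `ceac_curve` from [ceac()].
#' @param threshold probability threshold, default 0.5.
#' @export
ceac_crossing <- function(curve, threshold = 0.5) {
  stopifnot(inherits(curve, "ceac_curve"))
  hit <- which(curve$probability >= threshold)
  if (!length(hit)) NA_real_ else curve$lambda[hit[1]]
}

#' Export the cost-effectiveness plane
#'
#' Writes one row per retained draw with the incremental effectiveness
#' `dE`, incremental cost `dC`, and normalized weight -- the standard
#' scatter for the cost-effectiveness plane. Re-importing the table
#' reproduces the weighted incremental summaries exactly.
#'
#' @inheritParams cea_summary
#' @param path output CSV path.
#' @return invisibly, the exported data frame.
#' @export
export_plane <- function(sample, path) {
  stopifnot(inherits(sample, "posterior_sample"))
  d <- sample$draws
  ref <- sample$comparison[1]; trt <- sample$comparison[2]
  out <- data.frame(
    dE = d[[paste0("qaly_", trt)]] - d[[paste0("qaly_", ref)]],
    dC = d[[paste0("cost_", trt)]] - d[[paste0("cost_", ref)]],
    weight = sample$normalized_weights)
  write.csv(out, path, row.names = FALSE)
  invisible(out)
}
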