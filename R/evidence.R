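# External evidence as a scaled weight function on the log-effect scale.
#
# Evidence reported as a ratio estimate with a 95% CI is converted to a
# normal likelihood on the log scale; an optional between-study variance
# widens it to acknowledge transferability limits. The weight function is
# the normal kernel scaled to a maximum of exactly 1 (the rejection
# sampler requires weights that are valid probabilities), so it is bounded
# and continuous -- the regularity conditions the samplers need.

#' Pool a reported ratio estimate into an external-evidence likelihood
#'
#' Converts a published ratio-scale effect estimate (rate ratio, risk
#' ratio, ...) with its 95% CI into a normal likelihood on the log scale:
#' `mu = log(point)`, within-study `SE` recovered from the CI, and
#' `sigma = sqrt(SE^2 + between_study_variance)`.
#'
#' Two CI-to-SE conventions are available. `"upper"` (default) uses the
#' upper half-width, `(log(ci_high) - log(point)) / 1.959964`; `"symmetric"`
#' uses the full width, `(log(ci_high) - log(ci_low)) / (2 * 1.959964)`.
#' For a CI that is exactly symmetric on the log scale the two agree.
#'
#' @param point ratio-scale point estimate (> 0).
#' @param ci_low,ci_high 95% confidence bounds, `0 < ci_low < point < ci_high`.
#' @param between_study_variance heterogeneity variance tau^2 (>= 0) added
#'   to the within-study variance when transferring evidence across
#'   settings; default 0.
#' @param ci_convention `"upper"` or `"symmetric"` (see Details).
#' @param parameter label of the evidence parameter, e.g. `"log_RR_T3_vs_T1"`.
#' @return an `external_evidence` object with fields `mu`, `sigma` and a
#'   `provenance` record of all inputs.
#' @examples
#' ev <- pool_evidence(0.38, 0.25, 0.57, between_study_variance = 0.01783)
#' c(ev$mu, ev$sigma)  # -0.968, 0.246
#' @export
pool_evidence <- function(point, ci_low, ci_high, between_study_variance = 0,
                          ci_convention = c("upper", "symmetric"),
                          parameter = "log_RR") {
  ci_convention <- match.arg(ci_convention)
  if (!(point > 0 && ci_low > 0 && ci_high > 0))
    .stop_mod("evidence", "point and CI bounds must be positive")
  if (!(ci_low < point && point < ci_high))
    .stop_mod("evidence", "need ci_low < point < ci_high, got (%g, %g, %g)",
              ci_low, point, ci_high)
  if (between_study_variance < 0)
    .stop_mod("evidence", "between_study_variance must be >= 0")
  z975 <- 1.959964
  se <- switch(ci_convention,
               upper = (log(ci_high) - log(point)) / z975,
               symmetric = (log(ci_high) - log(ci_low)) / (2 * z975))
  new_evidence(
    type = "normal",
    mu = log(point),
    sigma = sqrt(se^2 + between_study_variance),
    parameter = parameter,
    provenance = list(point = point, ci_low = ci_low, ci_high = ci_high,
                      between_study_variance = between_study_variance,
                      ci_convention = ci_convention, within_study_se = se))
}

#' Construct an external-evidence object directly
#'
#' Lower-level constructor for a normal-on-log-scale likelihood with known
#' `mu` and `sigma`. Most users should call [pool_evidence()].
#'
#' @param mu mean on the log-effect scale.
#' @param sigma standard deviation on the log-effect scale (> 0).
#' @inheritParams pool_evidence
#' @export
normal_evidence <- function(mu, sigma, parameter = "log_RR") {
  if (!is.finite(mu)) .stop_mod("evidence", "mu must be finite")
  if (!is.finite(sigma) || sigma <= 0)
    .stop_mod("evidence", "sigma must be a positive finite number")
  new_evidence(type = "normal", mu = mu, sigma = sigma, parameter = parameter,
               provenance = list(direct = TRUE))
}

#' Flat (non-informative) evidence
#'
#' Weight identically 1 for every parameter value: the limit case in which
#' the evidence-weighted posterior reduces to the plain bootstrap
#' posterior. Under flat evidence the rejection sampler accepts every
#' replicate and the importance sampler assigns uniform weights.
#'
#' @inheritParams pool_evidence
#' @export
flat_evidence <- function(parameter = "log_RR") {
  new_evidence(type = "flat", mu = NA_real_, sigma = NA_real_,
               parameter = parameter, provenance = list(flat = TRUE))
}

#' User-supplied evidence weight function
#'
#' Extension point for evidence that is not normal on the log scale. The
#' function must be a bounded, continuous weight in (0, 1] (the scaled
#' likelihood); at registration it is probed on a coarse grid over
#' `support` and rejected if any value falls outside [0, 1]. Mixed-type
#' ("lump-and-smear") priors, which put point mass on a null value and
#' hence have unbounded density, cannot be expressed as such a weight
#' function and are unsupported by design.
#'
#' @param weight_fn vectorized function mapping the evidence parameter to a
#'   weight in `[0, 1]` with supremum 1.
#' @param support numeric length-2 range over which the function is probed.
#' @inheritParams pool_evidence
#' @export
custom_evidence <- function(weight_fn, support, parameter = "custom") {
  stopifnot(is.function(weight_fn), is.numeric(support), length(support) == 2,
            support[1] < support[2])
  grid <- seq(support[1], support[2], length.out = 501)
  v <- weight_fn(grid)
  if (any(!is.finite(v)) || any(v < 0) || any(v > 1 + 1e-12))
    .stop_mod("evidence",
              "weight_fn must map the support into [0, 1]; scale the likelihood by its maximum")
  new_evidence(type = "custom", mu = NA_real_, sigma = NA_real_,
               parameter = parameter,
               provenance = list(support = support), weight_fn = weight_fn)
}

new_evidence <- function(type, mu, sigma, parameter, provenance,
                         weight_fn = NULL) {
  structure(list(type = type, mu = mu, sigma = sigma, parameter = parameter,
                 provenance = provenance, weight_fn = weight_fn),
            class = "external_evidence")
}

#' Evaluate the scaled external likelihood
#'
#' Returns the evidence weight `P(D_e | theta_e)` scaled so that its
#' maximum over theta is exactly 1. For normal evidence this is
#' `exp(-(theta - mu)^2 / (2 sigma^2))`; for flat evidence it is 1.
#'
#' @param theta_e evidence-parameter value(s), finite.
#' @param evidence an `external_evidence` object.
#' @return weights in `(0, 1]`, same length as `theta_e`.
#' @examples
#' ev <- pool_evidence(0.38, 0.25, 0.57, 0.01783)
#' evidence_weight(ev$mu, ev)            # 1
#' evidence_weight(ev$mu + ev$sigma, ev) # exp(-0.5)
#' @export
evidence_weight <- function(theta_e, evidence) {
  stopifnot(inherits(evidence, "external_evidence"))
  if (any(!is.finite(theta_e)))
    .stop_mod("evidence", "theta_e must be finite")
  switch(evidence$type,
         flat = rep(1, length(theta_e)),
         normal = exp(-(theta_e - evidence$mu)^2 / (2 * evidence$sigma^2)),
         custom = {
           v <- evidence$weight_fn(theta_e)
           pmin(pmax(v, 0), 1)
         })
}

#' @export
print.external_evidence <- function(x, ...) {
  if (x$type == "normal")
    cat(sprintf("external evidence on %s: Normal(mu = %.4f, sigma = %.4f)\n",
                x$parameter, x$mu, x$sigma))
  else
    cat(sprintf("external evidence on %s: %s\n", x$parameter, x$type))
  invisible(x)
}
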