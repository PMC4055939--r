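# Per-arm bootstrap probability vectors: Bayesian (Dirichlet) or ordinary
# (scaled multinomial). One BootstrapWeights object defines one replicate.

#' Bayesian-bootstrap weights for one arm
#'
#' Draws a probability vector of length `n` from Dirichlet(1, ..., 1),
#' realized as normalized unit-rate exponentials. Under the Bayesian
#' bootstrap the distribution putting mass `p_i` on patient `i` is a draw
#' from the posterior of the arm's data-generating distribution.
#'
#' @param n arm size (>= 1).
#' @return numeric vector of length `n`, non-negative, summing to 1.
#' @export
draw_bayesian_weights <- function(n) {
  if (!is.numeric(n) || length(n) != 1 || n < 1)
    .stop_mod("resampling", "arm size n must be >= 1")
  e <- rexp(n)
  e / sum(e)
}

#' Ordinary-bootstrap weights for one arm
#'
#' Resamples `n` patients with replacement and returns the scaled
#' multinomial counts: each entry is an integer multiple of `1/n`. This is
#' the classical bootstrap expressed as a probability vector, and an
#' approximation to the Bayesian bootstrap.
#'
#' @inheritParams draw_bayesian_weights
#' @return numeric vector of length `n` with entries in `{0, 1/n, ..., 1}`
#'   summing to 1.
#' @export
draw_ordinary_weights <- function(n) {
  if (!is.numeric(n) || length(n) != 1 || n < 1)
    .stop_mod("resampling", "arm size n must be >= 1")
  n <- as.integer(n)
  tabulate(sample.int(n, n, replace = TRUE), nbins = n) / n
}

#' One bootstrap replicate of a trial
#'
#' Draws an independent probability vector for every arm (bootstrapping is
#' performed within arms), all under the same scheme. Seed the RNG before
#' calling for reproducibility; the sampling engines do this per replicate
#' via [replicate_seed()].
#'
#' @param data a [trial_data()] object.
#' @param scheme `"bayesian"` (Dirichlet) or `"ordinary"` (scaled
#'   multinomial).
#' @return a `bootstrap_weights` object: a named list (one probability
#'   vector per arm, in arm order) with a `scheme` attribute.
#' @examples
#' d <- generate_trial(synth_trial_spec(arm_sizes = c(5, 5, 5)), seed = 1)
#' set.seed(1); w <- draw_replicate(d, "bayesian")
#' sapply(w, sum)
#' @export
draw_replicate <- function(data, scheme = c("bayesian", "ordinary")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(data, "trial_data"))
  sizes <- vapply(arms(data), function(g) sum(data$arm == g), 1L)
  fn <- if (scheme == "bayesian") draw_bayesian_weights else draw_ordinary_weights
  w <- lapply(sizes, fn)
  structure(w, scheme = scheme, class = "bootstrap_weights")
}

#' @export
print.bootstrap_weights <- function(x, ...) {
  cat(sprintf("bootstrap_weights (%s): %s\n", attr(x, "scheme"),
              paste(sprintf("%s[%d]", names(x), lengths(x)), collapse = " ")))
  invisible(x)
}
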