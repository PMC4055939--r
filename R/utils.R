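# Shared internal helpers: replicate RNG substreams and weighted moments.

#' Deterministic per-replicate seed
#'
#' Derives the seed of the RNG substream used for bootstrap replicate
#' `index` under master seed `seed`. Every sampling engine in the package
#' re-seeds the RNG with this value at the top of each replicate, so a
#' rejection run and an importance run sharing a master seed see the
#' *identical* sequence of bootstrap replicates (common random numbers),
#' and any single replicate can be reconstructed after the fact.
#'
#' The map is a stateless integer hash of `(seed, index)` with all
#' intermediate products below 2^53 (exact in doubles) and a result in
#' `[1, 2^31 - 2]`, valid for [set.seed()].
#'
#' @param seed master seed, a non-negative integer below 2^31.
#' @param index replicate (attempt) index, positive integer.
#' @return an integer seed.
#' @examples
#' replicate_seed(1, 1:3)
#' @export
replicate_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1, seed >= 0, seed < 2^31,
            is.numeric(index), all(index >= 1))
  lo <- seed %% 65536
  hi <- seed %/% 65536
  s <- (lo * 40503 + hi * 30269 + index * 69069 + 12345) %% 2147483646
  as.integer(s + 1)
}

# weighted mean with normalized or unnormalized weights
.wmean <- function(x, w) sum(w * x) / sum(w)

# weighted SD with normalized weights (population-style; the Monte-Carlo
# spread of the draw cloud, not a small-sample-corrected estimator)
.wsd <- function(x, w) {
  w <- w / sum(w)
  m <- sum(w * x)
  sqrt(sum(w * (x - m)^2))
}

# Monte-Carlo standard error of a weighted (self-normalized importance
# sampling) mean estimate; reduces to sd/sqrt(M) for uniform weights.
.wmean_mcse <- function(x, w) {
  w <- w / sum(w)
  m <- sum(w * x)
  sqrt(sum(w^2 * (x - m)^2))
}

.stop_mod <- function(module, fmt, ...) {
  stop(sprintf("[%s] %s", module, sprintf(fmt, ...)), call. = FALSE)
}
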