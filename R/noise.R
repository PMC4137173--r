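#' Draw a per-trial noise series
#'
#' Sources of the stochastic value x that perturbs the activation slopes:
#' `"gaussian"` draws standard-normal values; `"rectangular"` draws uniform
#' values on \eqn{[-\sqrt 3, \sqrt 3]} (zero mean, unit variance, so the two
#' random sources are comparable); `"rp"` noise is not sampled here — it
#' comes from rescaled single-trial RP amplitudes via [rescale_noise()].
#'
#' @param source `"gaussian"` or `"rectangular"`.
#' @param n number of values.
#' @return Numeric vector of length `n` with attribute `source`.
#' @examples
#' set.seed(1); sample_noise("rectangular", 5)
#' @export
sample_noise <- function(source = c("gaussian", "rectangular"), n) {
  source <- match.arg(source)
  x <- switch(source,
              gaussian = rnorm(n),
              rectangular = runif(n, -sqrt(3), sqrt(3)))
  attr(x, "source") <- source
  x
}

# Match a noise pool to n trials: subsample without replacement when the pool
# is larger, resample with replacement (with a message) when smaller.
select_noise <- function(pool, n) {
  if (length(pool) == n) return(as.numeric(pool))
  if (length(pool) > n) {
    as.numeric(pool[sample.int(length(pool), n)])
  } else {
    message(sprintf("noise pool (%d) smaller than trial count (%d): %s",
                    length(pool), n, "resampling with replacement"))
    as.numeric(pool[sample.int(length(pool), n, replace = TRUE)])
  }
}

#' Rank-pair noise values to observed reaction times
#'
#' Within a participant-condition cell the noise values are paired to trials
#' by rank: the smallest value becomes x on the trial with the shortest RT,
#' the second smallest on the second shortest, and so on.  Ties in RT keep
#' the original trial order (stable sort), so the assignment is
#' deterministic.  The direction of the pairing is fixed; the sign of the
#' swell parameters is free during estimation, which resolves whether small
#' x speeds or slows a trial.
#'
#' @param noise numeric vector, same length as `rt`.
#' @param rt observed RTs (ms).
#' @return Numeric vector: the noise value assigned to each trial, in the
#'   original trial order.
#' @examples
#' assign_noise(c(-1, 0, 1), c(500, 400, 600))  # 0, -1, 1
#' @export
assign_noise <- function(noise, rt) {
  stopifnot(length(noise) == length(rt), all(is.finite(noise)),
            all(is.finite(rt)))
  ord <- order(rt)                        # stable: ties by original order
  out <- numeric(length(rt))
  out[ord] <- sort(as.numeric(noise))
  out
}
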