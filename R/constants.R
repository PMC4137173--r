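#' Fixed constants of the tectonic accumulation model
#'
#' All simulations share a small set of structural constants: the exponent of
#' the inverse-logistic activation function, the additive constant that keeps
#' the evidence log-ratio within the range of the stopping rule, the
#' multiplicative scale that maps the slope logistic onto activation slopes
#' (per ms), the decision threshold \eqn{\beta}, the asymptotic activation
#' bounds of the three activation classes, and the maximum number of
#' accumulation cycles (1 cycle = 1 ms) before a crossing search is abandoned.
#'
#' The defaults are the values used throughout: exponent 10, evidence constant
#' 6.0, slope scale 0.023, \eqn{\beta = 1}, bounds +1 (presented target),
#' -1 (remembered targets), -3 (distractors, a single pooled slope).
#'
#' Two structural invariants are enforced at construction: the evidence
#' denominator must stay positive when every activation sits at its bound
#' (`evidence_constant > |distractor_bound| + 2 |nontarget_bound|`), and the
#' threshold must be reachable
#' (`threshold_beta < log((target_bound + c) / (c + 2 nontarget_bound +
#' distractor_bound))`, the evidence supremum, log 7 at the defaults).
#'
#' @param asymptote_exponent positive integer exponent of the activation
#'   logistic.
#' @param evidence_constant additive constant in numerator and denominator of
#'   the evidence ratio.
#' @param slope_scale upper bound of the activation slope (ms^-1); the slope
#'   logistic is multiplied by this value.
#' @param threshold_beta decision threshold on the weight of evidence.
#' @param target_bound,nontarget_bound,distractor_bound asymptotic activation
#'   bounds.
#' @param max_cycles maximum accumulation time searched for a threshold
#'   crossing, in ms.
#' @return An object of class `"tam_constants"` (a validated list).
#' @examples
#' k <- tam_constants()
#' k$evidence_constant
#' @export
tam_constants <- function(asymptote_exponent = 10L,
                          evidence_constant = 6.0,
                          slope_scale = 0.023,
                          threshold_beta = 1.0,
                          target_bound = 1,
                          nontarget_bound = -1,
                          distractor_bound = -3,
                          max_cycles = 5000L) {
  k <- list(asymptote_exponent = as.integer(asymptote_exponent),
            evidence_constant = evidence_constant,
            slope_scale = slope_scale,
            threshold_beta = threshold_beta,
            target_bound = target_bound,
            nontarget_bound = nontarget_bound,
            distractor_bound = distractor_bound,
            max_cycles = as.integer(max_cycles))
  stopifnot(k$asymptote_exponent >= 1L, k$max_cycles >= 1L,
            is.finite(k$evidence_constant), is.finite(k$slope_scale),
            k$slope_scale > 0)
  if (k$evidence_constant <= abs(k$distractor_bound) + 2 * abs(k$nontarget_bound))
    stop("evidence constant too small: denominator of the evidence ratio ",
         "would reach zero at asymptote")
  sup <- log((k$target_bound + k$evidence_constant) /
               (k$evidence_constant + 2 * k$nontarget_bound + k$distractor_bound))
  if (k$threshold_beta >= sup)
    stop(sprintf("threshold beta = %g is not reachable: evidence supremum is %g",
                 k$threshold_beta, sup))
  structure(k, class = "tam_constants", evidence_sup = sup)
}

#' @export
print.tam_constants <- function(x, ...) {
  cat("Tectonic model constants\n")
  cat(sprintf("  activation exponent %d, evidence constant %.1f, slope scale %.3f\n",
              x$asymptote_exponent, x$evidence_constant, x$slope_scale))
  cat(sprintf("  threshold beta %.2f (evidence supremum %.5f)\n",
              x$threshold_beta, attr(x, "evidence_sup")))
  cat(sprintf("  bounds: target %+g, non-target %+g, distractor %+g; max %d cycles\n",
              x$target_bound, x$nontarget_bound, x$distractor_bound, x$max_cycles))
  invisible(x)
}
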