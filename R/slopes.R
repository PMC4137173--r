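#' Trial-level activation slopes from start/swell parameters
#'
#' On trial j the four activation slopes are logistic transforms of a
#' baseline level ("start") plus a noise sensitivity ("swell") times the
#' trial's stochastic value x, scaled to the admissible slope range:
#' \deqn{slope_{T_i}[j] = logistic(tstart_{T_i} + tswell \cdot x_j)\cdot 0.023}
#' \deqn{slope_d[j]     = logistic(dstart + dswell \cdot x_j)\cdot 0.023}
#' One shared x drives all four slopes of a trial.  Start parameters reflect
#' the long-term-memory component of activation, swell parameters the
#' coupling of trial-to-trial (short-term) fluctuation into slope.
#'
#' @param tstart,dstart start parameter (logistic argument, unbounded).
#' @param tswell,dswell swell parameter (unbounded; sign free, resolved by
#'   the rank pairing of noise to RTs during estimation).
#' @param x per-trial noise value(s).
#' @param scale multiplicative slope scale (default 0.023 ms^-1).
#' @return Slope value(s) strictly inside (0, scale), ms^-1.
#' @examples
#' target_slope(0, 1, 0)        # 0.5 * 0.023 = 0.0115
#' target_slope(1, 2, 0.5)      # logistic(2) * 0.023
#' @export
target_slope <- function(tstart, tswell, x, scale = 0.023) {
  stopifnot(is.finite(tstart), is.finite(tswell), all(is.finite(x)))
  plogis(tstart + tswell * x) * scale
}

#' @rdname target_slope
#' @export
distractor_slope <- function(dstart, dswell, x, scale = 0.023) {
  stopifnot(is.finite(dstart), is.finite(dswell), all(is.finite(x)))
  plogis(dstart + dswell * x) * scale
}

# Parameter vector layout used throughout estimation:
#   c(tstart_1, tstart_2, tstart_3, tswell, dstart, dswell)
PAR_NAMES <- c("tstart_1", "tstart_2", "tstart_3", "tswell", "dstart", "dswell")

# n x 4 slope matrix (slope_t1..3, slope_d) for n trials with noise x.
trial_slopes <- function(par, x, scale = 0.023) {
  st <- vapply(1:3, function(i) target_slope(par[i], par[4L], x, scale),
               numeric(length(x)))
  if (length(x) == 1L) st <- matrix(st, nrow = 1L)
  sd_ <- distractor_slope(par[5L], par[6L], x, scale)
  cbind(st, slope_d = sd_)
}
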