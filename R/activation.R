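#' Activation functions of the tectonic model
#'
#' Presentation of a target simultaneously triggers excitation of its own
#' representation and inhibition of every other stimulus representation held
#' in memory.  All three activation classes share one functional form, an
#' inverse logistic raised to a fixed exponent:
#' `act_target()` grows from (1/2)^k toward +1; `act_nontarget()` is its
#' negation, decaying toward -1 for each remembered, currently non-presented
#' target; `act_distractor()` decays toward -3, a single pooled inhibitory
#' trace for the whole distractor set.
#'
#' All three are vectorised over `t` (and over `slope` when lengths match).
#'
#' @param slope activation slope (ms^-1), non-negative.
#' @param t time since target onset, in ms (cycles), non-negative.
#' @param exponent the asymptote exponent (default 10).
#' @return Activation values: in (0, 1] for targets, [-1, 0) for non-presented
#'   targets, [-3, 0) for distractors.
#' @examples
#' act_target(0.01, 500)        # ~0.935
#' act_nontarget(0.01, 500)     # ~-0.935
#' act_distractor(0.01, 500)    # ~-2.805
#' @export
act_target <- function(slope, t, exponent = 10L) {
  if (!all(is.finite(slope)) || !all(is.finite(t)))
    stop("non-finite slope or time")
  if (any(slope < 0) || any(t < 0))
    stop("slope and t must be non-negative")
  plogis(slope * t)^exponent
}

#' @rdname act_target
#' @export
act_nontarget <- function(slope, t, exponent = 10L) {
  -act_target(slope, t, exponent)
}

#' @rdname act_target
#' @param bound asymptotic inhibitory bound of the pooled distractor trace.
#' @export
act_distractor <- function(slope, t, exponent = 10L, bound = -3) {
  bound * act_target(slope, t, exponent)
}

#' Weight of evidence for the presented target
#'
#' The decision variable is the log ratio of evidence for the presented
#' target against the combined inhibitory evidence of the two remembered
#' (non-presented) targets and the pooled distractor trace, each offset by
#' the evidence constant:
#' \deqn{E(t) = \log\frac{Act(T_i,t) + c}{\sum_{j \ne i} Act(T_j,t) +
#'   Act(D,t) + c}.}
#' A response is issued at the first `t` with \eqn{E(t) \ge \beta}.
#' `evidence()` is strictly increasing in `t` for positive slopes, equals
#' about 0.000977 at `t = 0` regardless of the slopes, and approaches
#' log 7 (~1.94591) as `t` grows (at the default constants).
#'
#' @param slope_t numeric length 3, activation slopes of targets 1..3
#'   (ms^-1); the remembered and perceived traces of one target share a
#'   slope by construction.
#' @param slope_d pooled distractor slope (ms^-1).
#' @param presented index (1, 2 or 3) of the target on this trial.
#' @param t time (ms), vectorised.
#' @param constants a [tam_constants()] object.
#' @return Evidence values, same length as `t`.
#' @examples
#' evidence(rep(0.01, 3), 0.01, 1, c(0, 500))
#' @export
evidence <- function(slope_t, slope_d, presented, t,
                     constants = tam_constants()) {
  stopifnot(length(slope_t) == 3L, length(slope_d) == 1L,
            presented %in% 1:3)
  slope_t <- unname(slope_t); slope_d <- unname(slope_d)
  k <- constants
  e <- k$asymptote_exponent
  num <- k$target_bound * act_target(slope_t[presented], t, e) +
    k$evidence_constant
  others <- setdiff(1:3, presented)
  den <- k$nontarget_bound * (act_target(slope_t[others[1L]], t, e) +
                                act_target(slope_t[others[2L]], t, e)) +
    k$distractor_bound * act_target(slope_d, t, e) +
    k$evidence_constant
  if (any(den <= 0))
    stop("evidence denominator non-positive; constants invariant violated")
  log(num / den)
}

#' Predicted reaction time by threshold crossing
#'
#' The predicted RT on a trial is the smallest time `t` at which the weight
#' of evidence reaches the stopping rule \eqn{\beta}.  The default method
#' solves the crossing continuously by bisection (the evidence function is
#' strictly increasing), to `|E(t) - beta| <= tol`; `method = "scan"`
#' iterates the evidence over integer cycles t = 1, 2, 3, ... and returns the
#' first crossing, the literal accumulation procedure, retained as an oracle.
#' The two agree within 1 ms.
#'
#' @inheritParams evidence
#' @param method `"bisection"` (continuous, default) or `"scan"` (integer
#'   cycles).
#' @param tol evidence tolerance for the bisection solve.
#' @return Predicted RT in ms.  Errors with condition class
#'   `"tam_max_cycles_error"` if the threshold is not crossed within
#'   `constants$max_cycles` (for example when all slopes are ~0).
#' @examples
#' predict_rt(rep(0.01, 3), 0.01, 1)
#' @export
predict_rt <- function(slope_t, slope_d, presented = 1L,
                       constants = tam_constants(),
                       method = c("bisection", "scan"), tol = 1e-9) {
  method <- match.arg(method)
  k <- constants
  ev <- function(t) evidence(slope_t, slope_d, presented, t, k)
  if (ev(0) >= k$threshold_beta) return(0)
  if (ev(k$max_cycles) < k$threshold_beta)
    stop(structure(class = c("tam_max_cycles_error", "error", "condition"),
                   list(message = sprintf(
                     "evidence does not reach beta = %g within %d cycles",
                     k$threshold_beta, k$max_cycles), call = sys.call(-1L))))
  if (method == "scan") {
    # vectorised chunked scan over integer cycles
    lo <- 1L
    repeat {
      hi <- min(lo + 511L, k$max_cycles)
      e <- ev(lo:hi)
      idx <- which(e >= k$threshold_beta)
      if (length(idx)) return(as.numeric(lo + idx[1L] - 1L))
      lo <- hi + 1L
    }
  }
  lo <- 0; hi <- k$max_cycles
  for (iter in 1:200) {
    mid <- (lo + hi) / 2
    e <- ev(mid)
    if (abs(e - k$threshold_beta) <= tol) return(mid)
    if (e < k$threshold_beta) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Vectorised bisection for many trials at once: slope_mat is n x 3 (target
# slopes), slope_d length n, presented in 1..3 length n.  Used by backfit and
# the simulator; semantics identical to predict_rt(method = "bisection").
# With extend = TRUE the bracket doubles past max_cycles until the threshold
# is crossed (the crossing always exists for positive slopes since the
# evidence supremum exceeds beta): the backfit solves for the true crossing
# time even when it falls beyond the simulation horizon, whereas forward
# simulation keeps the strict max_cycles error contract.
crossing_times <- function(slope_mat, slope_d, presented,
                           constants = tam_constants(), tol = 1e-9,
                           extend = FALSE) {
  k <- constants
  n <- nrow(slope_mat)
  stopifnot(length(slope_d) == n, length(presented) == n)
  e <- k$asymptote_exponent
  idx <- cbind(seq_len(n), presented)
  ev_at <- function(t) {
    A <- plogis(slope_mat * t)^e              # n x 3, recycles t column-wise
    ad <- plogis(slope_d * t)^e
    num <- k$target_bound * A[idx] + k$evidence_constant
    den <- k$nontarget_bound * (rowSums(A) - A[idx]) +
      k$distractor_bound * ad + k$evidence_constant
    log(num / den)
  }
  beta <- k$threshold_beta
  hi <- rep(as.numeric(k$max_cycles), n)
  e_hi <- ev_at(hi)
  if (any(e_hi < beta)) {
    if (!extend)
      stop(structure(class = c("tam_max_cycles_error", "error", "condition"),
                     list(message = sprintf(
                       "%d trial(s) do not reach beta within %d cycles",
                       sum(e_hi < beta), k$max_cycles), call = sys.call(-1L))))
    for (dbl in 1:40) {                      # bracket up to ~5e15 cycles
      short <- e_hi < beta
      if (!any(short)) break
      hi[short] <- hi[short] * 2
      e_hi <- ev_at(hi)
    }
    if (any(e_hi < beta))
      stop(structure(class = c("tam_max_cycles_error", "error", "condition"),
                     list(message = "threshold unreachable: slopes are ~0",
                          call = sys.call(-1L))))
  }
  lo <- rep(0, n)
  done <- ev_at(lo) >= beta                   # already past threshold at t=0
  hi[done] <- 0
  for (iter in 1:128) {
    mid <- (lo + hi) / 2
    ev <- ev_at(mid)
    below <- ev < beta
    lo[below & !done] <- mid[below & !done]
    hi[!below & !done] <- mid[!below & !done]
    conv <- abs(ev - beta) <= tol
    done <- done | conv
    hi[conv] <- mid[conv]; lo[conv] <- mid[conv]
    if (all(done)) break
  }
  (lo + hi) / 2
}
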