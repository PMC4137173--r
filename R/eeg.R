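#' @name eeg-epochs
#' @title Single-trial slow-wave extraction from Fz epochs
#'
#' @description
#' Epochs are single-channel (Fz) voltage series sampled at 250 Hz from
#' 100 ms before stimulus onset to 696 ms after: 200 samples, 4 ms apart,
#' sample k (0-based) at time -100 + 4k ms.  The slow-wave measures derived
#' from them are the rejection positivity (RP, distractor trials) and the
#' processing negativity (PN, target trials): the mean voltage in the
#' 400-600 ms post-stimulus window after baseline correction.
#'
#' `epoch_times()` gives the sample times; `baseline_correct()` subtracts
#' the mean of the pre-stimulus samples (times in [-100, 0) ms);
#' `is_artifact()` flags epochs whose absolute voltage exceeds the artifact
#' threshold (100 uV) anywhere; `window_mean()` averages the samples whose
#' times fall in [400, 600) ms — exactly 50 samples, the half-open window
#' avoiding double use of the 600 ms sample.
#'
#' All epoch functions accept a numeric vector of 200 samples or a matrix
#' with 200 columns (one epoch per row).
NULL

EPOCH_N <- 200L
EPOCH_STEP <- 4
EPOCH_T0 <- -100

#' @rdname eeg-epochs
#' @return `epoch_times()`: the 200 sample times in ms.
#' @export
epoch_times <- function() EPOCH_T0 + EPOCH_STEP * (seq_len(EPOCH_N) - 1L)

as_epoch_matrix <- function(x) {
  if (is.vector(x) && is.numeric(x)) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != EPOCH_N)
    stop(sprintf("malformed epoch: expected %d samples, got %d",
                 EPOCH_N, ncol(x)))
  storage.mode(x) <- "double"
  x
}

#' @rdname eeg-epochs
#' @param epoch numeric vector of 200 samples (uV) or a matrix of epochs in
#'   rows.
#' @return `baseline_correct()`: the epoch(s) with the pre-stimulus mean
#'   subtracted, same shape as the input.
#' @export
baseline_correct <- function(epoch) {
  vec <- is.vector(epoch) && is.numeric(epoch)
  m <- as_epoch_matrix(epoch)
  base_idx <- which(epoch_times() < 0)        # [-100, 0): samples 1..25
  out <- m - rowMeans(m[, base_idx, drop = FALSE])
  if (vec) drop(out) else out
}

#' @rdname eeg-epochs
#' @param threshold_uv artifact rejection threshold in uV (default 100).
#' @return `is_artifact()`: logical, one per epoch; `TRUE` means reject.
#'   Epochs are expected to be baseline-corrected first.
#' @export
is_artifact <- function(epoch, threshold_uv = 100) {
  m <- as_epoch_matrix(epoch)
  apply(abs(m) > threshold_uv, 1L, any)
}

#' @rdname eeg-epochs
#' @param from,to window endpoints in ms; the window is half-open `[from, to)`.
#' @return `window_mean()`: mean voltage (uV) in the window, one per epoch.
#' @export
window_mean <- function(epoch, from = 400, to = 600) {
  vec <- is.vector(epoch) && is.numeric(epoch)
  m <- as_epoch_matrix(epoch)
  tt <- epoch_times()
  idx <- which(tt >= from & tt < to)
  out <- rowMeans(m[, idx, drop = FALSE])
  if (vec) out[[1L]] else out
}

#' Condition-average slow-wave amplitude
#'
#' Averages valid single-trial window-mean amplitudes within each
#' participant-condition cell, the signal-averaged RP (distractor trials) or
#' PN (target trials) amplitude used by the EEG-linked model variants.
#'
#' @param amplitudes data frame with columns `participant_id`, `condition`,
#'   `fz_mean_uv` and logical/0-1 `valid`.
#' @return Data frame `participant_id`, `condition`, `mean_uv`, `n_trials`.
#' @export
condition_average <- function(amplitudes) {
  stopifnot(all(c("participant_id", "condition", "fz_mean_uv", "valid")
                %in% names(amplitudes)))
  a <- amplitudes[as.logical(amplitudes$valid), , drop = FALSE]
  if (!nrow(a)) stop("no valid trials to average")
  agg <- aggregate(fz_mean_uv ~ participant_id + condition, data = a,
                   FUN = mean)
  cnt <- aggregate(fz_mean_uv ~ participant_id + condition, data = a,
                   FUN = length)
  names(agg)[3L] <- "mean_uv"
  agg$n_trials <- cnt$fz_mean_uv
  agg[order(agg$participant_id, agg$condition), , drop = FALSE]
}

#' Rescale single-trial amplitudes into a noise series
#'
#' Single-trial RP amplitudes enter the model as the stochastic value x after
#' rescaling by a multiplicative constant.  The default convention sets the
#' constant to 1/SD of the participant-condition pool, giving unit dispersion
#' comparable with the unit-variance random-noise sources; `mode = "zscore"`
#' additionally centres the pool (any shift is absorbed by the start
#' parameters during estimation, so centring is optional).
#'
#' @param values numeric vector of single-trial amplitudes (uV), one
#'   participant-condition pool.
#' @param mode `"sd"` (scale only, default) or `"zscore"` (centre and scale).
#' @return Numeric vector of noise values with attributes `mode` and
#'   `constant` (the multiplier applied).  Errors on a constant pool
#'   (zero SD).
#' @examples
#' x <- rescale_noise(c(1, 3, 5))
#' sd(x)   # 1
#' @export
rescale_noise <- function(values, mode = c("sd", "zscore")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(values), length(values) >= 2L, all(is.finite(values)))
  s <- sd(values)
  if (s == 0) stop("cannot rescale a constant amplitude series (zero SD)")
  out <- if (mode == "zscore") (values - mean(values)) / s else values / s
  attr(out, "mode") <- mode
  attr(out, "constant") <- 1 / s
  out
}

#' Process raw epochs into single-trial amplitudes
#'
#' Applies the extraction chain to an epochs table: baseline correction,
#' artifact flagging at 100 uV, and the 400-600 ms window mean at Fz.
#'
#' @param epochs data frame with columns `participant_id`, `condition`,
#'   `trial_index` and sample columns `s000`..`s199` (uV).
#' @param threshold_uv artifact threshold passed to [is_artifact()].
#' @return Amplitudes data frame: `participant_id`, `condition`,
#'   `trial_index`, `fz_mean_uv`, `valid`.
#' @export
extract_amplitudes <- function(epochs, threshold_uv = 100) {
  scol <- sprintf("s%03d", 0:(EPOCH_N - 1L))
  if (!all(scol %in% names(epochs)))
    stop("epochs table must have sample columns s000..s199")
  m <- baseline_correct(as.matrix(epochs[, scol]))
  data.frame(participant_id = epochs$participant_id,
             condition = epochs$condition,
             trial_index = epochs$trial_index,
             fz_mean_uv = window_mean(m),
             valid = !is_artifact(m, threshold_uv))
}
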