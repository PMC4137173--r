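#' @name synthetic-data
#' @title Synthetic Garner-paradigm filtering experiment
#'
#' @description
#' The source design is an auditory selective-attention experiment: one
#' baseline and three filtering conditions, each with three target tones
#' (962, 1000, 1040 Hz, identical across conditions) and a distractor set
#' whose pitch range widens from baseline (a single 1020 Hz distractor) to
#' Filtering 3, increasing distractor salience.  Each condition has 300
#' trials — 150 target trials (50 per target) and 150 distractor trials —
#' in random order with onset-to-onset intervals uniform on 1450-1600 ms.
#' Participants respond to targets and withhold responses to distractors.
#'
#' The generator reproduces that structure with known ground truth so every
#' pipeline stage is testable: a trial schedule, single-trial slow-wave
#' amplitudes (RP on distractor trials, PN on target trials) whose condition
#' means decrease as distractor salience grows, and per-trial RTs produced
#' by the accumulation model itself (no added measurement noise, keeping the
#' forward/backfit roundtrip exact).
NULL

TAM_CONDITIONS <- c("baseline", "filtering1", "filtering2", "filtering3")

TAM_FREQUENCIES <- list(
  target = c(962, 1000, 1040),
  distractor = list(baseline   = c(1020, 1020, 1020),
                    filtering1 = c(982, 1020, 1060),
                    filtering2 = c(954, 1020, 1090),
                    filtering3 = c(929, 1020, 1120)))

#' Trial schedule for the synthetic experiment
#'
#' @param n_participants number of synthetic participants (default 11).
#' @param trials_per_stimulus trials per individual stimulus (default 50,
#'   i.e. 300 trials per condition: 150 target + 150 distractor).
#' @param seed integer seed for trial-order and ISI randomisation.
#' @return Data frame with one row per trial: `participant_id`, `condition`,
#'   `trial_index`, `stimulus_role` ("target"/"distractor"),
#'   `stimulus_level` (1-3), `frequency_hz`, `isi_ms`.
#' @export
make_design <- function(n_participants = 11L, trials_per_stimulus = 50L,
                        seed = 1L) {
  set.seed(seed)
  one_cell <- function(pid, cond) {
    role <- rep(c("target", "distractor"), each = 3L * trials_per_stimulus)
    level <- rep(rep(1:3, each = trials_per_stimulus), times = 2L)
    ord <- sample.int(length(role))
    role <- role[ord]; level <- level[ord]
    freq <- ifelse(role == "target",
                   TAM_FREQUENCIES$target[level],
                   TAM_FREQUENCIES$distractor[[cond]][level])
    data.frame(participant_id = pid, condition = cond,
               trial_index = seq_along(role),
               stimulus_role = role, stimulus_level = level,
               frequency_hz = freq,
               isi_ms = runif(length(role), 1450, 1600))
  }
  pids <- sprintf("P%02d", seq_len(n_participants))
  out <- do.call(rbind, lapply(pids, function(p)
    do.call(rbind, lapply(TAM_CONDITIONS, function(cc) one_cell(p, cc)))))
  rownames(out) <- NULL
  out
}

#' Generative ground truth for the synthetic experiment
#'
#' Per-participant start/swell parameters plus the condition-level amplitude
#' model.  Condition-mean RP amplitude decreases with distractor salience
#' (defaults 2.0, 1.5, 1.0, 0.5 uV — configuration defaults reproducing the
#' monotone frontal slow-wave pattern, not empirical values), and each
#' participant's `dstart` is an exact linear function of that mean
#' (`dstart = intercept + coefficient * amplitude`, coefficient positive),
#' so weaker RP in more salient conditions means slower distractor
#' inhibition and longer RTs.  Start parameters are jittered across
#' participants; swell parameters are negative so that, under the fixed
#' rank-pairing direction (smallest x with shortest RT), small noise values
#' produce steep slopes and fast trials.
#'
#' @param n_participants number of participants.
#' @param seed integer seed for parameter jitter.
#' @param rp_mean_uv named condition means of distractor-trial (RP)
#'   amplitude, uV.
#' @param pn_mean_uv named condition means of target-trial (PN) amplitude,
#'   uV.
#' @param trial_sd_uv single-trial amplitude SD, uV.
#' @param error_rate probability that a target trial is an error (default
#'   0.05).
#' @return List of class `"tam_truth"`: condition amplitude model, error
#'   rate, and `participants`, one entry per participant with `tstart`
#'   (length 3), `tswell`, `dswell`, `link` (intercept, coefficient) and the
#'   implied per-condition `dstart`.
#' @export
ground_truth <- function(n_participants = 11L, seed = 1L,
                         rp_mean_uv = c(baseline = 2.0, filtering1 = 1.5,
                                        filtering2 = 1.0, filtering3 = 0.5),
                         pn_mean_uv = c(baseline = -1.0, filtering1 = -1.2,
                                        filtering2 = -1.4, filtering3 = -1.6),
                         trial_sd_uv = 1.0, error_rate = 0.05) {
  stopifnot(all(TAM_CONDITIONS %in% names(rp_mean_uv)),
            all(diff(rp_mean_uv[TAM_CONDITIONS]) < 0))
  set.seed(seed)
  participants <- lapply(seq_len(n_participants), function(i) {
    link <- c(intercept = -1.85 + rnorm(1, 0, 0.08),
              coefficient = 0.5 + rnorm(1, 0, 0.05))
    dstart <- link[["intercept"]] +
      link[["coefficient"]] * rp_mean_uv[TAM_CONDITIONS]
    list(tstart = c(-1.35, -1.45, -1.55) + rnorm(3, 0, 0.08),
         tswell = -0.22 + rnorm(1, 0, 0.03),
         dswell = -0.22 + rnorm(1, 0, 0.03),
         link = link,
         dstart = dstart)
  })
  names(participants) <- sprintf("P%02d", seq_len(n_participants))
  structure(list(n_participants = as.integer(n_participants),
                 conditions = TAM_CONDITIONS,
                 rp_mean_uv = rp_mean_uv[TAM_CONDITIONS],
                 pn_mean_uv = pn_mean_uv[TAM_CONDITIONS],
                 trial_sd_uv = trial_sd_uv,
                 error_rate = error_rate,
                 seed = as.integer(seed),
                 participants = participants),
            class = "tam_truth")
}

#' Single-trial slow-wave amplitudes (and optional epochs)
#'
#' Draws one amplitude per trial: distractor trials around the condition RP
#' mean, target trials around the condition PN mean, both with the trial SD
#' of the ground truth.  With `epochs = TRUE` a full 200-sample Fz epoch is
#' emitted per trial, built so that baseline correction followed by the
#' 400-600 ms window mean reproduces the tabulated amplitude to numerical
#' precision (a boxcar slow wave on top of zero-mean background noise).
#'
#' @param truth a [ground_truth()] object.
#' @param design a [make_design()] schedule.
#' @param seed integer seed.
#' @param epochs also generate raw epochs? (default FALSE)
#' @param background_sd_uv background noise SD for generated epochs.
#' @return Amplitudes data frame (`participant_id`, `condition`,
#'   `trial_index`, `fz_mean_uv`, `valid`); with `epochs = TRUE`, a list
#'   `list(amplitudes, epochs)`.
#' @export
gen_amplitudes <- function(truth, design, seed = 1L, epochs = FALSE,
                           background_sd_uv = 2.0) {
  set.seed(seed)
  mu <- ifelse(design$stimulus_role == "distractor",
               truth$rp_mean_uv[design$condition],
               truth$pn_mean_uv[design$condition])
  amp <- data.frame(participant_id = design$participant_id,
                    condition = design$condition,
                    trial_index = design$trial_index,
                    fz_mean_uv = rnorm(nrow(design), mu, truth$trial_sd_uv),
                    valid = TRUE)
  if (!epochs) return(amp)
  tt <- epoch_times()
  base_idx <- which(tt < 0)
  win_idx <- which(tt >= 400 & tt < 600)
  m <- matrix(rnorm(nrow(amp) * EPOCH_N, 0, background_sd_uv),
              nrow = nrow(amp))
  # zero the baseline mean, then pin the window mean to the trial amplitude
  m <- m - rowMeans(m[, base_idx, drop = FALSE])
  m[, win_idx] <- m[, win_idx] - rowMeans(m[, win_idx, drop = FALSE]) +
    amp$fz_mean_uv
  colnames(m) <- sprintf("s%03d", 0:(EPOCH_N - 1L))
  ep <- cbind(amp[c("participant_id", "condition", "trial_index")],
              as.data.frame(m))
  list(amplitudes = amp, epochs = ep)
}

#' Forward-simulate trial reaction times from the ground truth
#'
#' For each correct-response target trial a noise value x is drawn (or, for
#' RP-noise, taken from the participant-condition pool of rescaled
#' distractor-trial amplitudes and permuted over trials), the four slopes
#' are built from the participant's parameters, and the RT is the evidence
#' threshold-crossing time.  Distractor trials carry no RT.  Correctness is
#' drawn independently at the configured error rate.
#'
#' @param truth a [ground_truth()] object.
#' @param design a [make_design()] schedule.
#' @param noise `"rp"`, `"gaussian"` or `"rectangular"`.
#' @param amplitudes amplitudes table (required for `noise = "rp"`).
#' @param seed integer seed.
#' @param constants a [tam_constants()] object.
#' @param rescale_mode [rescale_noise()] mode for RP-noise.  The pipeline
#'   default is `"zscore"`: the per-trial noise is the fluctuation about the
#'   condition-mean RP level, which itself enters the model through the
#'   amplitude link rather than through x.
#' @return The design with columns added: `x` (noise value, target trials),
#'   `rt_ms` (NA on distractor trials), `correct` (0/1, target trials).
#' @export
simulate_rts <- function(truth, design, noise = c("rp", "gaussian",
                                                  "rectangular"),
                         amplitudes = NULL, seed = 1L,
                         constants = tam_constants(),
                         rescale_mode = c("zscore", "sd")) {
  rescale_mode <- match.arg(rescale_mode)
  noise <- match.arg(noise)
  if (noise == "rp" && is.null(amplitudes))
    stop("RP noise requires the amplitudes table")
  set.seed(seed)
  out <- design
  out$x <- NA_real_
  out$rt_ms <- NA_real_
  out$correct <- NA_integer_
  for (pid in unique(design$participant_id)) {
    pp <- truth$participants[[pid]]
    for (cond in TAM_CONDITIONS) {
      cell <- which(design$participant_id == pid & design$condition == cond)
      tgt <- cell[design$stimulus_role[cell] == "target"]
      n <- length(tgt)
      x <- switch(noise,
                  gaussian = sample_noise("gaussian", n),
                  rectangular = sample_noise("rectangular", n),
                  rp = {
                    da <- amplitudes[amplitudes$participant_id == pid &
                                       amplitudes$condition == cond &
                                       amplitudes$valid, ]
                    da <- da[da$trial_index %in%
                               design$trial_index[cell][
                                 design$stimulus_role[cell] == "distractor"], ]
                    pool <- rescale_noise(da$fz_mean_uv, rescale_mode)
                    sample(select_noise(pool, n))   # random trial assignment
                  })
      par <- c(pp$tstart, pp$tswell, pp$dstart[[cond]], pp$dswell)
      sl <- trial_slopes(par, as.numeric(x), constants$slope_scale)
      rt <- crossing_times(sl[, 1:3, drop = FALSE], sl[, 4L],
                           design$stimulus_level[tgt], constants)
      out$x[tgt] <- as.numeric(x)
      out$rt_ms[tgt] <- rt
      out$correct[tgt] <- rbinom(n, 1L, 1 - truth$error_rate)
    }
  }
  out
}

#' Simulate a complete synthetic experiment
#'
#' Convenience wrapper chaining [make_design()], [ground_truth()],
#' [gen_amplitudes()] and [simulate_rts()] under one master seed (fanned out
#' into independent sub-seeds for design, parameters, amplitudes and RTs, so
#' each component is independently reproducible).
#'
#' @param n_participants number of participants (default 11).
#' @param seed master integer seed.
#' @param noise noise source for RT generation.
#' @param epochs also emit raw epochs.
#' @param ... passed to [ground_truth()].
#' @return List of class `"tam_data"`: `trials`, `amplitudes`, optional
#'   `epochs`, `truth`, `noise_source`, `seed`.
#' @examples
#' dat <- simulate_experiment(n_participants = 2, seed = 7, noise = "gaussian")
#' head(subset(dat$trials, stimulus_role == "target"))
#' @export
simulate_experiment <- function(n_participants = 11L, seed = 1L,
                                noise = c("rp", "gaussian", "rectangular"),
                                epochs = FALSE, ...) {
  noise <- match.arg(noise)
  set.seed(seed)
  sub <- sample.int(.Machine$integer.max, 4L)
  design <- make_design(n_participants, seed = sub[1L])
  truth <- ground_truth(n_participants, seed = sub[2L], ...)
  amp <- gen_amplitudes(truth, design, seed = sub[3L], epochs = epochs)
  if (epochs) { ep <- amp$epochs; amp <- amp$amplitudes } else ep <- NULL
  trials <- simulate_rts(truth, design, noise, amp, seed = sub[4L])
  structure(list(trials = trials, amplitudes = amp, epochs = ep,
                 truth = truth, noise_source = noise,
                 seed = as.integer(seed)),
            class = "tam_data")
}

#' @export
print.tam_data <- function(x, ...) {
  tr <- x$trials
  cat("Synthetic filtering experiment\n")
  cat(sprintf("  %d participants x %d conditions, %d trials (%d target)\n",
              length(unique(tr$participant_id)),
              length(unique(tr$condition)), nrow(tr),
              sum(tr$stimulus_role == "target")))
  ok <- tr$stimulus_role == "target" & tr$correct == 1L
  cat(sprintf("  noise source: %s; mean correct-target RT %.0f ms\n",
              x$noise_source, mean(tr$rt_ms[ok], na.rm = TRUE)))
  invisible(x)
}

#' Write / read a synthetic dataset as plain-text files
#'
#' `write_dataset()` emits `trials.csv`, `amplitudes.csv`, `truth.json` and,
#' when present, `epochs.csv` into a directory; `read_dataset()` restores
#' the `"tam_data"` object.  CSV values round-trip exactly (written at full
#' precision).
#'
#' @param data a `"tam_data"` object.
#' @param dir output directory (created if needed).
#' @return `write_dataset()` the directory, invisibly; `read_dataset()` a
#'   `"tam_data"` object (without the truth's class-internal jitter seed
#'   semantics altered — the truth is restored verbatim).
#' @export
write_dataset <- function(data, dir) {
  stopifnot(inherits(data, "tam_data"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(d, f) {
    old <- options(digits = 17); on.exit(options(old))
    write.csv(d, file.path(dir, f), row.names = FALSE, quote = FALSE)
  }
  wcsv(data$trials, "trials.csv")
  wcsv(data$amplitudes, "amplitudes.csv")
  if (!is.null(data$epochs)) wcsv(data$epochs, "epochs.csv")
  meta <- unclass(data$truth)
  jsonlite::write_json(list(truth = meta, noise_source = data$noise_source,
                            seed = data$seed),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  req <- c("trials.csv", "amplitudes.csv", "truth.json")
  missing <- req[!file.exists(file.path(dir, req))]
  if (length(missing))
    stop("dataset directory is missing: ", paste(missing, collapse = ", "))
  trials <- read.csv(file.path(dir, "trials.csv"))
  need <- c("participant_id", "condition", "trial_index", "stimulus_role",
            "stimulus_level", "rt_ms", "correct")
  if (!all(need %in% names(trials)))
    stop("trials.csv is missing columns: ",
         paste(setdiff(need, names(trials)), collapse = ", "))
  amp <- read.csv(file.path(dir, "amplitudes.csv"))
  meta <- jsonlite::read_json(file.path(dir, "truth.json"),
                              simplifyVector = TRUE)
  truth <- meta$truth
  conds <- unlist(truth$conditions)
  truth$rp_mean_uv <- setNames(unlist(truth$rp_mean_uv), conds)
  truth$pn_mean_uv <- setNames(unlist(truth$pn_mean_uv), conds)
  truth$participants <- lapply(truth$participants, function(p) {
    p$tstart <- unlist(p$tstart)
    p$link <- setNames(unlist(p$link), c("intercept", "coefficient"))
    p$dstart <- setNames(unlist(p$dstart), conds)
    p
  })
  class(truth) <- "tam_truth"
  ep_path <- file.path(dir, "epochs.csv")
  structure(list(trials = trials, amplitudes = amp,
                 epochs = if (file.exists(ep_path)) read.csv(ep_path),
                 truth = truth, noise_source = meta$noise_source,
                 seed = meta$seed),
            class = "tam_data")
}
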