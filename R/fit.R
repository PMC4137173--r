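#' Evidence objective for parameter estimation
#'
#' The estimation-stage objective substitutes each trial's observed RT for
#' the accumulation time and measures how far the implied weight of evidence
#' sits from the stopping rule:
#' \deqn{objFunc = \sum_{h=1}^{N} (\beta - E(T_{i(h)}, t_h))^2,}
#' summed over the N correct target trials of one participant-condition
#' cell.  It is nonnegative, zero exactly when every trial's evidence at its
#' observed RT equals \eqn{\beta}, and invariant to trial order.
#'
#' @param par parameter vector `c(tstart_1, tstart_2, tstart_3, tswell,
#'   dstart, dswell)`.
#' @param rt observed RTs (ms).
#' @param level presented target level per trial (1-3).
#' @param x per-trial noise values (same order as `rt`).
#' @param constants a [tam_constants()] object.
#' @return The scalar objective value.
#' @examples
#' objective(c(0, 0, 0, 0.5, 0, 0.5), rt = c(500, 650), level = c(1, 2),
#'           x = c(-0.5, 0.5))
#' @export
objective <- function(par, rt, level, x, constants = tam_constants()) {
  stopifnot(length(par) == 6L, length(rt) == length(level),
            length(rt) == length(x))
  k <- constants
  e <- k$asymptote_exponent
  sl <- trial_slopes(par, x, k$slope_scale)
  A <- plogis(sl[, 1:3, drop = FALSE] * rt)^e
  ad <- plogis(sl[, 4L] * rt)^e
  idx <- cbind(seq_along(rt), level)
  num <- k$target_bound * A[idx] + k$evidence_constant
  den <- k$nontarget_bound * (rowSums(A) - A[idx]) +
    k$distractor_bound * ad + k$evidence_constant
  ev <- log(num / den)
  sum((k$threshold_beta - ev)^2)
}

# -- stage-1 optimisers -------------------------------------------------------

# The evidence objective evaluates parameters only at the observed RTs, so
# it has degenerate optima in the saturation regime of the slope logistic:
# a start/swell pair driving the logistic argument far beyond its responsive
# range pins slopes at 0 or 0.023 for most trials, can fit the observed
# evidence values well, and extrapolates pathologically (crossing times for
# its own trials far beyond the simulation horizon).  A restart is
# admissible only if (i) its parameters reproduce every fitted trial within
# max_cycles — the contract the forward simulator enforces — and (ii) the
# realized slope arguments on those trials stay inside the logistic's
# responsive range (|start + swell * x| <= arg_bound; beyond it the
# parameters have no local effect on any fitted trial).
ARG_BOUND <- 12

slope_arguments <- function(par, x) {
  cbind(outer(x, par[1:3], function(xx, st) st + par[4L] * xx),
        par[5L] + par[6L] * x)
}

admissible_fit <- function(par, x, level, constants,
                           arg_bound = ARG_BOUND) {
  x <- as.numeric(x)
  if (max(abs(slope_arguments(par, x))) > arg_bound) return(FALSE)
  k <- constants
  sl <- trial_slopes(par, x, k$slope_scale)
  e <- k$asymptote_exponent
  tmax <- as.numeric(k$max_cycles)
  A <- plogis(sl[, 1:3, drop = FALSE] * tmax)^e
  ad <- plogis(sl[, 4L] * tmax)^e
  idx <- cbind(seq_along(x), level)
  num <- k$target_bound * A[idx] + k$evidence_constant
  den <- k$nontarget_bound * (rowSums(A) - A[idx]) +
    k$distractor_bound * ad + k$evidence_constant
  if (!all(log(num / den) >= k$threshold_beta)) return(FALSE)
  # self-consistency with the rank pairing the fit was conditioned on: the
  # noise assignment pairs ascending x with ascending RT, so the fitted
  # model must map ascending x to non-decreasing predicted RTs (per target,
  # since targets differ in baseline slope)
  ord <- order(x)
  rt_pred <- crossing_times(sl[ord, 1:3, drop = FALSE], sl[ord, 4L],
                            level[ord], constants, tol = 1e-6)
  lvl_s <- level[ord]
  for (i in 1:3) {
    r <- rt_pred[lvl_s == i]
    if (length(r) > 1L && any(diff(r) < -1e-3)) return(FALSE)
  }
  TRUE
}

# Nelder-Mead over `free` components of the parameter vector, multi-start:
# first restart from `start` unjittered, then jittered starts.  Candidates
# are screened by `validate` (by default admissibility on the fitted cell;
# callers substitute a validator spanning every cell the parameters will
# serve, including variant-linked per-condition substitutions) and ranked by
# the raw objective.  If no plain restart validates, the restarts are
# repeated on a smoothly penalized objective (quadratic barrier on slope-
# argument excess over `barrier_x`) that steers the simplex back toward the
# admissible region.  If that also fails, the best overall fit is returned
# flagged as unconverged.
nm_fit <- function(start, free, rt, level, x, constants, control,
                   validate = NULL, barrier_x = x, select_score = NULL) {
  if (is.null(validate))
    validate <- function(p) admissible_fit(p, x, level, constants)
  raw_obj <- function(p) objective(p, rt, level, x, constants)
  if (is.null(select_score)) select_score <- raw_obj
  barrier <- function(p) {
    excess <- pmax(abs(slope_arguments(p, as.numeric(barrier_x))) - ARG_BOUND,
                   0)
    sum(excess^2)
  }
  run_restarts <- function(penalized) {
    best <- NULL; best_valid <- NULL
    for (r in seq_len(control$restarts)) {
      init <- start[free]
      if (r > 1L) init <- init + rnorm(length(free), 0, control$jitter_sd)
      o <- optim(init, function(theta) {
        p <- start; p[free] <- theta
        raw_obj(p) + if (penalized) barrier(p) else 0
      }, method = "Nelder-Mead",
      control = list(reltol = control$reltol, maxit = control$maxit))
      p <- start; p[free] <- o$par
      o$value <- raw_obj(p)                   # the fitted-cell objective
      o$admissible <- validate(p)
      # admissible candidates compete on the selection score (by default the
      # fitted-cell objective; the baseline stage scores candidates by the
      # whole sequential procedure they will seed)
      if (o$admissible) o$score <- select_score(p)
      if (is.null(best) || o$value < best$value) best <- o
      if (o$admissible && (is.null(best_valid) || o$score < best_valid$score))
        best_valid <- o
    }
    list(best = best, best_valid = best_valid)
  }
  res <- run_restarts(penalized = FALSE)
  if (is.null(res$best_valid)) {
    res2 <- run_restarts(penalized = TRUE)
    if (!is.null(res2$best_valid)) res$best_valid <- res2$best_valid
    else if (res2$best$value < res$best$value) res$best <- res2$best
  }
  degenerate <- is.null(res$best_valid)
  best <- if (degenerate) res$best else res$best_valid
  par <- start; par[free] <- best$par
  list(par = par, value = best$value,
       converged = best$convergence == 0L && !degenerate,
       iterations = best$counts[["function"]])
}

# 1-D refit of a single component by golden-section search (the objective is
# smooth in one coordinate; a simplex is degenerate in 1-D).
refit_one <- function(par, index, rt, level, x, constants,
                      interval = c(-12, 12), tol = 1e-8) {
  o <- optimize(function(v) {
    p <- par; p[index] <- v
    objective(p, rt, level, x, constants)
  }, interval = interval, tol = tol)
  par[index] <- o$minimum
  list(par = par, value = o$objective, converged = TRUE)
}

default_control <- function(control = list()) {
  ctl <- list(restarts = 5L, reltol = 1e-8, maxit = 2000L, jitter_sd = 0.25)
  ctl[names(control)] <- control
  ctl
}

# -- per-participant data assembly -------------------------------------------

# Correct target trials of one participant, split by condition, with the
# rank-paired noise assignment already attached.
prepare_participant <- function(trials_p, amplitudes_p, noise_source,
                                control, rescale_mode = "zscore") {
  cells <- list()
  for (cond in TAM_CONDITIONS) {
    tr <- trials_p[trials_p$condition == cond &
                     trials_p$stimulus_role == "target" &
                     trials_p$correct == 1L & !is.na(trials_p$rt_ms), ,
                   drop = FALSE]
    if (!nrow(tr)) stop("no correct target trials in condition ", cond)
    n <- nrow(tr)
    pool <- switch(noise_source,
                   gaussian = sample_noise("gaussian", n),
                   rectangular = sample_noise("rectangular", n),
                   rp_noise = {
                     if (is.null(amplitudes_p))
                       stop("rp_noise requires single-trial amplitudes")
                     da_idx <- trials_p$trial_index[
                       trials_p$condition == cond &
                         trials_p$stimulus_role == "distractor"]
                     da <- amplitudes_p[amplitudes_p$condition == cond &
                                          amplitudes_p$valid &
                                          amplitudes_p$trial_index %in% da_idx, ]
                     if (nrow(da) < 2L)
                       stop("too few valid distractor amplitudes in ", cond)
                     select_noise(rescale_noise(da$fz_mean_uv, rescale_mode),
                                  n)
                   })
    tr$x <- assign_noise(pool, tr$rt_ms)
    cells[[cond]] <- tr
  }
  cells
}

# Condition-mean amplitudes (uV) for the EEG-linked variants.  role is
# "distractor" (RP) or "target" (PN).
mean_amplitudes <- function(trials_p, amplitudes_p, role) {
  idx <- trials_p[trials_p$stimulus_role == role,
                  c("condition", "trial_index")]
  a <- merge(amplitudes_p, idx, by = c("condition", "trial_index"))
  ca <- condition_average(a)
  out <- ca$mean_uv[match(TAM_CONDITIONS, ca$condition)]
  names(out) <- TAM_CONDITIONS
  out
}

# -- variant estimation for one participant ----------------------------------

START_BASE <- c(0, 0, 0, 0.5, 0, 0.5)

fit_participant <- function(cells, amps_rp, amps_pn, variant, constants,
                            control) {
  with_cell <- function(f, cond, ...) {
    cc <- cells[[cond]]
    f(rt = cc$rt_ms, level = cc$stimulus_level, x = cc$x, ...)
  }
  # admissibility of carried-over parameters is checked against every cell
  # they will serve (with any per-condition linked substitutions applied),
  # not just the cell being fitted
  all_x <- unlist(lapply(cells, `[[`, "x"), use.names = FALSE)
  validate_cells <- function(p, dstart_by_cond = NULL,
                             tstart_by_cond = NULL) {
    for (cond in names(cells)) {
      cc <- cells[[cond]]
      pc <- p
      if (!is.null(dstart_by_cond)) pc[5L] <- dstart_by_cond[[cond]]
      if (!is.null(tstart_by_cond)) pc[1:3] <- tstart_by_cond[cond, ]
      if (!admissible_fit(pc, cc$x, cc$stimulus_level, constants))
        return(FALSE)
    }
    TRUE
  }
  # score a baseline candidate by the whole sequential procedure it seeds:
  # its own cell objective plus, per filtering cell, the objective after a
  # cheap 1-D refit of the inhibitory level (dstart, the pair member whose
  # baseline identifiability is weakest).  The score is deliberately
  # variant-independent so every variant proceeds from the same baseline
  # estimates — the models are identical in the baseline condition.
  refit_dims <- 5L
  score_sequential <- function(p) {
    total <- 0
    for (cond in names(cells)) {
      cc <- cells[[cond]]
      if (cond == "baseline") {
        total <- total +
          objective(p, cc$rt_ms, cc$stimulus_level, cc$x, constants)
      } else {
        pc <- p
        for (d in refit_dims) {
          f <- refit_one(pc, d, cc$rt_ms, cc$stimulus_level, cc$x,
                         constants, tol = 1e-6)
          pc <- f$par
        }
        total <- total + f$value
      }
    }
    total
  }
  base <- with_cell(function(rt, level, x)
    nm_fit(START_BASE, 1:6, rt, level, x, constants, control,
           validate = validate_cells, barrier_x = all_x,
           select_score = score_sequential), "baseline")

  params <- matrix(rep(base$par, each = 4L), nrow = 4L,
                   dimnames = list(TAM_CONDITIONS, PAR_NAMES))
  fits <- list(baseline = base)
  link <- NULL

  inhibition_refit <- function(params) {
    for (cond in TAM_CONDITIONS[-1L]) {
      f <- with_cell(function(rt, level, x)
        refit_one(base$par, 5L, rt, level, x, constants), cond)
      params[cond, "dstart"] <- f$par[5L]
      fits[[cond]] <<- f
    }
    params
  }
  excitation_refit <- function(params) {
    for (cond in TAM_CONDITIONS[-1L]) {
      f <- with_cell(function(rt, level, x)
        nm_fit(base$par, 1:3, rt, level, x, constants, control), cond)
      params[cond, 1:3] <- f$par[1:3]
      fits[[cond]] <<- f
    }
    params
  }

  if (variant == "inhibition_only") {
    params <- inhibition_refit(params)
  } else if (variant == "excitation_only") {
    params <- excitation_refit(params)
  } else if (variant == "rp") {
    params <- inhibition_refit(params)
    link <- fit_link(params[, "dstart"], amps_rp)
    dlink <- apply_link(link, amps_rp)
    # re-estimate the excitatory and swell parameters at baseline with the
    # linked dstart held fixed
    start <- base$par; start[5L] <- dlink[["baseline"]]
    score_linked_d <- function(p) {
      total <- 0
      for (cond in names(cells)) {
        cc <- cells[[cond]]
        pc <- p; pc[5L] <- dlink[[cond]]
        total <- total +
          objective(pc, cc$rt_ms, cc$stimulus_level, cc$x, constants)
      }
      total
    }
    rebase <- with_cell(function(rt, level, x)
      nm_fit(start, c(1:4, 6L), rt, level, x, constants, control,
             validate = function(p) validate_cells(p, dstart_by_cond = dlink),
             barrier_x = all_x, select_score = score_linked_d), "baseline")
    params <- matrix(rep(rebase$par, each = 4L), nrow = 4L,
                     dimnames = list(TAM_CONDITIONS, PAR_NAMES))
    params[, "dstart"] <- dlink
    fits$baseline_relinked <- rebase
  } else if (variant == "pn") {
    params <- excitation_refit(params)
    link <- lapply(1:3, function(i)
      fit_link(params[, i], amps_pn))
    names(link) <- PAR_NAMES[1:3]
    tlink <- vapply(link, apply_link, numeric(4L), amplitude = amps_pn)
    start <- base$par; start[1:3] <- tlink["baseline", ]
    score_linked_t <- function(p) {
      total <- 0
      for (cond in names(cells)) {
        cc <- cells[[cond]]
        pc <- p; pc[1:3] <- tlink[cond, ]
        total <- total +
          objective(pc, cc$rt_ms, cc$stimulus_level, cc$x, constants)
      }
      total
    }
    rebase <- with_cell(function(rt, level, x)
      nm_fit(start, 4:6, rt, level, x, constants, control,
             validate = function(p) validate_cells(p, tstart_by_cond = tlink),
             barrier_x = all_x, select_score = score_linked_t), "baseline")
    params <- matrix(rep(rebase$par, each = 4L), nrow = 4L,
                     dimnames = list(TAM_CONDITIONS, PAR_NAMES))
    params[, 1:3] <- tlink
    fits$baseline_relinked <- rebase
  }

  obj_final <- vapply(TAM_CONDITIONS, function(cond) {
    cc <- cells[[cond]]
    objective(params[cond, ], cc$rt_ms, cc$stimulus_level, cc$x, constants)
  }, numeric(1L))

  list(params = params, link = link,
       objective = obj_final,
       converged = all(vapply(fits, `[[`, logical(1L), "converged")),
       baseline_objective = base$value,
       cells = cells)
}

#' Ordinary least-squares link between a parameter and slow-wave amplitude
#'
#' The EEG-linked variants replace per-condition free parameters with a
#' two-parameter linear link fitted per participant across the four
#' conditions: the parameter estimate from the free-parameter fit is
#' regressed on the condition-average slow-wave amplitude, and the linked
#' parameter in a condition is the intercept plus the coefficient times
#' that condition's amplitude.
#'
#' @param estimates named numeric vector: one parameter estimate per
#'   condition (the regression response).
#' @param amplitudes named numeric vector: condition-average amplitude (uV,
#'   the predictor), same conditions.
#' @return List of class `"tam_link"`: `intercept`, `coefficient`,
#'   `r_squared`, `n`.
#' @examples
#' fit_link(c(2, 4, 6, 8), c(1, 2, 3, 4))   # intercept 0, coefficient 2
#' @export
fit_link <- function(estimates, amplitudes) {
  stopifnot(length(estimates) == length(amplitudes),
            length(estimates) >= 2L)
  if (!is.null(names(estimates)) && !is.null(names(amplitudes)))
    amplitudes <- amplitudes[names(estimates)]
  y <- as.numeric(estimates)
  fit <- lm(y ~ a, data = data.frame(y = y, a = as.numeric(amplitudes)))
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(residuals(fit)^2) / ss_tot else NA_real_
  structure(list(intercept = unname(coef(fit)[1L]),
                 coefficient = unname(coef(fit)[2L]),
                 r_squared = r2,
                 n = length(estimates)),
            class = "tam_link")
}

#' @rdname fit_link
#' @param link a `"tam_link"` object.
#' @param amplitude amplitude value(s) (uV).
#' @return `apply_link()`: the linked parameter value(s),
#'   `intercept + coefficient * amplitude`.
#' @export
apply_link <- function(link, amplitude) {
  stopifnot(inherits(link, "tam_link"))
  link$intercept + link$coefficient * amplitude
}

#' @export
print.tam_link <- function(x, ...) {
  cat(sprintf("amplitude link: parameter = %.4f + %.4f * uV  (R^2 %.3f, n %d)\n",
              x$intercept, x$coefficient, x$r_squared, x$n))
  invisible(x)
}

#' Per-trial backfit: predicted RTs from fitted parameters
#'
#' Stage two of the fitting procedure: the estimated parameters are inserted
#' into the slope equations with the trial's noise value x, and the
#' accumulation time is solved per trial — the time minimising
#' \eqn{(\beta - E(t))^2}, which by monotonicity of the evidence is the
#' threshold-crossing time.  That crossing time is the model's predicted RT
#' for the trial.
#'
#' @param par parameter vector `c(tstart_1..3, tswell, dstart, dswell)`.
#' @param x per-trial noise values.
#' @param level presented target level per trial (1-3).
#' @param constants a [tam_constants()] object.
#' @param tol evidence tolerance of the crossing solve.
#' @return Numeric vector of predicted RTs (ms).  Unlike forward simulation,
#'   the backfit does not error when a predicted crossing falls beyond
#'   `constants$max_cycles`: the crossing always exists for positive slopes,
#'   and the solver extends its bracket to find it, so extreme noise values
#'   yield extreme (but finite and exact) predicted RTs.
#' @export
backfit <- function(par, x, level, constants = tam_constants(), tol = 1e-9) {
  stopifnot(length(par) == 6L, length(x) == length(level))
  sl <- trial_slopes(par, as.numeric(x), constants$slope_scale)
  crossing_times(sl[, 1:3, drop = FALSE], sl[, 4L], level, constants, tol,
                 extend = TRUE)
}

FREE_PARAMS <- c(inhibition_only = 9L, excitation_only = 15L,
                 rp = 7L, pn = 9L)

#' Fit a tectonic accumulation model to trial data
#'
#' Two-stage estimation of one of the four model variants for every
#' participant in a trial table.  Stage one estimates six free parameters in
#' the baseline condition by Nelder-Mead minimisation of the evidence
#' [objective()] (multi-start, seeded), then handles the filtering
#' conditions per variant:
#'
#' * `"inhibition_only"` (9 free parameters): `dstart` is re-estimated in
#'   each condition; everything else carries over from baseline.
#' * `"excitation_only"` (15): the three `tstart` parameters are
#'   re-estimated per condition; the rest carries over.
#' * `"rp"` (7): a per-participant OLS link from condition-average
#'   distractor-trial (RP) amplitude to the inhibition-only `dstart`
#'   estimates replaces the per-condition `dstart`s; the remaining
#'   parameters are then re-estimated at baseline with the linked `dstart`
#'   fixed.
#' * `"pn"` (9): the analogous links from target-trial (PN) amplitude to
#'   each `tstart`; `tswell`, `dstart`, `dswell` re-estimated at baseline.
#'
#' Before estimation, each participant-condition cell's noise values
#' (Gaussian, rectangular, or rescaled single-trial RP amplitudes) are
#' rank-paired to the observed RTs ([assign_noise()]).  Only correct target
#' trials enter the fit.
#'
#' @param data a `"tam_data"` object from [simulate_experiment()] /
#'   [read_dataset()], or a list with elements `trials` (and `amplitudes`
#'   for RP-noise or the EEG-linked variants).
#' @param variant `"inhibition_only"`, `"excitation_only"`, `"rp"` or
#'   `"pn"`.
#' @param noise `"gaussian"`, `"rectangular"` or `"rp_noise"`.
#' @param seed integer seed for noise sampling/selection and optimizer
#'   restarts.
#' @param constants a [tam_constants()] object.
#' @param control optional list overriding `restarts` (5), `reltol` (1e-8),
#'   `maxit` (2000), `jitter_sd` (0.25).
#' @param rescale_mode [rescale_noise()] mode for RP-noise (default
#'   `"zscore"`: per-trial noise is the fluctuation about the condition-mean
#'   amplitude; the mean level enters through the amplitude link).
#' @return An object of class `"tamfit"`; see [predict.tamfit()],
#'   [summary.tamfit()], [coef.tamfit()], [plot.tamfit()].
#' @examples
#' \donttest{
#' dat <- simulate_experiment(n_participants = 2, seed = 42,
#'                            noise = "gaussian")
#' fit <- tam_fit(dat, variant = "inhibition_only", noise = "gaussian",
#'                seed = 1)
#' coef(fit)[coef(fit)$participant_id == "P01", ]
#' }
#' @export
tam_fit <- function(data,
                    variant = c("inhibition_only", "excitation_only",
                                "rp", "pn"),
                    noise = c("gaussian", "rectangular", "rp_noise"),
                    seed = 1L, constants = tam_constants(),
                    control = list(), rescale_mode = c("zscore", "sd")) {
  variant <- match.arg(variant)
  noise <- match.arg(noise)
  rescale_mode <- match.arg(rescale_mode)
  trials <- data$trials
  amplitudes <- data$amplitudes
  stopifnot(is.data.frame(trials))
  need <- c("participant_id", "condition", "trial_index", "stimulus_role",
            "stimulus_level", "rt_ms", "correct")
  if (!all(need %in% names(trials)))
    stop("trials table is missing columns: ",
         paste(setdiff(need, names(trials)), collapse = ", "))
  if ((noise == "rp_noise" || variant %in% c("rp", "pn")) &&
      is.null(amplitudes))
    stop("variant/noise choice requires single-trial amplitudes")
  ctl <- default_control(control)
  set.seed(seed)
  pids <- sort(unique(trials$participant_id))
  # one sub-seed per participant: noise assignment and the baseline fit are
  # then identical across model variants (which consume different amounts of
  # randomness in their per-condition refits)
  pid_seeds <- sample.int(.Machine$integer.max, length(pids))
  names(pid_seeds) <- pids
  participants <- list()
  for (pid in pids) {
    set.seed(pid_seeds[[pid]])
    tr_p <- trials[trials$participant_id == pid, , drop = FALSE]
    am_p <- if (!is.null(amplitudes))
      amplitudes[amplitudes$participant_id == pid, , drop = FALSE]
    cells <- prepare_participant(tr_p, am_p, noise, ctl, rescale_mode)
    amps_rp <- if (variant == "rp") mean_amplitudes(tr_p, am_p, "distractor")
    amps_pn <- if (variant == "pn") mean_amplitudes(tr_p, am_p, "target")
    participants[[pid]] <- fit_participant(cells, amps_rp, amps_pn, variant,
                                           constants, ctl)
  }
  structure(list(participants = participants, variant = variant,
                 noise = noise, n_free = unname(FREE_PARAMS[variant]),
                 seed = as.integer(seed), constants = constants,
                 control = ctl,
                 data = list(trials = trials, amplitudes = amplitudes)),
            class = "tamfit")
}
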