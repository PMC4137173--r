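#' Pipeline configuration
#'
#' A plain serialisable list of everything a pipeline run depends on: paths,
#' master seed, dataset size, the model variant and noise source to fit, and
#' optimizer control.  The configuration (with the seed) is written into
#' every output directory, so a run can be reproduced byte-for-byte from its
#' outputs alone.
#'
#' @param out_dir output directory.
#' @param seed master integer seed; fanned out into sub-seeds for design,
#'   parameters, amplitudes, RT noise and optimizer restarts.
#' @param n_participants synthetic participants.
#' @param sim_noise noise source used to generate the synthetic RTs.
#' @param variant model variant to fit.
#' @param noise noise source used in fitting.
#' @param control optimizer control overrides (see [tam_fit()]).
#' @return List of class `"tam_config"`.
#' @export
tam_config <- function(out_dir, seed = 1L, n_participants = 11L,
                       sim_noise = c("rp", "gaussian", "rectangular"),
                       variant = c("inhibition_only", "excitation_only",
                                   "rp", "pn"),
                       noise = c("gaussian", "rectangular", "rp_noise"),
                       control = list()) {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 n_participants = as.integer(n_participants),
                 sim_noise = match.arg(sim_noise),
                 variant = match.arg(variant),
                 noise = match.arg(noise),
                 control = control),
            class = "tam_config")
}

write_config <- function(config, dir) {
  jsonlite::write_json(unclass(config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

#' Pipeline stages
#'
#' Thin orchestration over the package functions: `pipeline_simulate()`
#' generates and writes a synthetic dataset; `pipeline_fit()` fits the
#' configured variant and writes `params.json`; `pipeline_predict()` writes
#' the backfit predictions to `predicted_trials.csv`; `pipeline_evaluate()`
#' writes the condition report (`report.csv`: quantile means, densities,
#' chi-square) and the moment table (`moments.csv`).  `run_pipeline()` runs
#' all four.  Each stage logs counts at its boundary and re-running with
#' the same configuration reproduces the outputs exactly.
#'
#' @param config a [tam_config()] object.
#' @param data a `"tam_data"` object (defaults to reading/simulating per
#'   config).
#' @param fit a `"tamfit"` object.
#' @param quiet suppress stage messages.
#' @return `run_pipeline()` returns (invisibly) a list with the dataset,
#'   fit, predictions and summary; the stage functions return their stage
#'   product invisibly.
#' @export
pipeline_simulate <- function(config, quiet = FALSE) {
  dat <- simulate_experiment(config$n_participants, seed = config$seed,
                             noise = config$sim_noise)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_dataset(dat, file.path(config$out_dir, "dataset"))
  write_config(config, config$out_dir)
  if (!quiet)
    message(sprintf("simulate: %d trials, %d participants -> %s",
                    nrow(dat$trials), config$n_participants,
                    file.path(config$out_dir, "dataset")))
  invisible(dat)
}

#' @rdname pipeline_simulate
#' @export
pipeline_fit <- function(config, data = NULL, quiet = FALSE) {
  if (is.null(data)) data <- read_dataset(file.path(config$out_dir, "dataset"))
  fit <- tam_fit(data, variant = config$variant, noise = config$noise,
                 seed = config$seed, control = config$control)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  pars <- lapply(fit$participants, function(p) {
    out <- list(params = as.data.frame(p$params),
                objective = as.list(p$objective),
                converged = p$converged)
    if (!is.null(p$link)) {
      out$link <- if (inherits(p$link, "tam_link")) unclass(p$link)
      else lapply(p$link, unclass)
    }
    out
  })
  jsonlite::write_json(list(variant = fit$variant, noise = fit$noise,
                            n_free = fit$n_free, seed = fit$seed,
                            participants = pars),
                       file.path(config$out_dir, "params.json"),
                       auto_unbox = TRUE, digits = NA)
  write_config(config, config$out_dir)
  if (!quiet)
    message(sprintf("fit: %s / %s, %d participants, %d free parameters",
                    fit$variant, fit$noise, length(fit$participants),
                    fit$n_free))
  invisible(fit)
}

#' @rdname pipeline_simulate
#' @export
pipeline_predict <- function(config, fit, quiet = FALSE) {
  pred <- predict(fit)
  old <- options(digits = 17); on.exit(options(old))
  write.csv(pred, file.path(config$out_dir, "predicted_trials.csv"),
            row.names = FALSE, quote = FALSE)
  if (!quiet)
    message(sprintf("predict: %d backfit trials -> predicted_trials.csv",
                    nrow(pred)))
  invisible(pred)
}

#' @rdname pipeline_simulate
#' @export
pipeline_evaluate <- function(config, fit, quiet = FALSE) {
  s <- summary(fit)
  rep_tab <- do.call(rbind, lapply(names(s$quantiles), function(cond) {
    q <- s$quantiles[[cond]]
    cs <- s$conditions[s$conditions$condition == cond, ]
    data.frame(condition = cond,
               quantile = seq_along(q$observed),
               rt_obs_ms = q$observed, rt_pred_ms = q$predicted,
               density_obs = c(quantile_density(q$observed), NA),
               density_pred = c(quantile_density(q$predicted), NA),
               chi_square = cs$chi_square, df = cs$df,
               p_value = cs$p_value)
  }))
  write.csv(rep_tab, file.path(config$out_dir, "report.csv"),
            row.names = FALSE)
  write.csv(s$moments, file.path(config$out_dir, "moments.csv"),
            row.names = FALSE)
  if (!quiet)
    message(sprintf("evaluate: chi-square %s; pooled r = %.4f",
                    paste(sprintf("%s %.2f", s$conditions$condition,
                                  s$conditions$chi_square), collapse = ", "),
                    s$pooled_r))
  invisible(s)
}

#' @rdname pipeline_simulate
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  dat <- pipeline_simulate(config, quiet = quiet)
  fit <- pipeline_fit(config, dat, quiet = quiet)
  pred <- pipeline_predict(config, fit, quiet = quiet)
  s <- pipeline_evaluate(config, fit, quiet = quiet)
  invisible(list(data = dat, fit = fit, predictions = pred, summary = s))
}
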