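#' @export
print.tamfit <- function(x, ...) {
  cat(sprintf("Tectonic accumulation model fit: %s, %s noise\n",
              x$variant, sub("_noise", "", x$noise)))
  cat(sprintf("  %d participants, %d free parameters per participant, seed %d\n",
              length(x$participants), x$n_free, x$seed))
  obj <- vapply(x$participants, function(p) sum(p$objective), numeric(1L))
  cat(sprintf("  total objective (sum over conditions): median %.4g, range %.4g-%.4g\n",
              median(obj), min(obj), max(obj)))
  if (!all(vapply(x$participants, `[[`, logical(1L), "converged")))
    cat("  warning: at least one optimizer stage did not converge\n")
  invisible(x)
}

#' Parameter estimates of a fitted model
#'
#' @param object a `"tamfit"` object.
#' @param ... unused.
#' @return Data frame with one row per participant-condition:
#'   `participant_id`, `condition`, the six model parameters, and the
#'   condition objective value.
#' @export
coef.tamfit <- function(object, ...) {
  out <- do.call(rbind, lapply(names(object$participants), function(pid) {
    p <- object$participants[[pid]]
    data.frame(participant_id = pid, condition = rownames(p$params),
               p$params, objective = unname(p$objective),
               row.names = NULL)
  }))
  out
}

#' Backfit predicted reaction times of a fitted model
#'
#' Runs the per-trial backfit for every participant-condition cell of the
#' fit: the noise values rank-paired during estimation are combined with the
#' final parameter estimates, and each trial's predicted RT is the evidence
#' threshold-crossing time.
#'
#' @param object a `"tamfit"` object.
#' @param ... unused.
#' @return Data frame: `participant_id`, `condition`, `trial_index`,
#'   `stimulus_level`, `x`, `rt_obs_ms`, `rt_pred_ms`.
#' @export
predict.tamfit <- function(object, ...) {
  out <- do.call(rbind, lapply(names(object$participants), function(pid) {
    p <- object$participants[[pid]]
    do.call(rbind, lapply(rownames(p$params), function(cond) {
      cc <- p$cells[[cond]]
      data.frame(participant_id = pid, condition = cond,
                 trial_index = cc$trial_index,
                 stimulus_level = cc$stimulus_level,
                 x = cc$x, rt_obs_ms = cc$rt_ms,
                 rt_pred_ms = backfit(p$params[cond, ], cc$x,
                                      cc$stimulus_level, object$constants),
                 row.names = NULL)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' @export
fitted.tamfit <- function(object, ...) predict(object)$rt_pred_ms

#' @export
residuals.tamfit <- function(object, ...) {
  p <- predict(object)
  p$rt_obs_ms - p$rt_pred_ms
}

#' Condition-level evaluation of a fitted model
#'
#' Computes, per condition, the Vincentized group quantile distributions of
#' observed and predicted RTs, the chi-square comparison of their
#' inter-quantile densities, and the pooled observed-predicted correlation;
#' plus the per-cell moment difference table.
#'
#' @param object a `"tamfit"` object.
#' @param n_quantiles quantile count for the group distributions.
#' @param ... unused.
#' @return An object of class `"summary.tamfit"`: list with `conditions`
#'   (data frame: condition, chi_square, df, p_value, mean RT
#'   observed/predicted), `pooled_r`, `moments` (moment difference table),
#'   `quantiles` (list per condition with observed/predicted group quantile
#'   means), and the fit's descriptors.
#' @export
summary.tamfit <- function(object, n_quantiles = 20L, ...) {
  pred <- predict(object)
  conds <- unique(pred$condition)
  quant <- lapply(conds, function(cond) {
    d <- pred[pred$condition == cond, ]
    list(observed = group_quantiles(
           data.frame(participant_id = d$participant_id, rt_ms = d$rt_obs_ms),
           n_quantiles),
         predicted = group_quantiles(
           data.frame(participant_id = d$participant_id, rt_ms = d$rt_pred_ms),
           n_quantiles))
  })
  names(quant) <- conds
  cond_tab <- do.call(rbind, lapply(conds, function(cond) {
    q <- quant[[cond]]
    cs <- chisq_quantiles(q$observed, q$predicted, n_quantiles)
    d <- pred[pred$condition == cond, ]
    data.frame(condition = cond, chi_square = cs$statistic, df = cs$df,
               p_value = cs$p_value,
               mean_obs_ms = mean(d$rt_obs_ms),
               mean_pred_ms = mean(d$rt_pred_ms))
  }))
  mom <- moment_table(
    data.frame(participant_id = pred$participant_id,
               condition = pred$condition, rt_ms = pred$rt_pred_ms),
    data.frame(participant_id = pred$participant_id,
               condition = pred$condition, rt_ms = pred$rt_obs_ms))
  structure(list(variant = object$variant, noise = object$noise,
                 n_free = object$n_free,
                 n_participants = length(object$participants),
                 conditions = cond_tab, pooled_r = cor(pred$rt_obs_ms,
                                                       pred$rt_pred_ms),
                 moments = mom, quantiles = quant),
            class = "summary.tamfit")
}

#' @export
print.summary.tamfit <- function(x, ...) {
  cat(sprintf("Model evaluation: %s, %s noise (%d free parameters, %d participants)\n",
              x$variant, sub("_noise", "", x$noise), x$n_free,
              x$n_participants))
  tab <- x$conditions
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  %-11s chi2(%d) = %6.2f (p = %.3f)  mean RT obs %.0f / pred %.0f ms\n",
                tab$condition[i], tab$df[i], tab$chi_square[i],
                tab$p_value[i], tab$mean_obs_ms[i], tab$mean_pred_ms[i]))
  cat(sprintf("  pooled observed-predicted correlation r = %.4f\n", x$pooled_r))
  invisible(x)
}

#' Vincentized density plot of observed vs predicted RT distributions
#'
#' One panel per condition: the 19 inter-quantile densities plotted as
#' smooth lines against the quantile midpoints, observed solid, predicted
#' dashed.
#'
#' @param x a `"tamfit"` object.
#' @param n_quantiles quantile count.
#' @param ... further arguments passed to [graphics::matplot()].
#' @return Invisibly, the `summary.tamfit` used for plotting.
#' @export
plot.tamfit <- function(x, n_quantiles = 20L, ...) {
  s <- summary(x, n_quantiles = n_quantiles)
  conds <- names(s$quantiles)
  old <- par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(par(old))
  for (cond in conds) {
    q <- s$quantiles[[cond]]
    mid_o <- (q$observed[-1L] + q$observed[-n_quantiles]) / 2
    mid_p <- (q$predicted[-1L] + q$predicted[-n_quantiles]) / 2
    d_o <- quantile_density(q$observed)
    d_p <- quantile_density(q$predicted)
    matplot(cbind(mid_o, mid_p), cbind(d_o, d_p), type = "l",
            lty = c(1, 2), col = c("black", "red3"),
            xlab = "RT (ms)", ylab = "density", main = cond, ...)
  }
  invisible(s)
}

#' Forward-simulate reaction times from a fitted model
#'
#' Draws fresh noise from the fit's noise source (for RP-noise, resamples
#' the participant-condition amplitude pools) and generates new trial RTs
#' from the fitted parameters by threshold crossing.
#'
#' @param object a `"tamfit"` object.
#' @param nsim number of simulated datasets.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return A list of `nsim` data frames (`participant_id`, `condition`,
#'   `stimulus_level`, `x`, `rt_ms`).
#' @export
simulate.tamfit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  one <- function() {
    do.call(rbind, lapply(names(object$participants), function(pid) {
      p <- object$participants[[pid]]
      do.call(rbind, lapply(rownames(p$params), function(cond) {
        cc <- p$cells[[cond]]
        n <- nrow(cc)
        x <- switch(object$noise,
                    gaussian = sample_noise("gaussian", n),
                    rectangular = sample_noise("rectangular", n),
                    rp_noise = sample(cc$x, n, replace = TRUE))
        data.frame(participant_id = pid, condition = cond,
                   stimulus_level = cc$stimulus_level, x = x,
                   rt_ms = backfit(p$params[cond, ], x, cc$stimulus_level,
                                   object$constants),
                   row.names = NULL)
      }))
    }))
  }
  replicate(nsim, one(), simplify = FALSE)
}
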