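test_that("objective matches the brute-force trial loop and its anchors", {
  par <- c(-1.3, -1.5, -1.6, -0.2, -1.0, -0.2)
  set.seed(30)
  x <- rnorm(10)
  level <- sample(1:3, 10, replace = TRUE)
  rt <- runif(10, 450, 900)
  expect_equal(objective(par, rt, level, x), oracle_objective(par, rt, level, x),
               tolerance = 1e-10)
  # zero exactly when each trial's evidence at its observed RT equals beta:
  # take RTs from the model's own crossing times
  sl <- tamrt:::trial_slopes(par, x)
  rt_star <- tamrt:::crossing_times(sl[, 1:3], sl[, 4], level)
  expect_equal(objective(par, rt_star, level, x), 0, tolerance = 1e-12)
  # single trial with evidence 0.9 contributes (1 - 0.9)^2
  k <- tam_constants()
  s1 <- tamrt:::trial_slopes(par, x[1])
  t9 <- uniroot(function(t) evidence(s1[1, 1:3], s1[1, 4], level[1], t, k) - 0.9,
                c(0, 5000), tol = 1e-12)$root
  expect_equal(objective(par, t9, level[1], x[1]), 0.01, tolerance = 1e-8)
  # invariant to trial order
  o <- sample(10)
  expect_equal(objective(par, rt[o], level[o], x[o]),
               objective(par, rt, level, x))
})

test_that("OLS links recover closed-form lines and compose with apply_link", {
  l <- fit_link(c(2, 4, 6, 8), c(1, 2, 3, 4))
  expect_equal(l$intercept, 0, tolerance = 1e-12)
  expect_equal(l$coefficient, 2, tolerance = 1e-12)
  expect_equal(apply_link(l, 1.5), 3.0)
  lc <- fit_link(c(5, 5, 5, 5), c(1, 2, 3, 4))
  expect_equal(lc$coefficient, 0, tolerance = 1e-12)
  expect_equal(lc$intercept, 5, tolerance = 1e-12)
  expect_equal(apply_link(lc, 10), 5)
  set.seed(31)
  for (rep in 1:20) {
    a <- rnorm(4); y <- rnorm(4)
    l <- fit_link(y, a)
    cf <- coef(lm(y ~ a))
    expect_equal(c(l$intercept, l$coefficient), unname(cf), tolerance = 1e-10)
  }
  # collinear points reproduce in-sample values exactly
  a <- c(2, 1.5, 1, 0.5); y <- -1.8 + 0.6 * a
  expect_equal(apply_link(fit_link(y, a), a), y, tolerance = 1e-10)
})

test_that("backfit satisfies its defining property and the scan oracle", {
  set.seed(32)
  par <- c(-1.4, -1.4, -1.5, -0.25, -1.1, -0.25)
  x <- rnorm(30)
  level <- sample(1:3, 30, replace = TRUE)
  rt <- backfit(par, x, level)
  k <- tam_constants()
  for (i in seq_len(30)) {
    sl <- tamrt:::trial_slopes(par, x[i])
    expect_equal(evidence(sl[1, 1:3], sl[1, 4], level[i], rt[i], k), 1,
                 tolerance = 1e-6)
    expect_lt(abs(rt[i] - oracle_scan_rt(sl[1, 1:3], sl[1, 4], level[i])), 1)
  }
})

test_that("forward-simulated data round-trips through the backfit", {
  # RTs generated from known parameters and x, backfit with the same
  # parameters and x: per-trial equality
  set.seed(33)
  par <- c(-1.3, -1.45, -1.6, -0.22, -0.9, -0.2)
  x <- rnorm(100)
  level <- sample(1:3, 100, replace = TRUE)
  rt_fwd <- backfit(par, x, level)
  expect_lt(max(abs(backfit(par, x, level) - rt_fwd)), 1)
  # and the estimation objective is exactly zero at the truth
  expect_equal(objective(par, rt_fwd, level, x), 0, tolerance = 1e-10)
})

test_that("with zero swell the noise source is irrelevant", {
  par <- c(-1.3, -1.4, -1.5, 0, -1.0, 0)
  level <- rep(1:3, 10)
  rt_g <- backfit(par, rnorm(30), level)
  rt_r <- backfit(par, runif(30, -2, 2), level)
  expect_equal(rt_g, rt_r, tolerance = 1e-9)
  expect_equal(length(unique(round(rt_g, 6))), 3L)   # one RT per target level
})

test_that("estimation is a fixed point at the truth and seed-reproducible", {
  dat <- small_dataset(n_participants = 1, seed = 34)
  tr <- dat$trials
  tr1 <- tr[tr$participant_id == "P01" & tr$condition == "baseline" &
              tr$stimulus_role == "target" & tr$correct == 1, ]
  truth_p <- dat$truth$participants$P01
  par_true <- c(truth_p$tstart, truth_p$tswell,
                truth_p$dstart[["baseline"]], truth_p$dswell)
  # generated RTs carry zero objective at the generating parameters + x
  expect_equal(objective(par_true, tr1$rt_ms, tr1$stimulus_level, tr1$x),
               0, tolerance = 1e-9)
  # one Nelder-Mead start at the truth stays there
  ctl <- tamrt:::default_control(list(restarts = 1))
  fit0 <- tamrt:::nm_fit(par_true, 1:6, tr1$rt_ms, tr1$stimulus_level,
                         tr1$x, tam_constants(), ctl)
  expect_lt(fit0$value, 1e-8)
  expect_equal(fit0$par, par_true, tolerance = 0.05)

  f1 <- tam_fit(dat, "inhibition_only", "gaussian", seed = 99,
                control = list(restarts = 2, maxit = 400))
  f2 <- tam_fit(dat, "inhibition_only", "gaussian", seed = 99,
                control = list(restarts = 2, maxit = 400))
  expect_identical(coef(f1), coef(f2))
  expect_true(all(coef(f1)$objective >= 0))
})

test_that("variant bookkeeping: free-parameter counts and carried estimates", {
  dat <- small_dataset(n_participants = 1, seed = 35)
  fi <- tam_fit(dat, "inhibition_only", "gaussian", seed = 1,
                control = list(restarts = 2, maxit = 600))
  fe <- tam_fit(dat, "excitation_only", "gaussian", seed = 1,
                control = list(restarts = 2, maxit = 600))
  expect_equal(fi$n_free, 9L)
  expect_equal(fe$n_free, 15L)
  ci <- coef(fi); ce <- coef(fe)
  # inhibition-only: everything but dstart identical across conditions
  for (p in c("tstart_1", "tstart_2", "tstart_3", "tswell", "dswell"))
    expect_equal(length(unique(ci[[p]])), 1L)
  expect_gt(length(unique(ci$dstart)), 1L)
  # excitation-only: dstart, dswell, tswell carried from baseline
  for (p in c("tswell", "dstart", "dswell"))
    expect_equal(length(unique(ce[[p]])), 1L)
  expect_gt(length(unique(ce$tstart_1)), 1L)
})

test_that("EEG-linked variants expose their links with linked parameters", {
  dat <- small_dataset(n_participants = 1, seed = 36, noise = "rp")
  fr <- tam_fit(dat, "rp", "rp_noise", seed = 1,
                control = list(restarts = 2, maxit = 600))
  expect_equal(fr$n_free, 7L)
  p1 <- fr$participants$P01
  expect_s3_class(p1$link, "tam_link")
  # the per-condition dstart follows the link applied to the RP means
  amps <- tamrt:::mean_amplitudes(
    dat$trials[dat$trials$participant_id == "P01", ],
    dat$amplitudes[dat$amplitudes$participant_id == "P01", ], "distractor")
  expect_equal(unname(p1$params[, "dstart"]),
               unname(apply_link(p1$link, amps)), tolerance = 1e-10)

  fp <- tam_fit(dat, "pn", "rp_noise", seed = 1,
                control = list(restarts = 2, maxit = 600))
  expect_equal(fp$n_free, 9L)
  expect_length(fp$participants$P01$link, 3L)
})
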