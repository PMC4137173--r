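test_that("activation functions hit their closed-form anchors and bounds", {
  # logistic(0)^10 at t = 0, independent of slope
  expect_equal(act_target(0.5, 0), 0.5^10)
  expect_equal(act_target(0.023, 0), 0.5^10)
  expect_equal(act_target(0.01, 500), 0.935051674017987, tolerance = 1e-12)
  expect_equal(act_target(0.023, 4000), 1, tolerance = 1e-9)

  expect_equal(act_nontarget(0.01, 500), -0.935051674017987,
               tolerance = 1e-12)
  expect_equal(act_nontarget(0.3, 0), -0.5^10)
  expect_equal(act_nontarget(0.023, 4000), -1, tolerance = 1e-9)

  expect_equal(act_distractor(0.01, 500), -2.80515502205396,
               tolerance = 1e-12)
  expect_equal(act_distractor(0.7, 0), -3 * 0.5^10)
  expect_equal(act_distractor(0.023, 4000), -3, tolerance = 1e-9)

  expect_error(act_target(NaN, 1), "non-finite")
  expect_error(act_target(0.01, Inf), "non-finite")
  expect_error(act_target(-0.01, 10), "non-negative")
})

test_that("activation is strictly monotone in t", {
  tt <- seq(0, 3000, by = 7)
  a <- act_target(0.004, tt)
  expect_true(all(diff(a) > 0))
  expect_true(all(a > 0 & a < 1))
  expect_true(all(diff(act_nontarget(0.004, tt)) < 0))
})

test_that("evidence matches the term-by-term oracle and its anchors", {
  # t = 0 value is slope-independent
  for (sl in list(rep(0.01, 3), c(0.02, 0.001, 0.015))) {
    expect_equal(evidence(sl, 0.007, 2, 0), 0.000976880572638907,
                 tolerance = 1e-12)
  }
  expect_equal(evidence(rep(0.01, 3), 0.01, 1, 500), 1.6553710608016,
               tolerance = 1e-10)
  # supremum log 7 at the default constants
  expect_equal(evidence(rep(0.023, 3), 0.023, 1, 1e7), log(7),
               tolerance = 1e-9)

  set.seed(42)
  for (rep in 1:25) {
    s <- random_slope_set()
    pres <- sample(1:3, 1)
    t <- runif(1, 0, 2000)
    expect_equal(evidence(s$slope_t, s$slope_d, pres, t),
                 oracle_evidence(s$slope_t, s$slope_d, pres, t),
                 tolerance = 1e-12)
  }
})

test_that("evidence is strictly increasing and bounded on dense grids", {
  set.seed(7)
  # grid kept below activation saturation in double precision; beyond it the
  # mathematical strict increase flattens to machine equality at log 7
  tt <- seq(0, 1200, by = 7)
  for (rep in 1:10) {
    s <- random_slope_set()
    e <- evidence(s$slope_t, s$slope_d, sample(1:3, 1), tt)
    expect_true(all(diff(e) > 0))
    expect_true(all(e > 0 & e < log(7)))
  }
})

test_that("constants invariants are enforced", {
  expect_error(tam_constants(evidence_constant = 4.9), "too small")
  expect_error(tam_constants(threshold_beta = 2.1), "not reachable")
  expect_silent(k <- tam_constants())
  expect_equal(attr(k, "evidence_sup"), log(7))
})

test_that("threshold crossing: bisection and integer scan agree within 1 ms", {
  set.seed(99)
  for (rep in 1:100) {
    s <- random_slope_set()
    pres <- sample(1:3, 1)
    rt_b <- try(predict_rt(s$slope_t, s$slope_d, pres), silent = TRUE)
    if (inherits(rt_b, "try-error")) next   # no crossing inside max_cycles
    rt_s <- predict_rt(s$slope_t, s$slope_d, pres, method = "scan")
    expect_lt(abs(rt_b - rt_s), 1)
    expect_equal(rt_s, oracle_scan_rt(s$slope_t, s$slope_d, pres))
    # defining property of the continuous solve
    expect_equal(evidence(s$slope_t, s$slope_d, pres, rt_b), 1,
                 tolerance = 1e-6)
  }
})

test_that("degenerate crossings behave as specified", {
  # threshold below the t = 0 evidence: RT 0
  k_low <- tam_constants(threshold_beta = 0.0009)
  expect_equal(predict_rt(rep(0.01, 3), 0.01, 1, constants = k_low), 0)
  # all slopes ~0: evidence stuck near its t = 0 value, crossing impossible
  expect_error(predict_rt(rep(0, 3), 0, 1),
               class = "tam_max_cycles_error")
})

test_that("predicted RT decreases when any inhibitory slope grows", {
  base <- list(slope_t = c(0.006, 0.005, 0.004), slope_d = 0.004)
  rt0 <- predict_rt(base$slope_t, base$slope_d, 1)
  for (sd_ in seq(0.005, 0.02, by = 0.003)) {
    rt1 <- predict_rt(base$slope_t, sd_, 1)
    expect_lte(rt1, rt0)
    rt0 <- rt1
  }
  # and in the presented-target slope
  rts <- vapply(seq(0.004, 0.02, by = 0.004), function(s)
    predict_rt(c(s, 0.005, 0.004), 0.004, 1), numeric(1))
  expect_true(all(diff(rts) < 0))
})

test_that("slope equations follow the scaled logistic", {
  expect_equal(target_slope(0, 5, 0), 0.0115)
  expect_equal(target_slope(50, 1, 0), 0.023, tolerance = 1e-9)
  expect_equal(target_slope(1, 2, 0.5), 0.0202583327934913, tolerance = 1e-12)
  expect_equal(distractor_slope(0, 5, 0), 0.0115)
  expect_equal(distractor_slope(1, 2, 0.5), target_slope(1, 2, 0.5))
  # monotone in x when swell is nonzero, flat when zero
  xs <- seq(-3, 3, by = 0.5)
  expect_true(all(diff(target_slope(0, 1, xs)) > 0))
  expect_true(all(diff(target_slope(0, -1, xs)) < 0))
  expect_equal(length(unique(target_slope(0.3, 0, xs))), 1L)
  # strictly inside (0, 0.023)
  sl <- target_slope(rnorm(1), rnorm(1), rnorm(100))
  expect_true(all(sl > 0 & sl < 0.023))
})

test_that("vectorised crossing solver matches the scalar one", {
  set.seed(5)
  n <- 40
  sm <- matrix(runif(n * 3, 1e-3, 0.023), ncol = 3)
  sd_ <- runif(n, 1e-3, 0.023)
  lvl <- sample(1:3, n, replace = TRUE)
  rt_vec <- tamrt:::crossing_times(sm, sd_, lvl)
  rt_ind <- vapply(seq_len(n), function(i)
    predict_rt(sm[i, ], sd_[i], lvl[i]), numeric(1))
  expect_equal(rt_vec, rt_ind, tolerance = 1e-6)
})
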