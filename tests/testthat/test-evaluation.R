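test_that("vincentizing matches its binning oracle and preserves the mean", {
  expect_equal(vincentize(sample(1:20)), as.numeric(1:20))
  expect_equal(vincentize(1:40), seq(1.5, 39.5, by = 2))
  set.seed(20)
  for (n in c(47, 100, 153)) {
    v <- runif(n, 300, 900)
    q <- vincentize(v)
    expect_equal(q, oracle_vincentize(v))
    expect_true(all(diff(q) >= 0))
    # grand mean preserved under the size-weighted bin means
    sizes <- rep(n %/% 20, 20); r <- n %% 20
    if (r > 0) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1
    expect_equal(sum(q * sizes) / n, mean(v), tolerance = 1e-12)
  }
  expect_error(vincentize(1:19), "at least 20")
})

test_that("group distributions average participants quantile-wise", {
  one <- runif(60, 400, 800)
  expect_equal(group_quantiles(list(one)), vincentize(one))
  expect_equal(group_quantiles(list(one, one)), vincentize(one))
  set.seed(21)
  parts <- lapply(1:5, function(i) runif(40 + i, 400, 800))
  g <- group_quantiles(parts)
  expect_equal(g, rowMeans(sapply(parts, oracle_vincentize)))
})

test_that("quantile densities follow P(i) = 50 / spacing", {
  expect_equal(quantile_density(seq(100, 290, by = 10)), rep(5, 19))
  expect_equal(quantile_density(seq(0, 950, by = 50)), rep(1, 20 - 1))
  set.seed(22)
  q <- cumsum(c(400, runif(19, 1, 40)))
  expect_equal(quantile_density(q), 50 / diff(q))
  expect_warning(quantile_density(c(1, 1, 2)), "zero quantile spacing")
})

test_that("chi-square on densities is zero iff identical, df 17", {
  q <- cumsum(c(400, runif(19, 5, 40)))
  cs <- chisq_quantiles(q, q)
  expect_equal(cs$statistic, 0)
  expect_equal(cs$df, 17)
  expect_equal(cs$p_value, 1)
  # a single discrepant cell gives the closed-form contribution
  q2 <- q; q2[20] <- q2[20] + 25
  p_obs <- 50 / diff(q); p_pred <- 50 / diff(q2)
  expect_equal(chisq_quantiles(q, q2)$statistic,
               sum((p_obs - p_pred)^2 / p_pred))
  expect_gt(chisq_quantiles(q, q2)$statistic, 0)
  set.seed(23)
  qa <- cumsum(c(420, runif(19, 5, 40)))
  qb <- cumsum(c(430, runif(19, 5, 40)))
  expect_equal(chisq_quantiles(qa, qb)$statistic,
               sum((50 / diff(qa) - 50 / diff(qb))^2 / (50 / diff(qb))))
})

test_that("moments use population denominators and the excess term", {
  m <- rt_moments(c(1, 2, 3))
  expect_equal(m$mean, 2)
  expect_equal(m$dispersion, sqrt(2 / 3))
  expect_equal(m$skewness, 0)
  expect_equal(m$kurtosis, -1.5)
  # any symmetric sample has zero skewness
  expect_equal(rt_moments(c(2, 4, 6, 8, 10))$skewness, 0)
  set.seed(24)
  z <- rnorm(1e5)
  mz <- rt_moments(z)
  expect_equal(mz$skewness, 0, tolerance = 0.05)
  expect_equal(mz$kurtosis, 0, tolerance = 0.05)
  # oracle on arbitrary data; location shift moves only the mean
  r <- rexp(500, 1 / 100) + 400
  expect_equal(unlist(rt_moments(r)), oracle_moments(r))
  sh <- rt_moments(r + 5)
  expect_equal(sh$mean, rt_moments(r)$mean + 5)
  expect_equal(sh$dispersion, rt_moments(r)$dispersion)
  expect_equal(sh$skewness, rt_moments(r)$skewness)
  expect_equal(sh$kurtosis, rt_moments(r)$kurtosis)
})

test_that("moment difference table is predicted minus observed per cell", {
  set.seed(25)
  obs <- data.frame(participant_id = rep(c("P01", "P02"), each = 50),
                    condition = "baseline",
                    rt_ms = runif(100, 400, 900))
  tab0 <- moment_table(obs, obs)
  expect_equal(tab0$difference, rep(0, 8))
  shifted <- obs; shifted$rt_ms <- shifted$rt_ms + 5
  tab5 <- moment_table(shifted, obs)
  expect_equal(tab5$difference[tab5$moment == "mean"], c(5, 5))
  expect_equal(tab5$difference[tab5$moment != "mean"], rep(0, 6),
               tolerance = 1e-9)
  p1 <- obs$rt_ms[obs$participant_id == "P01"]
  expect_equal(tab5$observed[tab5$moment == "dispersion"][1],
               unname(oracle_moments(p1)["dispersion"]))
})
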