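test_that("the trial schedule reproduces the experimental design", {
  d <- make_design(n_participants = 2, seed = 40)
  expect_equal(nrow(d), 2 * 4 * 300)
  one <- d[d$participant_id == "P01" & d$condition == "filtering2", ]
  expect_equal(nrow(one), 300)
  expect_equal(sum(one$stimulus_role == "target"), 150)
  expect_equal(sum(one$stimulus_role == "distractor"), 150)
  # 50 trials per stimulus
  counts <- table(one$stimulus_role, one$stimulus_level)
  expect_true(all(counts == 50))
  # frequency table: targets constant, distractor range widens
  expect_setequal(unique(one$frequency_hz[one$stimulus_role == "target"]),
                  c(962, 1000, 1040))
  expect_setequal(unique(one$frequency_hz[one$stimulus_role == "distractor"]),
                  c(954, 1020, 1090))
  base <- d[d$condition == "baseline" & d$stimulus_role == "distractor", ]
  expect_true(all(base$frequency_hz == 1020))
  expect_true(all(d$isi_ms >= 1450 & d$isi_ms <= 1600))
  expect_identical(d, make_design(n_participants = 2, seed = 40))
})

test_that("generated amplitudes follow the condition means and roundtrip", {
  truth <- ground_truth(n_participants = 1, seed = 41, trial_sd_uv = 0)
  design <- make_design(1, seed = 41)
  a0 <- gen_amplitudes(truth, design, seed = 41)
  # zero trial SD: distractor amplitudes equal the condition mean exactly
  da <- a0[design$stimulus_role == "distractor", ]
  for (cond in unique(da$condition))
    expect_equal(unique(da$fz_mean_uv[da$condition == cond]),
                 unname(truth$rp_mean_uv[cond]))
  # condition means recovered within CLT tolerance at 150 trials
  truth1 <- ground_truth(n_participants = 1, seed = 41, trial_sd_uv = 1)
  a1 <- gen_amplitudes(truth1, design, seed = 41)
  da1 <- a1[design$stimulus_role == "distractor", ]
  for (cond in unique(da1$condition))
    expect_equal(mean(da1$fz_mean_uv[da1$condition == cond]),
                 unname(truth1$rp_mean_uv[cond]), tolerance = 0.3)
  # the generative RP pattern is monotone decreasing with salience
  expect_true(all(diff(truth$rp_mean_uv) < 0))
})

test_that("simulated RTs express the generative ordering and determinism", {
  dat <- simulate_experiment(n_participants = 2, seed = 42, noise = "gaussian")
  tr <- dat$trials
  tgt <- tr[tr$stimulus_role == "target", ]
  expect_true(all(!is.na(tgt$rt_ms)))
  expect_true(all(is.na(tr$rt_ms[tr$stimulus_role == "distractor"])))
  # dstart decreases across conditions, so mean RT increases
  m <- tapply(tgt$rt_ms, tgt$condition, mean)[c("baseline", "filtering1",
                                                "filtering2", "filtering3")]
  expect_true(all(diff(m) > 0))
  # error rate ~5%: correct trial count near 150 * 0.95 per cell
  cc <- tapply(tgt$correct, list(tgt$participant_id, tgt$condition), sum)
  expect_true(all(cc > 120 & cc <= 150))
  expect_true(abs(mean(cc) - 150 * 0.95) < 5)
  # bit-identical rerun under the same master seed
  dat2 <- simulate_experiment(n_participants = 2, seed = 42,
                              noise = "gaussian")
  expect_identical(dat$trials, dat2$trials)
  expect_identical(dat$amplitudes, dat2$amplitudes)
})

test_that("zero swell makes every RT in a cell identical", {
  truth <- ground_truth(n_participants = 1, seed = 43)
  truth$participants$P01$tswell <- 0
  truth$participants$P01$dswell <- 0
  design <- make_design(1, seed = 43)
  tr <- simulate_rts(truth, design, "gaussian", seed = 43)
  cell <- tr[tr$condition == "baseline" & tr$stimulus_role == "target" &
               tr$stimulus_level == 2, ]
  expect_equal(length(unique(round(cell$rt_ms, 6))), 1L)
})

test_that("datasets write and read back exactly", {
  dat <- simulate_experiment(n_participants = 1, seed = 44, noise = "rp")
  dir <- file.path(tempdir(), "tam-ds-test")
  write_dataset(dat, dir)
  expect_true(all(file.exists(file.path(dir, c("trials.csv",
                                               "amplitudes.csv",
                                               "truth.json")))))
  back <- read_dataset(dir)
  expect_equal(back$trials$rt_ms, dat$trials$rt_ms)
  expect_equal(back$amplitudes$fz_mean_uv, dat$amplitudes$fz_mean_uv)
  expect_equal(back$truth$participants$P01$dstart,
               dat$truth$participants$P01$dstart, tolerance = 1e-12)
  expect_identical(back$noise_source, "rp")
  # schema validation on a broken table
  broken <- dat$trials[, setdiff(names(dat$trials), "rt_ms")]
  write.csv(broken, file.path(dir, "trials.csv"), row.names = FALSE)
  expect_error(read_dataset(dir), "missing columns")
  unlink(dir, recursive = TRUE)
})
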