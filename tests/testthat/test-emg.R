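test_that("trial epochs tile [t-d, t+2d) with equal sample counts", {
  emg <- time_series(rnorm(30000), 1000, label = "emg", units = "mV")
  pr <- time_series(rnorm(600, 10), 20, label = "pressure", units = "cmH2O")
  ep <- epoch_trial(emg, pr, onset_s = 15, duration_s = 5)
  expect_identical(lengths(ep$emg[c("before", "stim", "after")]),
                   c(before = 5000L, stim = 5000L, after = 5000L))
  # contiguous, no overlap or gap: concatenation equals the direct slice
  expect_identical(c(ep$emg$before, ep$emg$stim, ep$emg$after),
                   emg$values[(10 * 1000 + 1):(25 * 1000)])
  expect_identical(length(ep$pressure$before), 100L)
  # stim too close to the trace start is out of bounds
  expect_error(epoch_trial(emg, NULL, onset_s = 3, duration_s = 5),
               "out of bounds")
})

test_that("total power matches closed forms and Parseval equivalence", {
  expect_identical(total_power(rep(0, 100)), 0)
  # sine of amplitude A over integer cycles: sum of squares = N A^2 / 2
  for (A in c(0.5, 2)) {
    n <- 1000
    x <- A * sin(2 * pi * 5 * (0:(n - 1)) / n)
    expect_equal(total_power(x), n * A^2 / 2, tolerance = 1e-9)
    # brute-force loop oracle
    expect_equal(total_power(x), sum(vapply(x - mean(x), function(v) v^2,
                                            numeric(1))), tolerance = 1e-12)
  }
  # frequency- and time-domain forms agree to 1e-9 relative
  set.seed(13)
  for (i in 1:100) {
    x <- rnorm(sample(100:2000, 1), mean = runif(1, -1, 1))
    tp <- total_power(x); tf <- total_power_freq(x)
    expect_lt(abs(tp - tf) / tp, 1e-9)
  }
  # DC retention switch
  x <- rnorm(500, mean = 2)
  expect_equal(total_power(x, remove_dc = FALSE), sum(x^2), tolerance = 1e-12)
})

test_that("epoch normalization satisfies its identities", {
  n1 <- normalize_epochs(1, 1, 1)
  expect_equal(c(n1$norm_before, n1$norm_stim, n1$norm_after),
               rep(100 / 3, 3), tolerance = 1e-12)
  n2 <- normalize_epochs(2, 1, 1)
  expect_equal(c(n2$norm_before, n2$norm_stim, n2$norm_after), c(50, 25, 25))
  set.seed(14)
  for (i in 1:200) {
    v <- runif(3, 0.01, 100)
    nn <- normalize_epochs(v[1], v[2], v[3])
    expect_lt(abs(nn$norm_before + nn$norm_stim + nn$norm_after - 100), 1e-9)
    # scale invariance: multiplying all EMG samples by k leaves shares alone
    nk <- normalize_epochs(9 * v[1], 9 * v[2], 9 * v[3])
    expect_equal(c(nk$norm_before, nk$norm_stim, nk$norm_after),
                 c(nn$norm_before, nn$norm_stim, nn$norm_after),
                 tolerance = 1e-9)
  }
  z <- normalize_epochs(0, 0, 0)
  expect_true(z$flagged)
  expect_true(is.na(z$norm_stim))
  expect_error(normalize_epochs(-1, 1, 1), ">= 0")
})

test_that("baseline artifacts exclude trials; stim artifacts never do", {
  p <- small_opto_params(seed = 15, n_stim_trials = 12,
                         emg_artifact_prob = 0.5,
                         emg_stim_artifact_prob = 0.5)
  trials <- make_stim_trials(p)
  emg <- simulate_emg(trials, p)
  # detection path: no ground-truth flags supplied
  tab <- build_trial_table(emg, NULL,
                           trials[c("trial_id", "onset_s", "duration_s")],
                           animal_id = "m1")
  expect_identical(tab$baseline_artifact, trials$baseline_artifact)
  kept <- exclude_artifact_trials(tab)
  expect_identical(kept$trial_id, trials$trial_id[!trials$baseline_artifact])
  # trials with only stim-phase artifacts are all retained
  stim_only <- trials$stim_artifact & !trials$baseline_artifact
  expect_true(all(trials$trial_id[stim_only] %in% kept$trial_id))
  # no artifacts -> identity
  clean <- tab; clean$baseline_artifact <- FALSE
  expect_identical(exclude_artifact_trials(clean), clean)
})

test_that("response rates recover programmed relaxation and reject pure filling", {
  # 10 trials, 7 with real relaxation -> 70% EMG response
  p <- small_opto_params(seed = 16, n_stim_trials = 10,
                         emg_relaxation_depth = 0.5)
  trials <- make_stim_trials(p)
  trials$relaxation <- rep(c(TRUE, FALSE), c(7, 3))
  emg <- simulate_emg(trials, p)
  pr <- simulate_opto_pressure(trials, p)
  tab <- build_trial_table(emg, pr, trials, animal_id = "m1")
  rr <- response_rates(tab)
  expect_equal(rr$emg_response_pct, 70)
  # pure filling ramp, no evoked contraction: trend correction removes the
  # ramp so the CMG response rate is 0
  expect_equal(rr$cmg_response_pct, 0)
  expect_identical(rr$n_trials, 10L)

  # noiseless analytic ramp case: predicted stim mean equals the actual
  pnn <- small_opto_params(seed = 17, n_stim_trials = 4,
                           noise_pressure_sd_cmh2o = 0,
                           infusion_rate_ul_min = 30,
                           compliance_cmh2o_per_ul = 0.1)
  tnn <- make_stim_trials(pnn)
  prn <- simulate_opto_pressure(tnn, pnn)
  en <- simulate_emg(tnn, pnn)
  tabn <- build_trial_table(en, prn, tnn, animal_id = "m1")
  expect_lt(max(abs(tabn$cmg_stim - tabn$cmg_stim_pred)), 1e-6)
})

test_that("per-animal trial subsampling is seeded and balanced", {
  tab <- data.frame(trial_id = sprintf("t%02d", 1:30),
                    animal_id = rep(c("a", "b", "c"), each = 10),
                    ttp_before = 1, ttp_stim = 1, ttp_after = 1)
  s <- subsample_trials(tab, 4, seed = 2)
  expect_true(all(table(s$animal_id) == 4))
  expect_identical(subsample_trials(tab, 4, seed = 2), s)
  expect_error(subsample_trials(tab, 11, seed = 2), "fewer than")
})
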