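test_that("noiseless cystometry fill ramp has exactly the programmed slope", {
  p <- sim_params(duration_s = 600, n_voids = 0, n_nvcs = 0,
                  noise_pressure_sd_cmh2o = 0, seed = 1)
  cm <- simulate_cmg(p)
  slope_true <- p$infusion_rate_ul_min / 60 * p$compliance_cmh2o_per_ul
  fd <- diff(cm$pressure$values) * cm$pressure$fs  # finite-difference oracle
  expect_lt(max(abs(fd - slope_true)), 1e-9)
  expect_equal(cm$truth$fill_slope_cmh2o_s, slope_true)
  expect_identical(nrow(cm$truth$events), 0L)
})

test_that("programmed event counts and window margins are honored", {
  p <- small_params(seed = 7, n_voids = 5, n_nvcs = 3, duration_s = 1400)
  cm <- simulate_cmg(p)
  ev <- cm$truth$events
  expect_identical(sum(ev$kind == "void"), 5L)
  expect_identical(sum(ev$kind == "nvc"), 3L)
  expect_true(all(ev$t_align_true > 60 & ev$t_align_true < 1400 - 60))
  expect_true(min(diff(sort(ev$t_align_true))) > 120)
  # too-dense request errors rather than producing overlapping windows
  expect_error(simulate_cmg(sim_params(duration_s = 400, n_voids = 5,
                                       n_nvcs = 3)),
               "overlap")
})

test_that("photometry generator injects shared artifacts and void-locked transients", {
  # artifact present with identical shape in both channels at the known time
  p <- small_params(seed = 3, transient_amp = 0, n_voids = 1, n_nvcs = 0,
                    motion_artifact_rate_per_min = 1,
                    noise_photometry_sd_au = 0)
  cm <- simulate_cmg(p)
  ph <- simulate_photometry(cm$truth, p)
  expect_gt(length(ph$truth$artifact_times), 0)
  t <- ts_time(ph$ch465)
  bleach465 <- p$f465_scale * (p$bleach_c + p$bleach_a1 * exp(-t / p$bleach_tau1_s) +
                                 p$bleach_a2 * exp(-t / p$bleach_tau2_s))
  bleach405 <- p$f405_scale * (p$bleach_c + p$bleach_a1 * exp(-t / p$bleach_tau1_s) +
                                 p$bleach_a2 * exp(-t / p$bleach_tau2_s))
  m465 <- ph$ch465$values - bleach465
  m405 <- ph$ch405$values - bleach405
  expect_equal(m465, m405, tolerance = 1e-12)  # zero transient amp, scale 1
  a1 <- ph$truth$artifact_times[1]
  w <- abs(t - a1) < 0.2
  expect_gt(max(abs(m465[w])), 0.8 * p$artifact_amp_au)

  # transient kernel integral matches the closed form (quadrature oracle)
  tr <- 0.5; td <- 4
  x <- seq(0, 80, by = 1e-3)
  k <- lutphysio:::transient_kernel(x, tr, td)
  expect_equal(max(k), 1, tolerance = 1e-6)  # peak-normalized
  tpk <- log(td / tr) * td * tr / (td - tr)
  pknorm <- exp(-tpk / td) - exp(-tpk / tr)
  expect_equal(sum(k) * 1e-3, (td - tr) / pknorm, tolerance = 1e-3)
})

test_that("EMG relaxation scales epoch power by (1 - depth)^2", {
  p <- small_opto_params(seed = 11, n_stim_trials = 6,
                         emg_relaxation_depth = 0.5, relax_prob = 1)
  trials <- make_stim_trials(p)
  emg <- simulate_emg(trials, p)
  ratios <- vapply(seq_len(nrow(trials)), function(i) {
    ep <- epoch_trial(emg, NULL, trials$onset_s[i], trials$duration_s[i])
    # brute-force sums of squares, not total_power, as the oracle
    sum((ep$emg$stim - mean(ep$emg$stim))^2) /
      sum((ep$emg$before - mean(ep$emg$before))^2)
  }, numeric(1))
  expect_equal(mean(ratios), 0.25, tolerance = 0.05)

  # depth 0 -> stationary power across epochs within sampling error
  p0 <- small_opto_params(seed = 12, n_stim_trials = 6,
                          emg_relaxation_depth = 0, relax_prob = 1)
  trials0 <- make_stim_trials(p0)
  emg0 <- simulate_emg(trials0, p0)
  r0 <- vapply(seq_len(nrow(trials0)), function(i) {
    ep <- epoch_trial(emg0, NULL, trials0$onset_s[i], trials0$duration_s[i])
    total_power(ep$emg$stim) / total_power(ep$emg$before)
  }, numeric(1))
  expect_equal(mean(r0), 1, tolerance = 0.15)
})

test_that("programmed relaxation fraction is recovered within the binomial CI", {
  p <- small_opto_params(seed = 5, n_stim_trials = 200, relax_prob = 0.75)
  trials <- make_stim_trials(p)
  phat <- mean(trials$relaxation)
  ci <- 0.75 + c(-1, 1) * 1.96 * sqrt(0.75 * 0.25 / 200)
  expect_gt(phat, ci[1])
  expect_lt(phat, ci[2])
})

test_that("generators are bitwise deterministic given (params, seed)", {
  p <- small_params(seed = 9)
  a <- simulate_cmg(p); b <- simulate_cmg(p)
  expect_identical(a$pressure$values, b$pressure$values)
  pa <- simulate_photometry(a$truth, p); pb <- simulate_photometry(b$truth, p)
  expect_identical(pa$ch465$values, pb$ch465$values)
  po <- small_opto_params(seed = 9, n_stim_trials = 3)
  ta <- make_stim_trials(po)
  expect_identical(simulate_emg(ta, po)$values, simulate_emg(ta, po)$values)
  fa <- simulate_thermal_frame(spot_spec(100, 100, 10), seed = 9)
  fb <- simulate_thermal_frame(spot_spec(100, 100, 10), seed = 9)
  expect_identical(fa$image, fb$image)
})

test_that("thermal frames rasterize spots at their analytic areas", {
  # circular spot of radius r: pixel count within 2% of pi r^2
  for (r in c(10, 18, 25)) {
    fr <- simulate_thermal_frame(spot_spec(cx = 160, cy = 120, rx = r),
                                 noise_sd = 0, seed = 2)
    a <- fr$truth$area_px[fr$truth$spot_id == "spot01"]
    expect_lt(abs(a - pi * r^2) / (pi * r^2), 0.02)
  }
  # template pixel count is exact by construction
  fr <- simulate_thermal_frame(spot_spec(numeric(0), numeric(0), numeric(0)),
                               template_px_w = 50, template_px_h = 40, seed = 1)
  expect_identical(fr$truth$area_px[fr$truth$spot_id == "template"], 2000L)
  # zero spots -> only the template segments above threshold
  regions <- segment_spots(fr$image)
  expect_identical(nrow(regions), 1L)
  # out-of-frame spot is a generation error
  expect_error(simulate_thermal_frame(spot_spec(cx = 5, cy = 120, rx = 10)),
               "out of frame")
})

test_that("marking generator matches its programmed rate and archetypes", {
  # rate 0 -> no marks, latency censored at session end
  s0 <- simulate_marking_session("custom", mark_rate_per_min = 0, seed = 1)
  expect_identical(nrow(s0$events), 0L)
  mm <- marking_metrics(numeric(0), s0$stimulus_time_s, s0$duration_s)
  expect_true(mm$latency_censored)
  expect_identical(mm$latency_s, s0$duration_s - s0$stimulus_time_s)

  # dominant archetype passes the >=10-mark, <=5-min screen
  sd_ <- simulate_marking_session("dominant", seed = 2)
  md <- marking_metrics(sd_$events$t_align_s, sd_$stimulus_time_s,
                        sd_$duration_s)
  expect_true(md$dominant)
  expect_gte(md$mark_count, 10)
  expect_lte(md$latency_s, 300)

  # Poisson oracle: mean count over 100 seeds matches rate x duration
  rate <- 0.4; counts <- vapply(1:100, function(s)
    nrow(simulate_marking_session("custom", mark_rate_per_min = rate,
                                  seed = s)$events), numeric(1))
  lam <- rate * (3600 - 600) / 60  # 20 expected marks
  se <- sqrt(lam / 100)
  expect_lt(abs(mean(counts) - lam), 3 * se)
})
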