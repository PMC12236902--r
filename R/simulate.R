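#' Parameters of the synthetic session generator
#'
#' Defaults emulate a standard awake-mouse filling cystometry session:
#' continuous saline infusion at 20 uL/min for 2 h, six voiding contractions
#' and four non-voiding contractions (NVCs), GCaMP transients time-locked to
#' void onset with double-exponential photobleaching and motion artifacts
#' shared across the 465/405 photometry channels, and tonic EUS-EMG with
#' relaxation during a programmed fraction of optogenetic stimulations.
#'
#' @param duration_s session length in seconds.
#' @param fs_pressure,fs_photometry,fs_emg per-channel sampling rates (Hz).
#'   Each must be at least twice the highest simulated frequency content of
#'   its channel (the EMG band is capped at `fs_emg / 4`).
#' @param infusion_rate_ul_min saline infusion rate, uL/min (15-30 typical).
#' @param compliance_cmh2o_per_ul bladder compliance: pressure rise per uL
#'   infused. Fill-ramp slope is `infusion_rate / 60 * compliance` cmH2O/s.
#' @param baseline_pressure_cmh2o resting intravesical pressure.
#' @param n_voids,n_nvcs programmed event counts per session.
#' @param void_pressure_peak_cmh2o voiding-contraction amplitude above the
#'   local pre-void pressure.
#' @param nvc_amplitude_cmh2o NVC peak amplitude (default 8, above the 5
#'   cmH2O inclusion threshold). May be a vector, recycled over NVCs, to
#'   program sub-threshold NVCs for gating tests.
#' @param void_rise_scale_s logistic time scale of the contraction upstroke;
#'   the steepest-rise time (the dP/dt alignment ground truth) is the
#'   logistic midpoint.
#' @param void_hold_s,void_decay_s plateau and relaxation time constants.
#' @param nvc_sigma_s Gaussian width of the single-peaked NVC bump.
#' @param noise_pressure_sd_cmh2o Gaussian pressure noise SD.
#' @param multipeak_void_frac fraction of voids generated with a second
#'   contraction peak (for testing the single-peak inclusion rule).
#' @param bleach_c,bleach_a1,bleach_tau1_s,bleach_a2,bleach_tau2_s
#'   double-exponential photobleach: baseline multiplier
#'   `c + a1 exp(-t/tau1) + a2 exp(-t/tau2)`.
#' @param f465_scale,f405_scale static fluorescence levels (a.u.) of the two
#'   channels.
#' @param transient_amp peak dF/F0 of the void-locked GCaMP transient.
#' @param nvc_atten NVC transient amplitude as a fraction of the void
#'   amplitude (< 1: NVC-locked activity attenuated relative to voids).
#' @param tau_rise_s,tau_decay_s difference-of-exponentials transient
#'   kinetics.
#' @param motion_artifact_rate_per_min expected shared motion artifacts per
#'   minute.
#' @param artifact_amp_au additive artifact amplitude (a.u., random sign).
#' @param artifact_sigma_s Gaussian artifact width.
#' @param artifact_scale_405 artifact gain in the 405 channel relative to 465.
#' @param noise_photometry_sd_au per-channel white noise SD (a.u.).
#' @param emg_tonic_mv tonic EMG RMS amplitude (mV).
#' @param emg_relaxation_depth fractional RMS drop during a responsive
#'   stimulation (0.5 halves the RMS, quartering total power).
#' @param emg_band_hz upper edge of the band-limited EMG noise.
#' @param n_stim_trials,stim_duration_s,stim_gap_s stimulation train layout.
#' @param relax_prob programmed probability that a stimulation produces EUS
#'   relaxation (the ground-truth response rate).
#' @param stim_pressure_rise_cmh2o evoked bladder-pressure rise in
#'   pressure-responsive trials.
#' @param pressure_response_prob probability a trial is pressure-responsive.
#' @param emg_artifact_prob probability a trial carries an injected
#'   electrical artifact during its baseline phase (for exclusion-rule
#'   tests); artifacts during the stim phase are controlled by
#'   `emg_stim_artifact_prob`.
#' @param emg_stim_artifact_prob see above.
#' @param seed RNG seed; all generators are deterministic given
#'   (params, seed).
#' @return named list of class `lut_sim_params`.
#' @export
sim_params <- function(duration_s = 7200,
                       fs_pressure = 20, fs_photometry = 100, fs_emg = 1000,
                       infusion_rate_ul_min = 20,
                       compliance_cmh2o_per_ul = 0.024,
                       baseline_pressure_cmh2o = 5,
                       n_voids = 6, n_nvcs = 4,
                       void_pressure_peak_cmh2o = 25,
                       nvc_amplitude_cmh2o = 8,
                       void_rise_scale_s = 0.5,
                       void_hold_s = 2, void_decay_s = 3,
                       nvc_sigma_s = 1.5,
                       noise_pressure_sd_cmh2o = 0.5,
                       multipeak_void_frac = 0,
                       bleach_c = 0.75, bleach_a1 = 0.15, bleach_tau1_s = 120,
                       bleach_a2 = 0.10, bleach_tau2_s = 3000,
                       f465_scale = 1.0, f405_scale = 0.8,
                       transient_amp = 0.15, nvc_atten = 0.3,
                       tau_rise_s = 0.5, tau_decay_s = 4,
                       motion_artifact_rate_per_min = 0.5,
                       artifact_amp_au = 0.05, artifact_sigma_s = 0.08,
                       artifact_scale_405 = 1.0,
                       noise_photometry_sd_au = 0.003,
                       emg_tonic_mv = 0.1, emg_relaxation_depth = 0.5,
                       emg_band_hz = NULL,
                       n_stim_trials = 20, stim_duration_s = 5,
                       stim_gap_s = 20,
                       relax_prob = 0.75,
                       stim_pressure_rise_cmh2o = 6,
                       pressure_response_prob = 0,
                       emg_artifact_prob = 0,
                       emg_stim_artifact_prob = 0,
                       seed = 1L) {
  p <- as.list(environment())
  if (is.null(p$emg_band_hz)) p$emg_band_hz <- p$fs_emg / 4
  stopifnot(p$duration_s > 0, p$fs_pressure > 0, p$fs_photometry > 0,
            p$fs_emg > 0, p$infusion_rate_ul_min >= 0,
            p$compliance_cmh2o_per_ul >= 0, p$noise_pressure_sd_cmh2o >= 0,
            p$noise_photometry_sd_au >= 0, p$motion_artifact_rate_per_min >= 0,
            p$emg_tonic_mv >= 0, p$emg_relaxation_depth >= 0,
            p$emg_relaxation_depth <= 1,
            p$relax_prob >= 0, p$relax_prob <= 1,
            p$emg_band_hz <= p$fs_emg / 2)
  class(p) <- "lut_sim_params"
  p
}

# Difference-of-exponentials transient kernel, peak-normalized to 1.
# Zero for x < 0. Peak occurs at tpk = log(td/tr) * td*tr/(td-tr).
transient_kernel <- function(x, tau_rise, tau_decay) {
  stopifnot(tau_decay > tau_rise, tau_rise > 0)
  tpk <- log(tau_decay / tau_rise) * tau_decay * tau_rise / (tau_decay - tau_rise)
  pk <- exp(-tpk / tau_decay) - exp(-tpk / tau_rise)
  out <- numeric(length(x))
  pos <- x >= 0
  out[pos] <- (exp(-x[pos] / tau_decay) - exp(-x[pos] / tau_rise)) / pk
  out
}

# Voiding-contraction pressure pulse: logistic upstroke (steepest rise at
# x = 0), brief plateau, exponential relaxation. Amplitude 1.
void_pulse <- function(x, scale, hold, decay) {
  plogis(x / scale) * exp(-pmax(0, x - hold) / decay)
}

#' Simulate a filling-cystometry pressure trace with ground truth
#'
#' Pressure = baseline + linear fill ramp (slope = infusion rate x
#' compliance, resetting at each void) + voiding-contraction pulses +
#' single-peaked NVC bumps + Gaussian noise. Void and NVC times are placed
#' strictly inside `(60, duration - 60)` s so the +/-60 s peri-event window
#' always fits, and spaced so no two analysis windows overlap.
#'
#' @param params a [sim_params()] object.
#' @return list with `pressure` (a [time_series()], cmH2O) and `truth`, a
#'   list holding `events` (data.frame: kind, t_align_true = steepest-rise
#'   time for voids / peak time for NVCs, t_peak_true, amplitude,
#'   n_peaks_true), plus `fill_slope_cmh2o_s`.
#' @export
simulate_cmg <- function(params = sim_params()) {
  p <- params
  with_seed(p$seed, {
    dur <- p$duration_s
    margin <- 61
    n_ev <- p$n_voids + p$n_nvcs
    if (n_ev > 0 && (dur - 2 * margin) / n_ev < 130)
      stop("simulate_cmg: events would overlap within one +/-60 s analysis window; ",
           "lengthen the session or reduce event counts")
    # voids evenly spaced with jitter; NVCs at inter-void midpoints
    void_t <- if (p$n_voids > 0) {
      base <- margin + (dur - 2 * margin) * (seq_len(p$n_voids) - 0.5) / p$n_voids
      sort(base + runif(p$n_voids, -0.03, 0.03) * (dur - 2 * margin) / p$n_voids)
    } else numeric(0)
    bounds <- c(margin, void_t, dur - margin)
    gaps <- diff(bounds)
    nvc_t <- numeric(0)
    if (p$n_nvcs > 0) {
      ord <- order(gaps, decreasing = TRUE)
      slots <- rep(ord, length.out = p$n_nvcs)  # round-robin, largest first
      for (g in unique(slots)) {
        k <- sum(slots == g)
        lo <- bounds[g] + 122; hi <- bounds[g + 1] - 122
        if (hi - lo < 122 * (k - 1))
          stop("simulate_cmg: events would overlap within one +/-60 s ",
               "analysis window; lengthen the session or reduce event counts")
        base <- if (k == 1) (lo + hi) / 2 else seq(lo, hi, length.out = k)
        slack <- if (k == 1) (hi - lo) / 2 else ((hi - lo) / (k - 1) - 122) / 2
        nvc_t <- c(nvc_t, base + runif(k, -1, 1) * pmin(slack, 10))
      }
      nvc_t <- sort(nvc_t)
    }
    all_t <- sort(c(void_t, nvc_t))
    if (length(all_t) > 1 && min(diff(all_t)) < 121)
      stop("simulate_cmg: programmed events overlap within one analysis window")

    t <- (seq_len(round(dur * p$fs_pressure)) - 1) / p$fs_pressure
    slope <- p$infusion_rate_ul_min / 60 * p$compliance_cmh2o_per_ul
    # global fill ramp; each void empties the bladder smoothly just after
    # the contraction peak (a sigmoid release of the accumulated fill, so
    # the pre-void dP/dt maximum stays at the contraction upstroke)
    pr <- p$baseline_pressure_cmh2o + slope * t
    release_t <- void_t + p$void_hold_s
    last <- 0
    for (k in seq_along(void_t)) {
      accum <- slope * (release_t[k] - last)
      pr <- pr - accum * plogis((t - release_t[k]) / 1)
      last <- release_t[k]
    }

    nv_amp <- rep_len(p$nvc_amplitude_cmh2o, max(p$n_nvcs, 1L))
    n_multi <- round(p$multipeak_void_frac * p$n_voids)
    multi <- seq_len(p$n_voids) <= n_multi  # deterministic: first voids multipeak
    for (k in seq_along(void_t)) {
      x <- t - void_t[k]
      keep <- abs(x) < 60
      pr[keep] <- pr[keep] + p$void_pressure_peak_cmh2o *
        void_pulse(x[keep], p$void_rise_scale_s, p$void_hold_s, p$void_decay_s)
      if (multi[k])
        pr[keep] <- pr[keep] + 0.6 * p$void_pressure_peak_cmh2o *
          void_pulse(x[keep] - 8, p$void_rise_scale_s, 1, p$void_decay_s)
    }
    for (k in seq_along(nvc_t)) {
      x <- t - nvc_t[k]
      keep <- abs(x) < 60
      pr[keep] <- pr[keep] + nv_amp[k] * exp(-x[keep]^2 / (2 * p$nvc_sigma_s^2))
    }
    if (p$noise_pressure_sd_cmh2o > 0)
      pr <- pr + rnorm(length(pr), 0, p$noise_pressure_sd_cmh2o)

    # noiseless peak time of the void pulse (numeric, on a fine local grid)
    pk_off <- if (p$n_voids > 0) {
      xg <- seq(0, p$void_hold_s + 5 * p$void_decay_s, by = 1e-3)
      xg[which.max(void_pulse(xg, p$void_rise_scale_s, p$void_hold_s,
                              p$void_decay_s))]
    } else 0
    ev <- rbind(
      if (p$n_voids > 0)
        data.frame(kind = "void", t_align_true = void_t,
                   t_peak_true = void_t + pk_off,
                   amplitude = p$void_pressure_peak_cmh2o,
                   n_peaks_true = ifelse(multi, 2L, 1L)),
      if (p$n_nvcs > 0)
        data.frame(kind = "nvc", t_align_true = nvc_t, t_peak_true = nvc_t,
                   amplitude = nv_amp[seq_len(p$n_nvcs)], n_peaks_true = 1L))
    if (is.null(ev)) ev <- data.frame(kind = character(0),
                                      t_align_true = numeric(0),
                                      t_peak_true = numeric(0),
                                      amplitude = numeric(0),
                                      n_peaks_true = integer(0))
    ev <- ev[order(ev$t_align_true), , drop = FALSE]
    rownames(ev) <- NULL
    list(pressure = time_series(pr, fs = p$fs_pressure, t0 = 0,
                                label = "pressure", units = "cmH2O"),
         truth = list(events = ev, fill_slope_cmh2o_s = slope,
                      params = p))
  })
}

#' Simulate two-channel fiber photometry locked to cystometry ground truth
#'
#' The 465 nm channel is `bleach x (1 + activity) + artifacts + noise` where
#' activity carries a difference-of-exponentials GCaMP transient at each
#' void onset and an attenuated transient at each NVC peak. The 405 nm
#' isosbestic channel carries the same bleach shape and the same motion
#' artifacts (scaled by `artifact_scale_405`) but no calcium activity.
#'
#' @param truth ground-truth list from [simulate_cmg()].
#' @param params a [sim_params()] object.
#' @return list with `ch465`, `ch405` ([time_series()], a.u.) and `truth`
#'   augmented with per-event transient amplitudes and artifact times.
#' @export
simulate_photometry <- function(truth, params = truth$params) {
  p <- params
  with_seed(p$seed + 1000L, {
    n <- round(p$duration_s * p$fs_photometry)
    t <- (seq_len(n) - 1) / p$fs_photometry
    bleach <- p$bleach_c + p$bleach_a1 * exp(-t / p$bleach_tau1_s) +
      p$bleach_a2 * exp(-t / p$bleach_tau2_s)
    ev <- truth$events
    amps <- numeric(nrow(ev))
    act <- numeric(n)
    for (k in seq_len(nrow(ev))) {
      a <- p$transient_amp * runif(1, 0.8, 1.2)
      if (ev$kind[k] == "nvc") a <- a * p$nvc_atten
      amps[k] <- a
      x <- t - ev$t_align_true[k]
      keep <- x >= 0 & x < 60
      act[keep] <- act[keep] +
        a * transient_kernel(x[keep], p$tau_rise_s, p$tau_decay_s)
    }
    n_art <- rpois(1, p$motion_artifact_rate_per_min * p$duration_s / 60)
    art_t <- sort(runif(n_art, 60, p$duration_s - 60))
    art_sign <- sample(c(-1, 1), n_art, replace = TRUE)
    m <- numeric(n)
    for (k in seq_len(n_art)) {
      x <- t - art_t[k]
      keep <- abs(x) < 6 * p$artifact_sigma_s
      m[keep] <- m[keep] + art_sign[k] * p$artifact_amp_au *
        exp(-x[keep]^2 / (2 * p$artifact_sigma_s^2))
    }
    ch465 <- p$f465_scale * bleach * (1 + act) + m +
      rnorm(n, 0, p$noise_photometry_sd_au)
    ch405 <- p$f405_scale * bleach + p$artifact_scale_405 * m +
      rnorm(n, 0, p$noise_photometry_sd_au)
    truth$transient_amplitudes <- amps
    truth$artifact_times <- art_t
    truth$artifact_signs <- art_sign
    list(ch465 = time_series(ch465, fs = p$fs_photometry, t0 = 0,
                             label = "photometry465", units = "a.u."),
         ch405 = time_series(ch405, fs = p$fs_photometry, t0 = 0,
                             label = "photometry405", units = "a.u."),
         truth = truth)
  })
}

#' Programmed optogenetic stimulation train with ground-truth response flags
#'
#' @param params a [sim_params()] object; uses `n_stim_trials`,
#'   `stim_duration_s`, `stim_gap_s`, `relax_prob`,
#'   `pressure_response_prob`, `emg_artifact_prob`,
#'   `emg_stim_artifact_prob` and `seed`.
#' @return data.frame with one row per trial: `trial_id`, `onset_s`,
#'   `duration_s`, `relaxation` (EUS relaxes during stim),
#'   `pressure_response`, `baseline_artifact`, `stim_artifact`.
#' @export
make_stim_trials <- function(params = sim_params()) {
  p <- params
  with_seed(p$seed + 2000L, {
    d <- p$stim_duration_s
    pitch <- 3 * d + p$stim_gap_s
    onset <- d + 1 + (seq_len(p$n_stim_trials) - 1) * pitch
    need <- onset[length(onset)] + 2 * d + 1
    if (need > p$duration_s)
      stop(sprintf("make_stim_trials: %d trials need %.0f s but duration_s = %.0f",
                   p$n_stim_trials, need, p$duration_s))
    data.frame(
      trial_id = sprintf("trial%03d", seq_len(p$n_stim_trials)),
      onset_s = onset, duration_s = d,
      relaxation = runif(p$n_stim_trials) < p$relax_prob,
      pressure_response = runif(p$n_stim_trials) < p$pressure_response_prob,
      baseline_artifact = runif(p$n_stim_trials) < p$emg_artifact_prob,
      stim_artifact = runif(p$n_stim_trials) < p$emg_stim_artifact_prob)
  })
}

#' Simulate tonic EUS-EMG with programmed relaxation epochs
#'
#' Band-limited Gaussian noise of RMS `emg_tonic_mv`; during each
#' stimulation flagged `relaxation`, the RMS drops by
#' `emg_relaxation_depth` (total power scales with RMS squared). Trials
#' flagged `baseline_artifact` / `stim_artifact` get a large brief spike
#' injected in the corresponding phase, for exclusion-rule testing.
#'
#' @param stim_trials data.frame from [make_stim_trials()].
#' @param params a [sim_params()] object.
#' @return a [time_series()] in mV at `fs_emg`.
#' @export
simulate_emg <- function(stim_trials, params = sim_params()) {
  p <- params
  with_seed(p$seed + 3000L, {
    n <- round(p$duration_s * p$fs_emg)
    w <- rnorm(n)
    # band-limit by spectral truncation: zero all bins above emg_band_hz
    W <- fft(w)
    fr <- (seq_len(n) - 1) / n * p$fs_emg
    fr <- pmin(fr, p$fs_emg - fr)
    W[fr > p$emg_band_hz] <- 0
    x <- Re(fft(W, inverse = TRUE)) / n
    x <- x / sqrt(mean(x^2)) * p$emg_tonic_mv
    t <- (seq_len(n) - 1) / p$fs_emg
    env <- rep(1, n)
    for (k in seq_len(nrow(stim_trials))) {
      tr <- stim_trials[k, ]
      if (isTRUE(tr$relaxation)) {
        idx <- t >= tr$onset_s & t < tr$onset_s + tr$duration_s
        env[idx] <- 1 - p$emg_relaxation_depth
      }
    }
    x <- x * env
    spike_n <- max(2L, round(0.005 * p$fs_emg))  # 5 ms artifact
    for (k in seq_len(nrow(stim_trials))) {
      tr <- stim_trials[k, ]
      if (isTRUE(tr$baseline_artifact)) {
        i0 <- ts_index(list(t0 = 0, fs = p$fs_emg),
                       tr$onset_s - tr$duration_s / 2)
        x[i0:(i0 + spike_n - 1L)] <- x[i0:(i0 + spike_n - 1L)] +
          30 * p$emg_tonic_mv
      }
      if (isTRUE(tr$stim_artifact)) {
        i0 <- ts_index(list(t0 = 0, fs = p$fs_emg),
                       tr$onset_s + tr$duration_s / 2)
        x[i0:(i0 + spike_n - 1L)] <- x[i0:(i0 + spike_n - 1L)] +
          30 * p$emg_tonic_mv
      }
    }
    time_series(x, fs = p$fs_emg, t0 = 0, label = "emg", units = "mV")
  })
}

#' Simulate bladder pressure during an optogenetic stimulation session
#'
#' Pure linear filling ramp plus, for trials flagged `pressure_response`, a
#' stimulus-locked pressure rise of `stim_pressure_rise_cmh2o` developing
#' over the stimulation epoch.
#'
#' @inheritParams simulate_emg
#' @return a [time_series()] in cmH2O at `fs_pressure`.
#' @export
simulate_opto_pressure <- function(stim_trials, params = sim_params()) {
  p <- params
  with_seed(p$seed + 4000L, {
    n <- round(p$duration_s * p$fs_pressure)
    t <- (seq_len(n) - 1) / p$fs_pressure
    slope <- p$infusion_rate_ul_min / 60 * p$compliance_cmh2o_per_ul
    pr <- p$baseline_pressure_cmh2o + slope * t
    for (k in seq_len(nrow(stim_trials))) {
      tr <- stim_trials[k, ]
      if (isTRUE(tr$pressure_response)) {
        x <- t - tr$onset_s
        keep <- x > -5 & x < tr$duration_s + 30
        pr[keep] <- pr[keep] + p$stim_pressure_rise_cmh2o *
          plogis((x[keep] - tr$duration_s / 8) / 0.5) *
          exp(-pmax(0, x[keep] - tr$duration_s) / 8)
      }
    }
    if (p$noise_pressure_sd_cmh2o > 0)
      pr <- pr + rnorm(n, 0, p$noise_pressure_sd_cmh2o)
    time_series(pr, fs = p$fs_pressure, t0 = 0, label = "pressure",
                units = "cmH2O")
  })
}

#' Simulate a complete fiber-photometry/cystometry session
#'
#' Convenience wrapper: [simulate_cmg()] then [simulate_photometry()],
#' packed into a [session_bundle()].
#'
#' @param params a [sim_params()] object.
#' @param animal_id animal identifier stored in the bundle.
#' @return list with `bundle` (a [session_bundle()]) and `truth`.
#' @export
simulate_session <- function(params = sim_params(), animal_id = "sim01") {
  cm <- simulate_cmg(params)
  ph <- simulate_photometry(cm$truth, params)
  bundle <- session_bundle(animal_id = animal_id,
                           photometry465 = ph$ch465,
                           photometry405 = ph$ch405,
                           pressure = cm$pressure,
                           metadata = list(
                             infusion_rate_ul_min = params$infusion_rate_ul_min,
                             seed = params$seed))
  list(bundle = bundle, truth = ph$truth)
}

#' Simulate an optogenetics EMG/cystometry session
#'
#' @inheritParams simulate_session
#' @return list with `bundle` (EMG + pressure + stim_train) and
#'   `stim_trials` (the ground-truth trial table).
#' @export
simulate_opto_session <- function(params = sim_params(duration_s = 900),
                                  animal_id = "sim01") {
  trials <- make_stim_trials(params)
  emg <- simulate_emg(trials, params)
  pressure <- simulate_opto_pressure(trials, params)
  bundle <- session_bundle(animal_id = animal_id, emg = emg,
                           pressure = pressure,
                           stim_train = trials[c("trial_id", "onset_s",
                                                 "duration_s")],
                           metadata = list(seed = params$seed))
  list(bundle = bundle, stim_trials = trials)
}

#' Simulate a scent-marking session event table
#'
#' A urine stimulus is presented at `stimulus_time_s`; marking events are
#' drawn from a homogeneous Poisson process at `mark_rate_per_min` over the
#' remainder of the session. The `"dominant"` archetype guarantees an early
#' first mark and a high count; `"subordinate"` a late, sparse profile.
#'
#' @param archetype `"dominant"`, `"subordinate"` or `"custom"` (pure
#'   Poisson at `mark_rate_per_min`).
#' @param duration_s session length (marking sessions are 1 h by default).
#' @param stimulus_time_s stimulus presentation time.
#' @param mark_rate_per_min Poisson mark rate after the stimulus.
#' @param first_latency_s for the archetypes: programmed latency from
#'   stimulus to first mark.
#' @param seed RNG seed.
#' @param animal_id animal identifier.
#' @return list with `events` (event table, kind `"mark"`),
#'   `stimulus_time_s`, `duration_s`.
#' @export
simulate_marking_session <- function(archetype = c("custom", "dominant",
                                                   "subordinate"),
                                     duration_s = 3600, stimulus_time_s = 600,
                                     mark_rate_per_min = 0.5,
                                     first_latency_s = 60,
                                     seed = 1L, animal_id = "sim01") {
  archetype <- match.arg(archetype)
  with_seed(seed, {
    span <- duration_s - stimulus_time_s
    if (archetype == "dominant") {
      mark_rate_per_min <- max(mark_rate_per_min, 15 / (span / 60))
      first_latency_s <- min(first_latency_s, 299)
    } else if (archetype == "subordinate") {
      mark_rate_per_min <- min(mark_rate_per_min, 5 / (span / 60))
      first_latency_s <- max(first_latency_s, 400)
    }
    n <- rpois(1, mark_rate_per_min * span / 60)
    tm <- sort(runif(n, stimulus_time_s, duration_s))
    if (archetype %in% c("dominant", "subordinate")) {
      if (archetype == "dominant" && n < 10) {
        n <- 12
        tm <- sort(runif(n, stimulus_time_s, duration_s))
      }
      if (archetype == "subordinate" && n > 9) { n <- 5; tm <- tm[seq_len(5)] }
      if (n > 0) tm[1] <- stimulus_time_s + first_latency_s
      tm <- sort(tm)
    }
    ev <- if (n > 0)
      data.frame(event_id = sprintf("mark%03d", seq_len(n)),
                 animal_id = animal_id, kind = "mark",
                 t_align_s = tm, t_start_s = tm - 0.5, t_end_s = tm + 0.5,
                 included = TRUE, exclusion_reason = "",
                 stringsAsFactors = FALSE)
    else empty_events()
    list(events = ev, stimulus_time_s = stimulus_time_s,
         duration_s = duration_s)
  })
}
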