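# EUS-EMG epoch analysis around optogenetic stimulations: Total Power
# (TTP) per before/stim/after epoch, three-epoch percent normalization,
# baseline-artifact trial exclusion, and per-animal response rates.

#' Epoch one stimulation trial
#'
#' Epochs tile `[t - d, t + 2d)` with no gap or overlap: before =
#' `[t - d, t)`, during = `[t, t + d)`, after = `[t + d, t + 2d)`, each with
#' the same sample count per channel.
#'
#' @param emg EMG [time_series()] (mV).
#' @param pressure bladder-pressure [time_series()] (cmH2O); may be `NULL`.
#' @param onset_s stimulation onset, seconds.
#' @param duration_s stimulation duration `d`, seconds.
#' @return list: `emg` (list of numeric vectors `before`, `stim`, `after`),
#'   `pressure` (same structure, plus `t` vectors, or `NULL`),
#'   `onset_s`, `duration_s`.
#' @export
epoch_trial <- function(emg, pressure, onset_s, duration_s) {
  slice3 <- function(ts) {
    i_before <- ts_slice_idx(ts, onset_s - duration_s, onset_s)
    i_stim <- ts_slice_idx(ts, onset_s, onset_s + duration_s)
    i_after <- ts_slice_idx(ts, onset_s + duration_s, onset_s + 2 * duration_s)
    stopifnot(length(i_before) == length(i_stim),
              length(i_stim) == length(i_after))
    tof <- function(i) ts$t0 + (i - 1) / ts$fs
    list(before = ts$values[i_before], stim = ts$values[i_stim],
         after = ts$values[i_after],
         t = list(before = tof(i_before), stim = tof(i_stim),
                  after = tof(i_after)))
  }
  out <- list(emg = slice3(emg), onset_s = onset_s, duration_s = duration_s)
  out$pressure <- if (!is.null(pressure)) slice3(pressure) else NULL
  out
}

#' Total power of an epoch
#'
#' TTP is the sum of power across all frequencies within the epoch. By
#' Parseval's theorem this equals the sum of squared (mean-removed) samples,
#' which is the canonical computation here; `total_power_freq()` provides
#' the periodogram-summation form, and the two agree to numerical
#' precision. The epoch mean (DC) is removed by default so that electrode
#' offset does not dominate the statistic (`ttp_remove_dc = FALSE`
#' retains it).
#'
#' @param x numeric vector of EMG samples (mV); units of the result are
#'   mV^2 (reported under the V^2 convention with an explicit scale note).
#' @param remove_dc subtract the epoch mean first.
#' @return total power, a single non-negative number.
#' @export
total_power <- function(x, remove_dc = lut_config()$ttp_remove_dc) {
  if (!length(x)) stop("total_power: empty epoch")
  if (remove_dc) x <- x - mean(x)
  sum(x * x)
}

#' Total power via the periodogram (frequency domain)
#'
#' `sum(|FFT(x)|^2) / N` over all frequency bins; equals [total_power()]
#' by Parseval's theorem.
#'
#' @inheritParams total_power
#' @return total power, a single non-negative number.
#' @export
total_power_freq <- function(x, remove_dc = lut_config()$ttp_remove_dc) {
  if (!length(x)) stop("total_power_freq: empty epoch")
  if (remove_dc) x <- x - mean(x)
  sum(Mod(fft(x))^2) / length(x)
}

#' Three-epoch percent normalization of total power
#'
#' `TTP_p = TTP_p / (TTP_before + TTP_stim + TTP_after) x 100` for each
#' epoch p, removing between-trial and between-animal voltage variability.
#' The three shares always sum to 100. An all-zero trial has no defined
#' shares and is flagged rather than reported as 0/0.
#'
#' @param ttp_before,ttp_stim,ttp_after raw epoch total powers (>= 0).
#' @return list: `norm_before`, `norm_stim`, `norm_after` (percent, or NA
#'   when flagged), `flagged`.
#' @export
normalize_epochs <- function(ttp_before, ttp_stim, ttp_after) {
  v <- c(ttp_before, ttp_stim, ttp_after)
  if (any(v < 0)) stop("normalize_epochs: total power must be >= 0")
  tot <- sum(v)
  if (tot == 0)
    return(list(norm_before = NA_real_, norm_stim = NA_real_,
                norm_after = NA_real_, flagged = TRUE))
  s <- v / tot * 100
  list(norm_before = s[1], norm_stim = s[2], norm_after = s[3],
       flagged = FALSE)
}

# Baseline-artifact detector: any run of samples exceeding
# `artifact_mad_mult` x the session's robust (MAD) amplitude scale for at
# least `artifact_min_ms`, within the baseline epoch.
detect_baseline_artifact <- function(baseline, session_scale, fs, config) {
  thr <- config$artifact_mad_mult * session_scale
  over <- abs(baseline - median(baseline)) > thr
  if (!any(over)) return(FALSE)
  need <- max(1L, round(config$artifact_min_ms / 1000 * fs))
  r <- rle(over)
  any(r$values & r$lengths >= need)
}

#' Build the per-trial epoch-power table for a stimulation session
#'
#' Epochs each trial, computes raw and normalized TTP, mean bladder
#' pressure per epoch with a baseline-trend-extrapolated prediction for the
#' stim epoch, and the baseline-artifact flag (detected from the EMG, or
#' taken from a supplied ground-truth column).
#'
#' @param emg EMG [time_series()].
#' @param pressure bladder-pressure [time_series()] or `NULL`.
#' @param stims data.frame with `trial_id`, `onset_s`, `duration_s` and
#'   optionally `baseline_artifact` (ground-truth flags override
#'   detection).
#' @param config analysis configuration.
#' @param animal_id identifier stamped on trials.
#' @return data.frame, one row per trial that fits the trace:
#'   `trial_id`, `animal_id`, `ttp_before/stim/after` (mV^2),
#'   `norm_before/stim/after` (%), `cmg_before`, `cmg_stim`,
#'   `cmg_stim_pred` (cmH2O), `baseline_artifact`.
#' @export
build_trial_table <- function(emg, pressure, stims, config = lut_config(),
                              animal_id = "unknown") {
  scale <- mad(emg$values)
  rows <- list()
  for (i in seq_len(nrow(stims))) {
    st <- stims[i, ]
    ep <- tryCatch(epoch_trial(emg, pressure, st$onset_s, st$duration_s),
                   error = function(e) NULL)
    if (is.null(ep)) {
      lut_log("build_trial_table",
              sprintf("excluded %s: epochs out of bounds", st$trial_id))
      next
    }
    ttp <- vapply(ep$emg[c("before", "stim", "after")], total_power,
                  numeric(1), remove_dc = config$ttp_remove_dc)
    nm <- normalize_epochs(ttp[1], ttp[2], ttp[3])
    art <- if (!is.null(st$baseline_artifact)) isTRUE(st$baseline_artifact)
           else detect_baseline_artifact(ep$emg$before, scale, emg$fs, config)
    cmg_before <- cmg_stim <- cmg_pred <- NA_real_
    if (!is.null(ep$pressure)) {
      cmg_before <- mean(ep$pressure$before)
      cmg_stim <- mean(ep$pressure$stim)
      # account for the natural filling-related pressure rise: extrapolate
      # the baseline-epoch linear trend across the stim epoch
      tb <- ep$pressure$t$before
      fit <- lm(ep$pressure$before ~ tb)
      cmg_pred <- mean(coef(fit)[1] + coef(fit)[2] * ep$pressure$t$stim)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      trial_id = st$trial_id, animal_id = animal_id,
      ttp_before = ttp[[1]], ttp_stim = ttp[[2]], ttp_after = ttp[[3]],
      norm_before = nm$norm_before, norm_stim = nm$norm_stim,
      norm_after = nm$norm_after,
      cmg_before = cmg_before, cmg_stim = cmg_stim,
      cmg_stim_pred = cmg_pred,
      baseline_artifact = art, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else NULL
  lut_log("build_trial_table", sprintf("%d stims -> %d trials",
                                       nrow(stims), NROW(out)))
  out
}

#' Exclude trials with baseline-phase artifacts
#'
#' Trials with movement or electrical/static artifacts during the baseline
#' phase are removed; artifacts during the stimulation or recovery phase
#' never cause removal (retaining them avoids bias in trial selection).
#'
#' @param trials data.frame from [build_trial_table()].
#' @return filtered data.frame.
#' @export
exclude_artifact_trials <- function(trials) {
  drop <- trials$baseline_artifact
  for (id in trials$trial_id[drop])
    lut_log("exclude_artifact_trials",
            sprintf("excluded %s: baseline artifact", id))
  trials[!drop, , drop = FALSE]
}

#' Randomly subsample an equal number of trials per animal
#'
#' @param trials data.frame with an `animal_id` column.
#' @param n_per_animal trials kept per animal (error if any animal has
#'   fewer).
#' @param seed RNG seed.
#' @return subsampled data.frame, deterministic given the seed.
#' @export
subsample_trials <- function(trials, n_per_animal, seed) {
  animals <- unique(trials$animal_id)
  short <- animals[vapply(animals, function(a)
    sum(trials$animal_id == a) < n_per_animal, logical(1))]
  if (length(short))
    stop("subsample_trials: animal(s) with fewer than n_per_animal trials: ",
         paste(short, collapse = ", "))
  with_seed(seed, {
    keep <- unlist(lapply(animals, function(a) {
      idx <- which(trials$animal_id == a)
      if (length(idx) == n_per_animal) idx else sort(sample(idx, n_per_animal))
    }))
    trials[keep, , drop = FALSE]
  })
}

#' Per-animal EMG and CMG response rates
#'
#' EMG response: stimulation total power at least `emg_drop_frac` (default
#' 5%) below baseline total power. CMG response: mean stim-epoch pressure
#' exceeding the baseline-trend prediction (which accounts for the natural
#' filling-related rise) by at least `cmg_rise_cmh2o` (default 3 cmH2O).
#'
#' @param trials data.frame from [build_trial_table()], typically after
#'   [exclude_artifact_trials()] and [subsample_trials()].
#' @param config analysis configuration.
#' @return data.frame, one row per animal: `animal_id`, `n_trials`,
#'   `emg_response_pct`, `cmg_response_pct` (NA without pressure data).
#' @export
response_rates <- function(trials, config = lut_config()) {
  if (!nrow(trials)) stop("response_rates: no trials")
  out <- lapply(split(trials, trials$animal_id), function(tr) {
    emg_resp <- tr$ttp_stim <= (1 - config$emg_drop_frac) * tr$ttp_before
    cmg_resp <- if (all(is.na(tr$cmg_stim))) NA_real_
      else mean(tr$cmg_stim - tr$cmg_stim_pred >= config$cmg_rise_cmh2o) * 100
    data.frame(animal_id = tr$animal_id[1], n_trials = nrow(tr),
               emg_response_pct = mean(emg_resp) * 100,
               cmg_response_pct = cmg_resp, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
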