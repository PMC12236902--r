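# Cystometry event detection: candidate contraction episodes from the
# detrended pressure trace, void/NVC gating per the inclusion rules
# (single contraction peak; NVC rise >= 5 cmH2O), and alignment points
# (voids: max dP/dt preceding the contraction; NVCs: peak pressure).

# earliest sample attaining the maximum, with a relative tolerance so that
# analytically tied maxima separated by float rounding still tie
argmax_earliest <- function(x, tol = 1e-9) {
  m <- max(x)
  which(x >= m - tol * abs(m))[1]
}

# moving-average smoother, centered, edge-padded by replication
smooth_ma <- function(x, k) {
  k <- max(1L, as.integer(k))
  if (k %% 2L == 0L) k <- k + 1L
  if (k == 1L) return(x)
  xp <- c(rep(x[1], k %/% 2), x, rep(x[length(x)], k %/% 2))
  as.numeric(stats::filter(xp, rep(1 / k, k), sides = 2))[
    (k %/% 2 + 1):(k %/% 2 + length(x))]
}

#' Differential bladder-pressure change rate dP/dt
#'
#' Centered finite difference of the moving-average-smoothed pressure
#' trace, in cmH2O/s. Edge samples use one-sided differences.
#'
#' @param pressure a [time_series()] in cmH2O.
#' @param smooth_s moving-average width in seconds (>= 2 samples).
#' @return list of class `lut_dpdt`: `values` (cmH2O/s, same length as the
#'   input), `fs`, `t0`, `smooth_s`.
#' @export
compute_dpdt <- function(pressure, smooth_s = lut_config()$smooth_s) {
  stopifnot(inherits(pressure, "lut_ts"))
  k <- round(smooth_s * pressure$fs)
  if (k < 2) stop("compute_dpdt: smooth_s must span at least 2 samples")
  if (length(pressure$values) <= k)
    stop("compute_dpdt: trace shorter than the smoothing window")
  ps <- smooth_ma(pressure$values, k)
  n <- length(ps)
  d <- numeric(n)
  d[2:(n - 1)] <- (ps[3:n] - ps[1:(n - 2)]) * pressure$fs / 2
  d[1] <- (ps[2] - ps[1]) * pressure$fs
  d[n] <- (ps[n] - ps[n - 1]) * pressure$fs
  structure(list(values = d, fs = pressure$fs, t0 = pressure$t0,
                 smooth_s = smooth_s), class = "lut_dpdt")
}

# count local maxima within an episode whose topographic prominence is at
# least `frac` of the episode rise; prominence = height above the key
# saddle, found by walking outward on each side until terrain higher than
# the peak (or the episode edge) is met
count_peaks <- function(x, frac) {
  n <- length(x)
  if (n < 3L) return(1L)
  rise <- max(x) - min(x)
  if (rise <= 0) return(1L)
  ismax <- which(diff(sign(diff(x))) < 0) + 1L
  if (!length(ismax)) return(1L)
  saddle <- function(i, step) {
    m <- x[i]; j <- i + step
    while (j >= 1L && j <= n && x[j] <= x[i]) {
      if (x[j] < m) m <- x[j]
      j <- j + step
    }
    m
  }
  cnt <- 0L
  for (i in ismax) {
    prom <- x[i] - max(saddle(i, -1L), saddle(i, 1L))
    if (prom >= frac * rise) cnt <- cnt + 1L
  }
  max(cnt, 1L)
}

#' Detect candidate bladder contractions
#'
#' The pressure trace is detrended by a running median over
#' `detrend_span_s` (which absorbs the slow filling ramp), smoothed, and
#' scanned for episodes where the detrended pressure exceeds half the
#' prominence threshold. Each episode's pressure rise is measured against
#' the median of the `pre_baseline_s` seconds preceding it; episodes rising
#' at least `contraction_prominence_cmh2o` become candidates. Candidates
#' closer than `min_interevent_s` are merged. The per-episode peak count
#' (local maxima with prominence >= `peak_prominence_frac` of the episode
#' rise) is recorded for the single-peak inclusion rule.
#'
#' @param pressure a [time_series()] in cmH2O.
#' @param config analysis configuration ([lut_config()]).
#' @return data.frame of candidates: `t_peak_s`, `t_start_s`, `t_end_s`,
#'   `rise_cmh2o`, `n_peaks`. May have zero rows.
#' @export
detect_contractions <- function(pressure, config = lut_config()) {
  fs <- pressure$fs
  p <- pressure$values
  ksm <- max(3L, round(config$smooth_s * fs))
  ps <- smooth_ma(p, ksm)
  kmed <- round(config$detrend_span_s * fs)
  if (kmed %% 2L == 0L) kmed <- kmed + 1L
  kmed <- min(kmed, length(ps) - (1 - length(ps) %% 2))
  trend <- stats::runmed(ps, kmed, endrule = "median")
  d <- ps - trend
  thr <- config$contraction_prominence_cmh2o / 2
  above <- d > thr
  if (!any(above)) return(data.frame(t_peak_s = numeric(0),
                                     t_start_s = numeric(0),
                                     t_end_s = numeric(0),
                                     rise_cmh2o = numeric(0),
                                     n_peaks = integer(0)))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(s = starts[r$values], e = ends[r$values])
  # merge runs separated by less than min_interevent_s
  gap <- config$min_interevent_s * fs
  keep <- list()
  cur <- runs[1, ]
  for (i in seq_len(nrow(runs))[-1]) {
    if (runs$s[i] - cur$e < gap) cur$e <- runs$e[i]
    else { keep[[length(keep) + 1L]] <- cur; cur <- runs[i, ] }
  }
  keep[[length(keep) + 1L]] <- cur
  runs <- do.call(rbind, keep)

  tvec <- ts_time(pressure)
  npre <- round(config$pre_baseline_s * fs)
  out <- lapply(seq_len(nrow(runs)), function(i) {
    s <- runs$s[i]; e <- runs$e[i]
    ipk <- s - 1L + which.max(ps[s:e])
    pre <- ps[max(1L, s - npre):max(1L, s - 1L)]
    rise <- ps[ipk] - median(pre)
    data.frame(t_peak_s = tvec[ipk], t_start_s = tvec[s], t_end_s = tvec[e],
               rise_cmh2o = rise,
               n_peaks = count_peaks(ps[s:e], config$peak_prominence_frac))
  })
  out <- do.call(rbind, out)
  out <- out[out$rise_cmh2o >= config$contraction_prominence_cmh2o, ,
             drop = FALSE]
  rownames(out) <- NULL
  lut_log("detect_contractions", sprintf("%d candidate episodes", nrow(out)))
  out
}

#' Classify candidates as voids or NVCs and apply the inclusion rules
#'
#' A candidate whose peak time matches a confirmed void time (thermal-camera
#' confirmation in real sessions; the ground-truth flag in synthetic ones)
#' within `confirm_match_tol_s` becomes a void; all others are non-voiding
#' contractions. Inclusion rules: any multi-peak episode is excluded with
#' reason `"multi_peak"`; NVCs rising less than `nvc_min_rise_cmh2o` are
#' excluded with reason `"sub_threshold"`. Gating is per-candidate and
#' therefore order-independent.
#'
#' @param candidates data.frame from [detect_contractions()].
#' @param confirmed_void_times numeric vector of confirmed void times (s).
#' @param pressure the pressure [time_series()] (for alignment points).
#' @param config analysis configuration.
#' @param animal_id identifier stamped on the events.
#' @return event table (see [write_events()]) with `t_align_s` filled by
#'   [alignment_point()] for included events.
#' @export
classify_and_gate <- function(candidates, confirmed_void_times, pressure,
                              config = lut_config(), animal_id = "unknown") {
  if (nrow(candidates) == 0L) return(empty_events())
  dpdt <- compute_dpdt(pressure, config$smooth_s)
  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    cand <- candidates[i, ]
    is_void <- length(confirmed_void_times) > 0 &&
      min(abs(confirmed_void_times - cand$t_peak_s)) <= config$confirm_match_tol_s
    kind <- if (is_void) "void" else "nvc"
    included <- TRUE; reason <- ""
    if (cand$n_peaks > 1L) { included <- FALSE; reason <- "multi_peak" }
    else if (!is_void && cand$rise_cmh2o < config$nvc_min_rise_cmh2o) {
      included <- FALSE; reason <- "sub_threshold"
    }
    t_align <- NA_real_
    if (included) {
      t_align <- tryCatch(
        alignment_point(pressure, kind, cand$t_peak_s, config, dpdt = dpdt),
        error = function(e) NA_real_)
      if (is.na(t_align)) { included <- FALSE; reason <- "window_truncated" }
    }
    if (!included)
      lut_log("classify_and_gate",
              sprintf("excluded %s at %.1f s: %s", kind, cand$t_peak_s, reason))
    data.frame(event_id = sprintf("%s_ev%03d", animal_id, i),
               animal_id = animal_id, kind = kind,
               t_align_s = t_align,
               t_start_s = if (included) min(cand$t_start_s, t_align - 1)
                           else cand$t_start_s,
               t_end_s = if (included) max(cand$t_end_s, t_align + 1)
                         else cand$t_end_s,
               included = included,
               exclusion_reason = reason, stringsAsFactors = FALSE)
  })
  ev <- do.call(rbind, rows)
  lut_log("classify_and_gate",
          sprintf("%d candidates -> %d included", nrow(candidates),
                  sum(ev$included)))
  validate_events(ev)
}

#' Alignment point of a contraction event
#'
#' Voids are aligned to the maximum of dP/dt in the `search_back_s` window
#' preceding peak pressure — the steepest pre-void pressure rise. NVCs are
#' aligned to the time of peak pressure. Ties break to the earliest sample.
#'
#' @param pressure a [time_series()] in cmH2O.
#' @param kind `"void"` or `"nvc"`.
#' @param t_peak_s episode peak-pressure time, seconds.
#' @param config analysis configuration.
#' @param dpdt optional precomputed [compute_dpdt()] result.
#' @return alignment time in seconds.
#' @export
alignment_point <- function(pressure, kind, t_peak_s, config = lut_config(),
                            dpdt = NULL) {
  fs <- pressure$fs
  ipk <- ts_index(pressure, t_peak_s)
  ipk <- min(max(ipk, 1L), length(pressure$values))
  if (kind == "void") {
    if (is.null(dpdt)) dpdt <- compute_dpdt(pressure, config$smooth_s)
    i0 <- ipk - as.integer(round(config$search_back_s * fs))
    if (i0 < 1L)
      stop("alignment_point: search window truncated by trace start")
    # the dP/dt maximum is broad relative to sample noise; smooth the
    # derivative once more before the argmax so the located maximum tracks
    # the underlying steepest rise rather than a noise excursion
    seg <- smooth_ma(dpdt$values[i0:ipk], max(3L, round(config$smooth_s * fs)))
    ts_time(pressure)[i0 - 1L + argmax_earliest(seg)]
  } else {
    ksm <- max(3L, round(config$smooth_s * fs))
    ps <- smooth_ma(pressure$values, ksm)
    half <- as.integer(round(10 * fs))
    i0 <- max(1L, ipk - half); i1 <- min(length(ps), ipk + half)
    ts_time(pressure)[i0 - 1L + argmax_earliest(ps[i0:i1])]
  }
}

#' Detect, classify and align contractions in one call
#'
#' @param pressure a [time_series()] in cmH2O.
#' @param confirmed_void_times confirmed void times (s); in real sessions
#'   from thermal-camera confirmation, in synthetic ones from ground truth.
#' @param config analysis configuration.
#' @param animal_id identifier stamped on the events.
#' @return event table.
#' @export
detect_events <- function(pressure, confirmed_void_times,
                          config = lut_config(), animal_id = "unknown") {
  cand <- detect_contractions(pressure, config)
  classify_and_gate(cand, confirmed_void_times, pressure, config, animal_id)
}
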