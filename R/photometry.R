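# Fiber-photometry processing: block-mean downsampling to 0.1 s, dF/F0
# against a fitted whole-trace baseline, isosbestic (405 nm) motion
# correction, per-event percent normalization and z-scoring.

#' Downsample a time series by non-overlapping block means
#'
#' @param ts a [time_series()].
#' @param target_dt_s target resolution in seconds (default 0.1 s).
#' @return a [time_series()] of block means; length
#'   `floor(n / (fs * target_dt_s))`, sampling rate `fs / block`. The block
#'   size must be a whole number of source samples.
#' @export
downsample <- function(ts, target_dt_s = 0.1) {
  stopifnot(inherits(ts, "lut_ts"))
  block <- ts$fs * target_dt_s
  if (block < 1 - 1e-9)
    stop("downsample: target_dt_s is finer than the source resolution")
  if (abs(block - round(block)) > 1e-9)
    stop("downsample: fs * target_dt_s must be a whole number of samples")
  block <- as.integer(round(block))
  n_out <- length(ts$values) %/% block
  if (n_out < 2L) stop("downsample: fewer than 2 output samples")
  v <- .colMeans(ts$values[seq_len(block * n_out)], block, n_out)
  # t0 moves to the center-of-mass of the first block
  time_series(v, fs = ts$fs / block,
              t0 = ts$t0 + (block - 1) / (2 * ts$fs),
              label = ts$label, units = ts$units)
}

# The dF/F0 formula itself, kept as a pure function so it can be checked
# against a one-loop oracle independent of the baseline fit.
dff_formula <- function(f, f0) (f - f0) / f0

# Baseline-fit cascade. Families, in order: double exponential,
# single exponential + constant, 2nd-order polynomial. Returns the fitted
# baseline and a descriptor, or NULL when a family fails.
fit_baseline_family <- function(t, y, family) {
  n <- length(y)
  span <- t[n] - t[1]
  if (family == "poly2") {
    fit <- lm(y ~ poly(t, 2, raw = TRUE))
    return(list(f0 = as.numeric(fitted(fit)), family = family,
                coefficients = coef(fit),
                rms = sqrt(mean(residuals(fit)^2))))
  }
  res <- tryCatch({
    if (family == "double_exp") {
      st <- list(c0 = quantile(y, 0.05), a1 = (y[1] - quantile(y, 0.05)) * 0.6,
                 t1 = span / 20, a2 = (y[1] - quantile(y, 0.05)) * 0.4,
                 t2 = span / 2)
      fit <- minpack.lm::nlsLM(
        y ~ c0 + a1 * exp(-t / t1) + a2 * exp(-t / t2),
        start = st, control = minpack.lm::nls.lm.control(maxiter = 200),
        lower = c(c0 = -Inf, a1 = -Inf, t1 = span * 1e-4,
                  a2 = -Inf, t2 = span * 1e-4))
    } else {  # single_exp
      st <- list(c0 = quantile(y, 0.05), a1 = y[1] - quantile(y, 0.05),
                 t1 = span / 5)
      fit <- minpack.lm::nlsLM(
        y ~ c0 + a1 * exp(-t / t1),
        start = st, control = minpack.lm::nls.lm.control(maxiter = 200),
        lower = c(c0 = -Inf, a1 = -Inf, t1 = span * 1e-4))
    }
    list(f0 = as.numeric(predict(fit)), family = family,
         coefficients = coef(fit),
         rms = sqrt(mean(residuals(fit)^2)))
  }, error = function(e) NULL, warning = function(w) NULL)
  res
}

#' Compute dF/F0 against a fitted whole-trace baseline
#'
#' `F0` is a best-fit bleach curve over the entire trace; the value at each
#' sample is `(F - F0) / F0`. The fit cascade (double exponential, then
#' single exponential + constant, then 2nd-order polynomial) falls through
#' on non-convergence or a non-positive fitted baseline, with the fallback
#' logged; the family actually used is kept in `baseline_model`.
#'
#' @param ts a [time_series()] of strictly positive fluorescence (a.u.),
#'   typically already downsampled to 0.1 s resolution.
#' @param config analysis configuration ([lut_config()]); uses
#'   `dff_baseline_family` as the first family of the cascade.
#' @return object of class `lut_dff`: fields `values`, `fs`, `t0`,
#'   `corrected` (isosbestic flag, `FALSE` here), `baseline_model`
#'   (`family`, `coefficients`, `rms`), and `f0` (the fitted baseline).
#' @export
compute_dff <- function(ts, config = lut_config()) {
  stopifnot(inherits(ts, "lut_ts"))
  if (any(ts$values <= 0))
    stop("compute_dff: fluorescence must be strictly positive")
  t <- ts_time(ts) - ts$t0
  cascade <- unique(c(config$dff_baseline_family,
                      "double_exp", "single_exp", "poly2"))
  fit <- NULL
  for (fam in cascade) {
    fit <- fit_baseline_family(t, ts$values, fam)
    if (!is.null(fit) && all(fit$f0 > 0)) break
    lut_log("compute_dff", sprintf("baseline family '%s' failed; next", fam))
    fit <- NULL
  }
  if (is.null(fit)) {
    # degenerate fallback: constant mean baseline (always positive here)
    fit <- list(f0 = rep(mean(ts$values), length(ts$values)),
                family = "constant", coefficients = c(c0 = mean(ts$values)),
                rms = sd(ts$values))
    lut_log("compute_dff", "all families failed; constant baseline")
  }
  structure(list(values = dff_formula(ts$values, fit$f0),
                 fs = ts$fs, t0 = ts$t0, corrected = FALSE,
                 baseline_model = fit[c("family", "coefficients", "rms")],
                 f0 = fit$f0),
            class = "lut_dff")
}

#' @export
print.lut_dff <- function(x, ...) {
  cat(sprintf("<lut_dff> %d samples @ %g Hz, baseline = %s, corrected = %s\n",
              length(x$values), x$fs, x$baseline_model$family, x$corrected))
  invisible(x)
}

#' Isosbestic motion correction
#'
#' Subtracts the calcium-independent 405 nm dF/F0 from the 465 nm dF/F0.
#' By default the 405 trace is first rescaled onto the 465 trace by
#' least-squares gain and offset, which makes the subtraction robust to
#' channel-specific artifact gain; set `isosbestic_fit = "raw"` in the
#' config for direct (gain 1, offset 0) subtraction.
#'
#' @param dff465,dff405 `lut_dff` objects of equal length and rate.
#' @param config analysis configuration ([lut_config()]).
#' @return corrected `lut_dff` (flag `corrected = TRUE`).
#' @export
isosbestic_correct <- function(dff465, dff405, config = lut_config()) {
  stopifnot(inherits(dff465, "lut_dff"), inherits(dff405, "lut_dff"))
  if (length(dff465$values) != length(dff405$values) ||
      dff465$fs != dff405$fs)
    stop("isosbestic_correct: traces must share length and sampling rate")
  if (identical(config$isosbestic_fit, "raw")) {
    fitted405 <- dff405$values
  } else if (sd(dff405$values) == 0) {
    fitted405 <- numeric(length(dff405$values))  # no motion info to remove
  } else {
    x <- dff405$values; y <- dff465$values
    # plain least squares underestimates the gain when artifacts are sparse
    # (channel noise dilutes the regressor), so fit gain+offset on the
    # motion-informative samples where the 405 trace departs from its
    # baseline, then apply the line to the whole trace
    dev <- abs(x - median(x))
    sel <- dev > 5 * mad(x)
    if (sum(sel) < 10L) sel <- rep(TRUE, length(x))
    fit <- lm(y[sel] ~ x[sel])
    fitted405 <- as.numeric(coef(fit)[1] + coef(fit)[2] * x)
  }
  out <- dff465
  out$values <- dff465$values - fitted405
  out$corrected <- TRUE
  out
}

#' Per-event percent normalization of a peri-event window
#'
#' Each event window is normalized to its own pre-event baseline:
#' `(x - baseline) / baseline x 100`, with baseline the mean dF/F0 over the
#' `window_s` seconds preceding the alignment point. This absorbs
#' between-session differences in fluorescence level. When the baseline
#' mean is within `baseline_guard_eps` of zero the divisive step is ill
#' conditioned; the window is then normalized subtractively only
#' (`(x - baseline) x 100`, i.e. dF/F0 percentage points) and flagged.
#'
#' @param dff an `lut_dff` trace.
#' @param t_align event alignment time, seconds.
#' @param config analysis configuration; uses `peri_window_s` and
#'   `baseline_guard_eps`.
#' @return list: `values` (normalized window, lags `-window..+window`),
#'   `lag_s`, `baseline`, `guard_flagged`.
#' @export
normalize_per_event <- function(dff, t_align, config = lut_config()) {
  w <- config$peri_window_s
  nlag <- as.integer(round(w * dff$fs))
  i0 <- as.integer(round((t_align - dff$t0) * dff$fs)) + 1L
  if (i0 - nlag < 1L || i0 + nlag > length(dff$values))
    stop(sprintf("normalize_per_event: window +/-%g s out of bounds at t = %g",
                 w, t_align))
  win <- dff$values[(i0 - nlag):(i0 + nlag)]
  base <- mean(dff$values[(i0 - nlag):(i0 - 1L)])
  guard <- abs(base) < config$baseline_guard_eps
  vals <- if (guard) (win - base) * 100 else (win - base) / base * 100
  list(values = vals, lag_s = seq(-nlag, nlag) / dff$fs,
       baseline = base, guard_flagged = guard)
}

#' Z-score a window or matrix
#'
#' `Z = (x - mean(x)) / sd(x)` over all supplied values (for a matrix, each
#' row is scored over its own values). Zero-variance input yields all zeros
#' with `flagged = TRUE`.
#'
#' @param x numeric vector, or matrix scored row-wise.
#' @return for a vector: list `values`, `flagged`; for a matrix: list
#'   `values` (matrix), `flagged` (per-row logical).
#' @export
zscore <- function(x) {
  if (is.matrix(x)) {
    rows <- lapply(seq_len(nrow(x)), function(i) zscore(x[i, ]))
    return(list(values = do.call(rbind, lapply(rows, `[[`, "values")),
                flagged = vapply(rows, `[[`, logical(1), "flagged")))
  }
  s <- sd(x)
  if (!is.finite(s) || s == 0)
    return(list(values = numeric(length(x)), flagged = TRUE))
  list(values = (x - mean(x)) / s, flagged = FALSE)
}

#' Full photometry preprocessing chain for a session
#'
#' Downsamples both photometry channels to `dff_target_dt_s`, computes
#' dF/F0 per channel, and applies isosbestic correction.
#'
#' @param bundle a [session_bundle()] with both photometry channels.
#' @param config analysis configuration.
#' @return list: `dff465`, `dff405`, `dff_corrected` (all `lut_dff`).
#' @export
process_photometry <- function(bundle, config = lut_config()) {
  if (is.null(bundle$photometry465) || is.null(bundle$photometry405))
    stop("process_photometry: bundle lacks one or both photometry channels")
  d465 <- compute_dff(downsample(bundle$photometry465, config$dff_target_dt_s),
                      config)
  d405 <- compute_dff(downsample(bundle$photometry405, config$dff_target_dt_s),
                      config)
  list(dff465 = d465, dff405 = d405,
       dff_corrected = isosbestic_correct(d465, d405, config))
}
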