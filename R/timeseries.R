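#' Uniformly sampled physiological channel
#'
#' Container for one uniformly sampled signal: bladder pressure (cmH2O),
#' EUS-EMG voltage (mV), or fluorescence (a.u.). The time of sample `i`
#' (1-based) is exactly `t0 + (i - 1) / fs`; gaps are not representable.
#'
#' @param values numeric vector of finite samples, length >= 2.
#' @param fs sampling rate in Hz, > 0.
#' @param t0 time of the first sample in seconds from session start.
#' @param label channel name, e.g. `"pressure"`, `"photometry465"`.
#' @param units one of `"cmH2O"`, `"mV"`, `"a.u."`, `"dimensionless"`.
#' @return An object of class `lut_ts`.
#' @export
time_series <- function(values, fs, t0 = 0, label = "signal", units = "a.u.") {
  if (!is.numeric(values) || length(values) < 2L)
    stop("time_series: 'values' must be numeric with length >= 2")
  if (!all(is.finite(values)))
    stop("time_series: all values must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("time_series: 'fs' must be a single positive number")
  units <- match.arg(units, c("cmH2O", "mV", "a.u.", "dimensionless"))
  structure(
    list(label = as.character(label), t0 = as.numeric(t0),
         fs = as.numeric(fs), values = as.numeric(values), units = units),
    class = "lut_ts")
}

#' @export
print.lut_ts <- function(x, ...) {
  cat(sprintf("<lut_ts> %s [%s]: %d samples @ %g Hz, t0 = %g s, span %.1f s\n",
              x$label, x$units, length(x$values), x$fs, x$t0,
              (length(x$values) - 1) / x$fs))
  invisible(x)
}

#' @export
length.lut_ts <- function(x) length(x$values)

#' Time axis of a time series
#' @param ts a [time_series()] object.
#' @return numeric vector of sample times in seconds.
#' @export
ts_time <- function(ts) ts$t0 + (seq_along(ts$values) - 1) / ts$fs

#' Index of the sample nearest to a time point
#' @param ts a [time_series()] object.
#' @param t time in seconds.
#' @return 1-based integer index (may fall outside `1..length(ts)` if `t`
#'   lies outside the trace; callers check bounds).
#' @export
ts_index <- function(ts, t) as.integer(round((t - ts$t0) * ts$fs)) + 1L

#' End time of a time series
#' @inheritParams ts_time
#' @return time of the last sample, seconds.
#' @export
ts_end <- function(ts) ts$t0 + (length(ts$values) - 1) / ts$fs

# Extract samples covering [from, to) as indices; errors if out of bounds.
ts_slice_idx <- function(ts, from, to) {
  i0 <- ts_index(ts, from)
  n <- as.integer(round((to - from) * ts$fs))
  if (i0 < 1L || i0 + n - 1L > length(ts$values))
    stop(sprintf("window [%g, %g) out of bounds for trace [%g, %g]",
                 from, to, ts$t0, ts_end(ts)))
  seq.int(i0, length.out = n)
}

#' Bundle of simultaneously recorded session channels
#'
#' Groups the channels of one recording session: two-channel photometry
#' (465 nm calcium-dependent, 405 nm isosbestic), bladder pressure, EUS-EMG,
#' and an optional table of programmed stimulation trials. At least one
#' channel must be present; when both photometry channels are present they
#' must share sampling rate, start time and length.
#'
#' @param animal_id opaque animal identifier.
#' @param photometry465,photometry405 optional [time_series()] in a.u.
#' @param pressure optional [time_series()] in cmH2O.
#' @param emg optional [time_series()] in mV.
#' @param stim_train optional data.frame with columns `onset_s`, `duration_s`.
#' @param metadata named list of free-form session metadata
#'   (e.g. `infusion_rate_ul_min`).
#' @return An object of class `lut_session`.
#' @export
session_bundle <- function(animal_id, photometry465 = NULL, photometry405 = NULL,
                           pressure = NULL, emg = NULL, stim_train = NULL,
                           metadata = list()) {
  chans <- list(photometry465 = photometry465, photometry405 = photometry405,
                pressure = pressure, emg = emg)
  present <- !vapply(chans, is.null, logical(1))
  if (!any(present)) stop("session_bundle: at least one channel required")
  for (nm in names(chans)[present])
    if (!inherits(chans[[nm]], "lut_ts"))
      stop(sprintf("session_bundle: '%s' must be a time_series", nm))
  if (!is.null(photometry465) && !is.null(photometry405)) {
    if (photometry465$fs != photometry405$fs ||
        photometry465$t0 != photometry405$t0 ||
        length(photometry465$values) != length(photometry405$values))
      stop("session_bundle: photometry channels must share fs, t0 and length")
  }
  expected_units <- c(photometry465 = "a.u.", photometry405 = "a.u.",
                      pressure = "cmH2O", emg = "mV")
  for (nm in names(chans)[present])
    if (chans[[nm]]$units != expected_units[[nm]])
      stop(sprintf("session_bundle: channel '%s' must have units '%s', got '%s'",
                   nm, expected_units[[nm]], chans[[nm]]$units))
  structure(
    list(animal_id = as.character(animal_id),
         photometry465 = photometry465, photometry405 = photometry405,
         pressure = pressure, emg = emg,
         stim_train = stim_train, metadata = metadata),
    class = "lut_session")
}

#' @export
print.lut_session <- function(x, ...) {
  present <- c("photometry465", "photometry405", "pressure", "emg")
  present <- present[!vapply(x[present], is.null, logical(1))]
  cat(sprintf("<lut_session> animal %s: channels {%s}%s\n", x$animal_id,
              paste(present, collapse = ", "),
              if (!is.null(x$stim_train))
                sprintf(", %d stim trials", nrow(x$stim_train)) else ""))
  invisible(x)
}
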