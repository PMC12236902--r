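#' Default analysis configuration
#'
#' Every analysis threshold used by the pipeline is a named key with its
#' default value. Pass overrides as `lut_config(key = value, ...)` or load a
#' flat TOML-dialect file with [read_config()].
#'
#' Key groups (units in parentheses):
#' \describe{
#'   \item{photometry}{`dff_target_dt_s` (s) downsample resolution;
#'     `dff_baseline_family` first family of the baseline-fit cascade
#'     (`"double_exp"`, then `"single_exp"`, then `"poly2"`);
#'     `isosbestic_fit` `"lsq"` (least-squares gain+offset rescale of the
#'     405 channel) or `"raw"` (direct subtraction);
#'     `baseline_guard_eps` (dF/F0 units) divide-by-small-baseline guard;
#'     `peri_window_s` (s) half-width of the peri-event window.}
#'   \item{cystometry}{`contraction_prominence_cmh2o` (cmH2O) detection
#'     threshold; `min_interevent_s` (s); `detrend_span_s` (s) running-median
#'     span; `smooth_s` (s) moving-average width for dP/dt;
#'     `search_back_s` (s) dP/dt search-back window before peak pressure;
#'     `pre_baseline_s` (s) pre-episode segment for the rise measurement;
#'     `peak_prominence_frac` within-episode peak-counting prominence as a
#'     fraction of the episode rise; `nvc_min_rise_cmh2o` (cmH2O) inclusion
#'     threshold for non-voiding contractions.}
#'   \item{emg}{`emg_drop_frac` response threshold (fraction of baseline
#'     total power); `cmg_rise_cmh2o` (cmH2O) pressure-response threshold;
#'     `artifact_mad_mult` robust amplitude multiple flagging baseline
#'     artifacts; `artifact_min_ms` (ms) minimum artifact duration;
#'     `ttp_remove_dc` subtract the epoch mean before total power.}
#'   \item{mvt}{`mvt_threshold_mode` `"otsu"` or `"fixed"`;
#'     `mvt_fixed_level` 8-bit threshold when fixed; `template_area_cm2`
#'     (cm2) known area of the reflecting template; `min_spot_px` components
#'     below this pixel count are dropped as noise; `void_area_min_cm2`
#'     (cm2) and `corner_radius_cm` (cm) void-vs-leak geometric rule;
#'     `volume_slope_ul_per_cm2`, `volume_intercept_ul` linear area-to-volume
#'     calibration curve; `mark_latency_max_s` (s) and `mark_count_min`
#'     dominance screen.}
#' }
#'
#' @param ... named overrides of default keys. Unknown keys are an error.
#' @return named list of configuration values.
#' @export
lut_config <- function(...) {
  cfg <- list(
    # photometry
    dff_target_dt_s = 0.1,
    dff_baseline_family = "double_exp",
    isosbestic_fit = "lsq",
    baseline_guard_eps = 0.005,
    peri_window_s = 60,
    # cystometry
    contraction_prominence_cmh2o = 5,
    min_interevent_s = 20,
    detrend_span_s = 120,
    smooth_s = 1,
    search_back_s = 15,
    pre_baseline_s = 30,
    peak_prominence_frac = 0.2,
    nvc_min_rise_cmh2o = 5,
    confirm_match_tol_s = 5,
    # emg
    emg_drop_frac = 0.05,
    cmg_rise_cmh2o = 3,
    artifact_mad_mult = 8,
    artifact_min_ms = 2,
    ttp_remove_dc = TRUE,
    # mvt
    mvt_threshold_mode = "otsu",
    mvt_fixed_level = 128,
    template_area_cm2 = 10,
    min_spot_px = 12,
    void_area_min_cm2 = 0.5,
    corner_radius_cm = 7,
    volume_slope_ul_per_cm2 = 50,
    volume_intercept_ul = 0,
    mark_latency_max_s = 300,
    mark_count_min = 10
  )
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(names(over) == ""))
      stop("lut_config: overrides must be named")
    bad <- setdiff(names(over), names(cfg))
    if (length(bad))
      stop("lut_config: unknown config keys: ", paste(bad, collapse = ", "))
    cfg[names(over)] <- over
  }
  cfg
}

#' Read a flat key-value configuration file
#'
#' The format is a flat TOML dialect: one `key = value` pair per line,
#' `#` comments, bare numbers, `true`/`false`, and double-quoted strings.
#' Keys must be known configuration keys (see [lut_config()]).
#'
#' @param path file path.
#' @return named list as from [lut_config()], with the file's overrides.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  over <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(.+)$", ln))[[1]]
    if (length(m) != 3L)
      stop("read_config: malformed line: ", ln)
    key <- m[2]; raw <- trimws(m[3])
    val <- if (grepl('^".*"$', raw)) {
      substr(raw, 2, nchar(raw) - 1)
    } else if (raw %in% c("true", "false")) {
      raw == "true"
    } else {
      v <- suppressWarnings(as.numeric(raw))
      if (is.na(v)) stop("read_config: unparseable value for ", key, ": ", raw)
      v
    }
    over[[key]] <- val
  }
  do.call(lut_config, over)
}

#' Write a configuration to a flat key-value file
#' @param cfg named list as from [lut_config()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  fmt <- vapply(names(cfg), function(k) {
    v <- cfg[[k]]
    s <- if (is.character(v)) sprintf('"%s"', v)
         else if (is.logical(v)) tolower(as.character(v))
         else sprintf("%.17g", v)
    sprintf("%s = %s", k, s)
  }, character(1))
  writeLines(fmt, path)
  invisible(path)
}
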