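# Micturition video thermography: threshold the 8-bit frame, label
# connected warm regions, calibrate pixel area through the 10 cm2
# reflecting template, convert area to volume through the linear
# calibration curve, and classify spots geometrically (void / leak / mark).

# 8-connectivity connected-component labeling by BFS flood fill.
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  stack <- integer(sum(mask))
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    lab[start] <- cur
    stack[1L] <- start; sp <- 1L
    while (sp > 0L) {
      i <- stack[sp]; sp <- sp - 1L
      r <- (i - 1L) %% nr + 1L
      cc <- (i - 1L) %/% nr + 1L
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        rr <- r + dr; ccn <- cc + dc
        if (rr < 1L || rr > nr || ccn < 1L || ccn > nc) next
        j <- (ccn - 1L) * nr + rr
        if (mask[j] && lab[j] == 0L) {
          lab[j] <- cur
          sp <- sp + 1L; stack[sp] <- j
        }
      }
    }
  }
  lab
}

#' Segment warm regions in a thermal frame
#'
#' Thresholds the 8-bit grayscale frame (Otsu by default, or a fixed level)
#' and labels connected foreground components with 8-connectivity.
#' Components smaller than `min_spot_px` are dropped as noise.
#'
#' @param img numeric matrix of gray levels 0..255 (see
#'   [read_gray_image()]).
#' @param config analysis configuration; uses `mvt_threshold_mode`,
#'   `mvt_fixed_level`, `min_spot_px`.
#' @return data.frame of regions: `region_id`, `area_px`, `cx`, `cy`
#'   (0-based centroid column/row), `mean_level`; plus attribute
#'   `"threshold"`.
#' @export
segment_spots <- function(img, config = lut_config()) {
  stopifnot(is.matrix(img))
  thr <- if (identical(config$mvt_threshold_mode, "fixed")) {
    config$mvt_fixed_level
  } else {
    EBImage::otsu(EBImage::Image(img / 255), range = c(0, 1)) * 255
  }
  mask <- img > thr
  if (!any(mask)) {
    out <- data.frame(region_id = integer(0), area_px = integer(0),
                      cx = numeric(0), cy = numeric(0),
                      mean_level = numeric(0))
    attr(out, "threshold") <- thr
    return(out)
  }
  lab <- label_components(mask)
  ids <- seq_len(max(lab))
  idx <- which(lab > 0L)
  lv <- lab[idx]
  rr <- (idx - 1L) %% nrow(img)        # 0-based row (y)
  cc <- (idx - 1L) %/% nrow(img)       # 0-based col (x)
  area <- tabulate(lv, nbins = max(lab))
  cx <- tapply(cc, lv, mean)
  cy <- tapply(rr, lv, mean)
  ml <- tapply(img[idx], lv, mean)
  out <- data.frame(region_id = ids, area_px = area,
                    cx = as.numeric(cx), cy = as.numeric(cy),
                    mean_level = as.numeric(ml))
  out <- out[out$area_px >= config$min_spot_px, , drop = FALSE]
  out <- out[order(-out$area_px), , drop = FALSE]
  out$region_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "threshold") <- thr
  lut_log("segment_spots", sprintf("%d regions above threshold %.1f",
                                   nrow(out), thr))
  out
}

#' Calibrate the pixel-to-area scale from the reflecting template
#'
#' The brightest segmented region (or an explicitly identified one) is the
#' reflecting template of known area; its pixel count fixes the
#' pixels-per-cm2 scale of the frame, absorbing camera height and angle.
#'
#' @param regions data.frame from [segment_spots()].
#' @param known_area_cm2 true template area (default 10 cm2).
#' @param template_id optional `region_id` of the template; by default the
#'   region with the highest mean gray level.
#' @param volume_slope_ul_per_cm2,volume_intercept_ul linear area-to-volume
#'   curve coefficients.
#' @return list of class `lut_calibration`: `px_per_cm2`,
#'   `template_region_id`, `template_area_px`, `volume_slope_ul_per_cm2`,
#'   `volume_intercept_ul`.
#' @export
calibrate <- function(regions, known_area_cm2 = 10, template_id = NULL,
                      volume_slope_ul_per_cm2 = lut_config()$volume_slope_ul_per_cm2,
                      volume_intercept_ul = lut_config()$volume_intercept_ul) {
  if (!nrow(regions)) stop("calibrate: template not found (no regions)")
  tid <- template_id %||% regions$region_id[which.max(regions$mean_level)]
  row <- regions[regions$region_id == tid, , drop = FALSE]
  if (!nrow(row)) stop("calibrate: template not found (region_id ", tid, ")")
  structure(list(px_per_cm2 = row$area_px / known_area_cm2,
                 template_region_id = tid,
                 template_area_px = row$area_px,
                 volume_slope_ul_per_cm2 = volume_slope_ul_per_cm2,
                 volume_intercept_ul = volume_intercept_ul),
            class = "lut_calibration")
}

#' Estimate void volume from calibrated spot area
#'
#' Linear calibration curve `volume = slope x area + intercept`, clipped at
#' zero. The default curve is linear through the origin with a configurable
#' slope; generator and analyzer share the curve, so synthetic recovery is
#' exact up to segmentation error.
#'
#' @param area_cm2 calibrated spot area(s), cm2.
#' @param model an `lut_calibration` from [calibrate()].
#' @return estimated volume(s), uL.
#' @export
estimate_volume <- function(area_cm2, model) {
  pmax(0, model$volume_slope_ul_per_cm2 * area_cm2 +
         model$volume_intercept_ul)
}

#' Quantify and classify urine spots in a thermal frame
#'
#' Runs segmentation, template calibration, area and volume estimation, and
#' the geometric void/leak/mark classification. The classification is a
#' documented proxy for the behavioral one: mice void in arena corners, so
#' a spot is a `void` when its area reaches `void_area_min_cm2` and its
#' centroid lies within `corner_radius_cm` of an arena corner; otherwise it
#' is a `leak`, except that in marking mode sub-void-size non-corner spots
#' are `mark`s.
#'
#' @param img numeric gray-level matrix.
#' @param mode `"voiding"` or `"marking"`.
#' @param config analysis configuration.
#' @param t_appear_s optional appearance times matched to spots by
#'   decreasing area (used by [marking_metrics()]).
#' @return list: `spots` (data.frame: spot_id, cx, cy, area_px, area_cm2,
#'   volume_ul, corner_distance_cm, klass, t_appear_s), `calibration`,
#'   `regions` (raw segmentation).
#' @export
quantify_frame <- function(img, mode = c("voiding", "marking"),
                           config = lut_config(), t_appear_s = NULL) {
  mode <- match.arg(mode)
  regions <- segment_spots(img, config)
  cal <- calibrate(regions, config$template_area_cm2,
                   volume_slope_ul_per_cm2 = config$volume_slope_ul_per_cm2,
                   volume_intercept_ul = config$volume_intercept_ul)
  spots <- regions[regions$region_id != cal$template_region_id, ,
                   drop = FALSE]
  px_per_cm <- sqrt(cal$px_per_cm2)
  corners <- rbind(c(0, 0), c(ncol(img) - 1, 0),
                   c(0, nrow(img) - 1), c(ncol(img) - 1, nrow(img) - 1))
  cdist <- vapply(seq_len(nrow(spots)), function(i)
    min(sqrt((spots$cx[i] - corners[, 1])^2 +
               (spots$cy[i] - corners[, 2])^2)) / px_per_cm, numeric(1))
  area_cm2 <- spots$area_px / cal$px_per_cm2
  is_void <- area_cm2 >= config$void_area_min_cm2 &
    cdist <= config$corner_radius_cm
  klass <- ifelse(is_void, "void",
                  ifelse(mode == "marking" &
                           area_cm2 < config$void_area_min_cm2 &
                           cdist > config$corner_radius_cm,
                         "mark", "leak"))
  n <- nrow(spots)
  out <- data.frame(
    spot_id = if (n) sprintf("spot%02d", seq_len(n)) else character(0),
    cx = spots$cx, cy = spots$cy, area_px = spots$area_px,
    area_cm2 = area_cm2,
    volume_ul = estimate_volume(area_cm2, cal),
    corner_distance_cm = cdist, klass = klass,
    t_appear_s = if (is.null(t_appear_s)) rep(NA_real_, n)
                 else rep_len(t_appear_s, n),
    stringsAsFactors = FALSE)
  list(spots = out, calibration = cal, regions = regions)
}

#' Scent-marking metrics for one session
#'
#' Mark count excludes typical corner voids; latency is measured from the
#' urine-stimulus presentation to the first mark (censored at session end
#' when no marks occur). The dominance screen requires marking to start
#' within the first 5 minutes (`mark_latency_max_s`) and at least 10 marks
#' (`mark_count_min`) in the session.
#'
#' @param mark_times_s times of non-corner-void mark events, seconds.
#' @param stimulus_time_s urine-stimulus presentation time, seconds.
#' @param session_end_s session end, seconds.
#' @param config analysis configuration.
#' @return list: `mark_count`, `latency_s`, `latency_censored`,
#'   `dominant`.
#' @export
marking_metrics <- function(mark_times_s, stimulus_time_s, session_end_s,
                            config = lut_config()) {
  stopifnot(stimulus_time_s >= 0, stimulus_time_s <= session_end_s)
  mt <- sort(mark_times_s[mark_times_s >= stimulus_time_s])
  count <- length(mt)
  censored <- count == 0L
  latency <- if (censored) session_end_s - stimulus_time_s
             else mt[1] - stimulus_time_s
  list(mark_count = count, latency_s = latency,
       latency_censored = censored,
       dominant = !censored && latency <= config$mark_latency_max_s &&
         count >= config$mark_count_min)
}

#' Per-animal session summary
#'
#' Counts of voids and leaks, mean volume per void, and (in marking mode)
#' mark count, latency and dominance. Two-run averaging of a pair of
#' summaries is provided by [average_runs()].
#'
#' @param spots data.frame from [quantify_frame()]`$spots` (the union over
#'   a session's frames).
#' @param mode `"voiding"` or `"marking"`.
#' @param stimulus_time_s,session_end_s required in marking mode.
#' @param config analysis configuration.
#' @return one-row data.frame: `n_voids`, `n_leaks`, `mean_void_volume_ul`,
#'   and in marking mode `n_marks`, `latency_s`, `dominant`.
#' @export
session_summary <- function(spots, mode = c("voiding", "marking"),
                            stimulus_time_s = NULL, session_end_s = NULL,
                            config = lut_config()) {
  mode <- match.arg(mode)
  n_voids <- sum(spots$klass == "void")
  n_leaks <- sum(spots$klass == "leak")
  mv <- if (n_voids) mean(spots$volume_ul[spots$klass == "void"]) else 0
  out <- data.frame(n_voids = n_voids, n_leaks = n_leaks,
                    mean_void_volume_ul = mv)
  if (mode == "marking") {
    stopifnot(!is.null(stimulus_time_s), !is.null(session_end_s))
    mm <- marking_metrics(spots$t_appear_s[spots$klass == "mark"],
                          stimulus_time_s, session_end_s, config)
    out$n_marks <- mm$mark_count
    out$latency_s <- mm$latency_s
    out$dominant <- mm$dominant
  }
  out
}

#' Average two session-summary runs
#'
#' Behavioral sessions are run twice per condition and averaged; numeric
#' fields are averaged, logical fields combined by "either run".
#'
#' @param run1,run2 one-row data.frames from [session_summary()].
#' @return averaged one-row data.frame.
#' @export
average_runs <- function(run1, run2) {
  stopifnot(identical(names(run1), names(run2)))
  out <- run1
  for (nm in names(out)) {
    out[[nm]] <- if (is.logical(run1[[nm]])) run1[[nm]] | run2[[nm]]
                 else (run1[[nm]] + run2[[nm]]) / 2
  }
  out
}
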