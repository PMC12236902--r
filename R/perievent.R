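# Event-aligned analysis: peri-event matrices over the -60..+60 s window,
# shuffle-null pseudo-events, mean +/- SEM traces, per-animal equally
# weighted subsampling, and nonparametric group comparison.

#' Build a peri-event matrix
#'
#' One row per included event; the lag axis spans `-peri_window_s` to
#' `+peri_window_s` at the dF/F0 resolution. Rows are normalized per event
#' (`"percent"`, via [normalize_per_event()]), z-scored over the window
#' (`"zscore"`), or kept raw with the pre-event baseline subtracted
#' (`"raw"`). Events whose window leaves the trace are dropped with a
#' logged reason. Row order is deterministic: by animal, then event time.
#'
#' @param dff an `lut_dff` trace.
#' @param events event table (see [read_events()]); only `included` rows
#'   with kind `"void"` or `"nvc"` (or `"stim"`) are used.
#' @param normalization `"percent"`, `"zscore"` or `"raw"`.
#' @param config analysis configuration.
#' @return object of class `lut_pem`: `values` (events x lags matrix),
#'   `lag_s`, `rows` (data.frame: event_id, animal_id, kind, t_align_s,
#'   guard_flagged), `normalization`, `dropped` (data.frame of dropped
#'   events and reasons).
#' @export
build_matrix <- function(dff, events,
                         normalization = c("percent", "zscore", "raw"),
                         config = lut_config()) {
  normalization <- match.arg(normalization)
  w <- config$peri_window_s
  nlag <- as.integer(round(w * dff$fs))
  lag_s <- seq(-nlag, nlag) / dff$fs
  ev <- events[events$included, , drop = FALSE]
  ev <- ev[order(ev$animal_id, ev$t_align_s), , drop = FALSE]
  vals <- list(); meta <- list(); dropped <- list()
  for (i in seq_len(nrow(ev))) {
    e <- ev[i, ]
    i0 <- as.integer(round((e$t_align_s - dff$t0) * dff$fs)) + 1L
    if (i0 - nlag < 1L || i0 + nlag > length(dff$values)) {
      dropped[[length(dropped) + 1L]] <-
        data.frame(event_id = e$event_id, reason = "window_out_of_bounds")
      lut_log("build_matrix", sprintf("dropped %s: window out of bounds",
                                      e$event_id))
      next
    }
    win <- dff$values[(i0 - nlag):(i0 + nlag)]
    base <- mean(dff$values[(i0 - nlag):(i0 - 1L)])
    guard <- FALSE
    row <- switch(normalization,
      percent = {
        nz <- normalize_per_event(dff, e$t_align_s, config)
        guard <- nz$guard_flagged
        nz$values
      },
      zscore = zscore(win)$values,
      raw = win - base)
    vals[[length(vals) + 1L]] <- row
    meta[[length(meta) + 1L]] <-
      data.frame(event_id = e$event_id, animal_id = e$animal_id,
                 kind = e$kind, t_align_s = e$t_align_s,
                 guard_flagged = guard, stringsAsFactors = FALSE)
  }
  structure(list(
    values = if (length(vals)) do.call(rbind, vals)
             else matrix(numeric(0), 0, length(lag_s)),
    lag_s = lag_s,
    rows = if (length(meta)) do.call(rbind, meta)
           else data.frame(event_id = character(0), animal_id = character(0),
                           kind = character(0), t_align_s = numeric(0),
                           guard_flagged = logical(0)),
    normalization = normalization,
    dropped = if (length(dropped)) do.call(rbind, dropped)
              else data.frame(event_id = character(0), reason = character(0))),
    class = "lut_pem")
}

#' @export
print.lut_pem <- function(x, ...) {
  cat(sprintf("<lut_pem> %d events x %d lags (%s), %d dropped\n",
              nrow(x$values), ncol(x$values), x$normalization,
              nrow(x$dropped)))
  invisible(x)
}

#' Shuffle-null peri-event matrix
#'
#' Draws `n_events` pseudo-event times uniformly over the trace, with the
#' full +/-window margin kept from both edges so every pseudo-window fits,
#' and builds the matrix exactly as for real events. This estimates the
#' chance-level peri-event signal for the same trace and event count.
#' Optional exclusion zones (e.g. +/-60 s around true voids) are respected
#' by rejection sampling.
#'
#' @param dff an `lut_dff` trace.
#' @param n_events number of pseudo-events.
#' @param seed RNG seed; draws are deterministic given the seed.
#' @param exclusion_zones optional 2-column matrix of (start, end) times to
#'   avoid.
#' @param normalization as in [build_matrix()].
#' @param config analysis configuration.
#' @param animal_id label stamped on pseudo-events.
#' @return an `lut_pem` (kind `"shuffle"` rows).
#' @export
shuffle_null <- function(dff, n_events, seed, exclusion_zones = NULL,
                         normalization = c("percent", "zscore", "raw"),
                         config = lut_config(), animal_id = "shuffle") {
  normalization <- match.arg(normalization)
  w <- config$peri_window_s
  lo <- dff$t0 + w
  hi <- dff$t0 + (length(dff$values) - 1) / dff$fs - w
  if (hi <= lo)
    stop("shuffle_null: trace too short to host a +/-window pseudo-event")
  times <- with_seed(seed, {
    got <- numeric(0); tries <- 0L
    while (length(got) < n_events) {
      tries <- tries + 1L
      if (tries > 1000L * max(n_events, 1L))
        stop("shuffle_null: infeasible placement under the exclusion zones")
      cand <- runif(min(n_events * 2L, 1024L), lo, hi)
      if (!is.null(exclusion_zones) && nrow(exclusion_zones) > 0) {
        bad <- vapply(cand, function(tt)
          any(tt >= exclusion_zones[, 1] & tt <= exclusion_zones[, 2]),
          logical(1))
        cand <- cand[!bad]
      }
      got <- c(got, cand)
    }
    sort(got[seq_len(n_events)])
  })
  if (n_events == 0L) {
    ev <- empty_events()
  } else {
    ev <- data.frame(event_id = sprintf("shuf%04d", seq_len(n_events)),
                     animal_id = animal_id, kind = "nvc",
                     t_align_s = times, t_start_s = times - 1,
                     t_end_s = times + 1, included = TRUE,
                     exclusion_reason = "", stringsAsFactors = FALSE)
  }
  pem <- build_matrix(dff, ev, normalization, config)
  if (nrow(pem$rows)) pem$rows$kind <- "shuffle"
  pem
}

#' Mean and SEM trace of a peri-event matrix
#'
#' @param pem an `lut_pem`.
#' @return list: `lag_s`, `mean`, `sem` (NA-flagged when n = 1), `n`.
#' @export
average_trace <- function(pem) {
  n <- nrow(pem$values)
  if (n == 0L)
    return(list(lag_s = pem$lag_s, mean = rep(NA_real_, length(pem$lag_s)),
                sem = rep(NA_real_, length(pem$lag_s)), n = 0L))
  m <- colMeans(pem$values)
  sem <- if (n == 1L) rep(NA_real_, ncol(pem$values))
         else apply(pem$values, 2, sd) / sqrt(n)
  list(lag_s = pem$lag_s, mean = m, sem = sem, n = n)
}

#' Per-event summary values, equally weighted across animals
#'
#' For each animal, `n_per_animal` rows are sampled without replacement
#' (seeded) and each sampled row is reduced to its mean over the
#' `stat_window` lag range. Equal per-animal counts keep animals equally
#' weighted in pooled statistics. The subsample count is analysis-specific
#' and therefore a required argument.
#'
#' @param pem an `lut_pem`.
#' @param n_per_animal rows sampled per animal (error if any animal has
#'   fewer).
#' @param seed RNG seed.
#' @param stat_window numeric length-2: lag range (s) for the summary mean.
#' @return data.frame: `animal_id`, `event_id`, `value`.
#' @export
per_animal_summary <- function(pem, n_per_animal, seed,
                               stat_window = c(0, 10)) {
  if (nrow(pem$values) == 0L) stop("per_animal_summary: empty matrix")
  sel <- pem$lag_s >= stat_window[1] & pem$lag_s <= stat_window[2]
  stat <- rowMeans(pem$values[, sel, drop = FALSE])
  animals <- unique(pem$rows$animal_id)
  short <- animals[vapply(animals, function(a)
    sum(pem$rows$animal_id == a) < n_per_animal, logical(1))]
  if (length(short))
    stop("per_animal_summary: animal(s) with fewer than n_per_animal events: ",
         paste(short, collapse = ", "))
  with_seed(seed, {
    out <- lapply(animals, function(a) {
      idx <- which(pem$rows$animal_id == a)
      take <- if (length(idx) == n_per_animal) idx
              else sort(sample(idx, n_per_animal))
      data.frame(animal_id = a, event_id = pem$rows$event_id[take],
                 value = stat[take], stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

# Dunn's post-hoc z statistic on pooled ranks with tie correction;
# two-sided p-values adjusted by `method` (default Holm).
dunn_posthoc <- function(values, groups, method = "holm") {
  groups <- factor(groups)
  N <- length(values)
  r <- rank(values)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, groups, mean)
  ns <- tapply(r, groups, length)
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2)
  z <- p <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / ns[[a]] + 1 / ns[[b]]))
    z[j] <- (rbar[[a]] - rbar[[b]]) / se
    p[j] <- 2 * pnorm(-abs(z[j]))
  }
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z, p = p,
             p_adj = p.adjust(p, method = method),
             stringsAsFactors = FALSE)
}

#' Compare void, NVC and shuffle-null summary values
#'
#' Kruskal-Wallis omnibus test across the three groups, followed by Dunn's
#' pairwise comparisons with Holm adjustment (configurable method). With
#' exactly two non-empty groups a Mann-Whitney (Wilcoxon rank-sum) test is
#' reported instead.
#'
#' @param void_values,nvc_values,null_values numeric vectors of per-event
#'   summary values (e.g. from [per_animal_summary()]). `nvc_values` may be
#'   `NULL` for a two-group comparison.
#' @param p_adjust_method adjustment for the pairwise p-values.
#' @return list: `medians`, `n`, `omnibus` (`method`, `statistic`, `p`),
#'   `pairwise` (data.frame with `z`/`W`, `p`, `p_adj`).
#' @export
compare_groups <- function(void_values, nvc_values = NULL, null_values,
                           p_adjust_method = "holm") {
  gl <- list(void = void_values, nvc = nvc_values, shuffle = null_values)
  gl <- gl[!vapply(gl, is.null, logical(1))]
  if (any(vapply(gl, length, integer(1)) == 0L))
    stop("compare_groups: empty group(s): ",
         paste(names(gl)[vapply(gl, length, integer(1)) == 0L], collapse = ", "))
  values <- unlist(gl, use.names = FALSE)
  groups <- factor(rep(names(gl), vapply(gl, length, integer(1))),
                   levels = names(gl))
  if (length(gl) == 2L) {
    wt <- wilcox.test(gl[[1]], gl[[2]], exact = FALSE)
    pw <- data.frame(group1 = names(gl)[1], group2 = names(gl)[2],
                     W = unname(wt$statistic), p = wt$p.value,
                     p_adj = wt$p.value, stringsAsFactors = FALSE)
    omni <- list(method = "Mann-Whitney", statistic = unname(wt$statistic),
                 p = wt$p.value)
  } else {
    kw <- kruskal.test(values, groups)
    pw <- dunn_posthoc(values, groups, p_adjust_method)
    omni <- list(method = "Kruskal-Wallis", statistic = unname(kw$statistic),
                 p = kw$p.value)
  }
  list(medians = vapply(gl, median, numeric(1)),
       n = vapply(gl, length, integer(1)),
       omnibus = omni, pairwise = pw)
}
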