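# Session files are self-describing UTF-8 text: "#key=value" header lines
# (required: fs_hz, t0_s, channels, units, animal_id; free metadata as
# "#meta:key=value"), then a tab-separated body with a t_s column followed by
# one column per declared channel, one row per sample. Values are written with
# 17 significant digits so write -> read round-trips doubles bit-exactly.

.session_channels <- c("photometry465", "photometry405", "pressure", "emg")
.event_kinds <- c("void", "nvc", "stim", "mark", "leak")

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a session bundle to a delimited-text session file
#'
#' @param bundle a [session_bundle()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_session()] for the inverse; the round trip is lossless.
#' @export
write_session <- function(bundle, path) {
  if (!inherits(bundle, "lut_session")) stop("write_session: not a session bundle")
  chans <- .session_channels[!vapply(bundle[.session_channels], is.null, logical(1))]
  if (!length(chans)) stop("write_session: bundle has no channels")
  tss <- bundle[chans]
  fs <- unique(vapply(tss, function(x) x$fs, numeric(1)))
  t0 <- unique(vapply(tss, function(x) x$t0, numeric(1)))
  ns <- unique(vapply(tss, function(x) length(x$values), integer(1)))
  if (length(fs) != 1L || length(t0) != 1L || length(ns) != 1L)
    stop("write_session: all channels in one file must share fs, t0 and length")
  for (ts in tss)
    if (!all(is.finite(ts$values)))
      stop("write_session: non-finite values are not writable")
  hdr <- c(
    sprintf("#fs_hz=%s", fmt_num(fs)),
    sprintf("#t0_s=%s", fmt_num(t0)),
    sprintf("#animal_id=%s", bundle$animal_id),
    sprintf("#channels=%s", paste(chans, collapse = ",")),
    sprintf("#units=%s", paste(vapply(tss, function(x) x$units, character(1)),
                               collapse = ",")))
  if (length(bundle$metadata))
    hdr <- c(hdr, sprintf("#meta:%s=%s", names(bundle$metadata),
                          vapply(bundle$metadata, as.character, character(1))))
  tvals <- t0 + (seq_len(ns) - 1) / fs
  cols <- c(list(fmt_num(tvals)), lapply(tss, function(x) fmt_num(x$values)))
  body <- do.call(paste, c(cols, sep = "\t"))
  con <- tryCatch(file(path, "wb"), error = function(e)
    stop("write_session: cannot open path for writing: ", path))
  on.exit(close(con))
  writeLines(c(hdr, paste(c("t_s", chans), collapse = "\t"), body),
             con, sep = "\n")
  lut_log("write_session", sprintf("%d channels x %d samples -> %s",
                                   length(chans), ns, path))
  invisible(path)
}

#' Read a delimited-text session file
#'
#' Parses the `#key=value` header, validates the declared units against each
#' channel's role, and checks that the time column is uniform at the declared
#' sampling rate (implicit gaps and non-monotone times are rejected).
#'
#' @param path session file path.
#' @return a [session_bundle()].
#' @export
read_session <- function(path) {
  lines <- readLines(path, warn = FALSE)
  is_hdr <- startsWith(lines, "#")
  nhdr <- match(FALSE, is_hdr) - 1L
  if (is.na(nhdr) || nhdr < 1L)
    stop("read_session: format error: no header/body boundary found")
  hdr <- lines[seq_len(nhdr)]
  kv <- list()
  meta <- list()
  for (i in seq_along(hdr)) {
    m <- regmatches(hdr[i], regexec("^#(meta:)?([A-Za-z0-9_]+)=(.*)$", hdr[i]))[[1]]
    if (length(m) != 4L)
      stop(sprintf("read_session: format error in header line %d: '%s'", i, hdr[i]))
    if (m[2] == "meta:") meta[[m[3]]] <- m[4] else kv[[m[3]]] <- m[4]
  }
  req <- c("fs_hz", "t0_s", "channels", "units", "animal_id")
  miss <- setdiff(req, names(kv))
  if (length(miss))
    stop("read_session: format error: missing required header key(s): ",
         paste(miss, collapse = ", "))
  fs <- as.numeric(kv$fs_hz); t0 <- as.numeric(kv$t0_s)
  if (!is.finite(fs) || fs <= 0)
    stop("read_session: format error: fs_hz must be a positive number")
  chans <- strsplit(kv$channels, ",", fixed = TRUE)[[1]]
  units <- strsplit(kv$units, ",", fixed = TRUE)[[1]]
  if (length(units) != length(chans))
    stop("read_session: format error: units row does not match channels row")
  bad <- setdiff(chans, .session_channels)
  if (length(bad))
    stop("read_session: format error: unknown channel(s): ",
         paste(bad, collapse = ", "))
  body <- lines[(nhdr + 1L):length(lines)]
  colnames_row <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  if (!identical(colnames_row, c("t_s", chans)))
    stop("read_session: format error: body column names do not match header channels")
  body <- body[-1]
  mat <- matrix(as.numeric(unlist(strsplit(body, "\t", fixed = TRUE),
                                  use.names = FALSE)),
                ncol = length(chans) + 1L, byrow = TRUE)
  tcol <- mat[, 1]
  dt <- diff(tcol)
  if (any(dt <= 0))
    stop("read_session: sampling error: time column not strictly increasing")
  if (any(abs(dt - 1 / fs) > 1e-6 / fs))
    stop("read_session: sampling error: implicit gap or non-uniform time column")
  args <- list(animal_id = kv$animal_id, metadata = meta)
  for (j in seq_along(chans))
    args[[chans[j]]] <- time_series(mat[, j + 1L], fs = fs, t0 = t0,
                                    label = chans[j], units = units[j])
  do.call(session_bundle, args)
}

#' Write an event table to CSV
#'
#' Stable column order `event_id, animal_id, kind, t_align_s, t_start_s,
#' t_end_s, included, exclusion_reason`; times carry full double precision.
#'
#' @param events data.frame with the columns above (extra columns dropped).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  events <- validate_events(events)
  num <- function(x) ifelse(is.na(x), "", fmt_num(x))
  rows <- sprintf("%s,%s,%s,%s,%s,%s,%d,%s",
                  events$event_id, events$animal_id, events$kind,
                  num(events$t_align_s), num(events$t_start_s),
                  num(events$t_end_s), as.integer(events$included),
                  events$exclusion_reason)
  con <- tryCatch(file(path, "wb"), error = function(e)
    stop("write_events: cannot open path for writing: ", path))
  on.exit(close(con))
  writeLines(c("event_id,animal_id,kind,t_align_s,t_start_s,t_end_s,included,exclusion_reason",
               rows), con, sep = "\n")
  invisible(path)
}

#' Read an event table from CSV
#' @param path CSV path written by [write_events()] (or hand-authored with
#'   the same columns).
#' @return validated data.frame of events.
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(event_id = "character",
                                       animal_id = "character",
                                       kind = "character",
                                       t_align_s = "numeric",
                                       t_start_s = "numeric",
                                       t_end_s = "numeric",
                                       included = "integer",
                                       exclusion_reason = "character"))
  validate_events(df)
}

validate_events <- function(df) {
  req <- c("event_id", "animal_id", "kind", "t_align_s", "t_start_s",
           "t_end_s", "included", "exclusion_reason")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("events: missing column(s): ", paste(miss, collapse = ", "))
  df <- df[req]
  if (nrow(df) == 0L) {
    df$included <- as.logical(df$included)
    return(df)
  }
  bad <- setdiff(unique(df$kind), .event_kinds)
  if (length(bad))
    stop("events: unknown kind(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(df$event_id))
    stop("events: duplicate event_id(s): ",
         paste(unique(df$event_id[duplicated(df$event_id)]), collapse = ", "))
  df$included <- as.logical(df$included)
  df$exclusion_reason[is.na(df$exclusion_reason)] <- ""
  if (any(!df$included & !nzchar(df$exclusion_reason)))
    stop("events: excluded events must carry a non-empty exclusion_reason")
  ok <- df$included & is.finite(df$t_start_s) & is.finite(df$t_end_s)
  if (any(!(df$t_start_s[ok] < df$t_align_s[ok] &
            df$t_align_s[ok] < df$t_end_s[ok])))
    stop("events: included events must satisfy t_start < t_align < t_end")
  df
}

#' Merge session bundles recorded on different clocks
#'
#' A session file holds channels sharing one sampling clock; modalities
#' acquired at different rates (e.g. photometry vs cystometry) live in
#' separate files. This merges their bundles back into one session.
#'
#' @param ... [session_bundle()] objects with disjoint channels and equal
#'   `animal_id`.
#' @return a single [session_bundle()].
#' @export
merge_sessions <- function(...) {
  bundles <- list(...)
  stopifnot(length(bundles) >= 1L)
  if (length(bundles) == 1L) return(bundles[[1]])
  ids <- unique(vapply(bundles, function(b) b$animal_id, character(1)))
  if (length(ids) != 1L)
    stop("merge_sessions: bundles belong to different animals: ",
         paste(ids, collapse = ", "))
  args <- list(animal_id = ids, metadata = list())
  for (b in bundles) {
    for (ch in .session_channels) {
      if (is.null(b[[ch]])) next
      if (!is.null(args[[ch]]))
        stop("merge_sessions: channel '", ch, "' present in multiple bundles")
      args[[ch]] <- b[[ch]]
    }
    if (!is.null(b$stim_train)) args$stim_train <- b$stim_train
    args$metadata <- c(args$metadata, b$metadata)
  }
  args$metadata <- args$metadata[!duplicated(names(args$metadata))]
  do.call(session_bundle, args)
}

# Construct an empty but fully typed event table.
empty_events <- function() {
  data.frame(event_id = character(0), animal_id = character(0),
             kind = character(0), t_align_s = numeric(0),
             t_start_s = numeric(0), t_end_s = numeric(0),
             included = logical(0), exclusion_reason = character(0),
             stringsAsFactors = FALSE)
}
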