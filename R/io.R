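# Readers/writers for the two plain-text interchange formats and the
# sample-level annotation step that joins them.
#
# Recording CSV: header timestamp,x,y,z; ISO-8601 timestamps; accelerations
# in g.  Event-log CSV: header start,end,code.  Timestamps are stored at
# millisecond precision; device/video synchronisation is assumed done
# upstream, so hip and wrist streams share a common clock.

.parse_iso_time <- function(x) {
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
  if (anyNA(out)) {
    stop("unparseable ISO-8601 timestamp: ", x[which(is.na(out))[1L]],
         call. = FALSE)
  }
  # round to ms so round-trips through text are exact
  as.POSIXct(round(as.numeric(out) * 1000) / 1000, tz = "UTC",
             origin = "1970-01-01")
}

.format_iso_time <- function(t) {
  format(t, "%Y-%m-%dT%H:%M:%OS3", tz = "UTC")
}

#' Construct an accelerometer recording
#'
#' A recording is one subject x placement tri-axial acceleration stream with
#' uniform sampling: sample \eqn{i} (1-based) is taken at
#' \code{start_time + (i-1)/sample_rate_hz}.
#'
#' @param subject_id Subject identifier (single string).
#' @param placement \code{"hip"} or \code{"wrist"}.
#' @param sample_rate_hz Sampling rate in Hz; the study devices ran at 100 Hz.
#' @param start_time \code{POSIXct} time of the first sample (or an ISO-8601
#'   string).
#' @param samples Numeric matrix with N rows and columns \code{x,y,z},
#'   accelerations in g.
#' @return An object of class \code{pa_recording}.
#' @export
recording <- function(subject_id, placement, sample_rate_hz, start_time,
                      samples) {
  placement <- match.arg(placement, c("hip", "wrist"))
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1L ||
      sample_rate_hz <= 0) {
    stop("sample_rate_hz must be a single positive number", call. = FALSE)
  }
  if (is.character(start_time)) start_time <- .parse_iso_time(start_time)
  samples <- as.matrix(samples)
  if (ncol(samples) != 3L) stop("samples must have 3 columns", call. = FALSE)
  if (nrow(samples) < 1L) stop("recording must have at least one sample",
                               call. = FALSE)
  if (!all(is.finite(samples))) {
    stop("non-finite acceleration value in recording", call. = FALSE)
  }
  colnames(samples) <- c("x", "y", "z")
  structure(
    list(subject_id = as.character(subject_id), placement = placement,
         sample_rate_hz = sample_rate_hz, start_time = start_time,
         samples = samples),
    class = "pa_recording"
  )
}

#' @export
print.pa_recording <- function(x, ...) {
  cat(sprintf("<pa_recording> subject %s, %s, %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$placement, nrow(x$samples), x$sample_rate_hz,
              nrow(x$samples) / x$sample_rate_hz))
  invisible(x)
}

#' Per-sample timestamps of a recording
#'
#' @param rec A \code{pa_recording}.
#' @return Numeric vector of times in seconds since the epoch, length N.
#' @export
sample_times <- function(rec) {
  as.numeric(rec$start_time) +
    (seq_len(nrow(rec$samples)) - 1L) / rec$sample_rate_hz
}

#' Construct a direct-observation event log
#'
#' An ordered sequence of non-overlapping labelled intervals of observed
#' behaviour.  Events are sorted by start time; each event's interval is
#' half-open \code{[start, end)} so a boundary instant belongs to the later
#' event only.
#'
#' @param subject_id Subject identifier.
#' @param start,end \code{POSIXct} (or ISO-8601 string) vectors of event
#'   boundaries; \code{start < end} elementwise.
#' @param code Character vector of event codes from \code{\link{event_codes}}.
#' @return An object of class \code{pa_eventlog} with a data frame
#'   \code{$events}.
#' @export
eventlog <- function(subject_id, start, end, code) {
  if (is.character(start)) start <- .parse_iso_time(start)
  if (is.character(end)) end <- .parse_iso_time(end)
  code <- as.character(code)
  bad <- setdiff(unique(code), event_codes())
  if (length(bad) > 0L) {
    stop("unknown event code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (length(start) != length(end) || length(start) != length(code)) {
    stop("start, end and code must have equal length", call. = FALSE)
  }
  if (any(as.numeric(end) <= as.numeric(start))) {
    stop("every event must have start < end", call. = FALSE)
  }
  ord <- order(as.numeric(start))
  start <- start[ord]; end <- end[ord]; code <- code[ord]
  if (length(start) > 1L &&
      any(as.numeric(start[-1L]) < as.numeric(end[-length(end)]) - 1e-9)) {
    stop("overlapping events in log", call. = FALSE)
  }
  structure(
    list(subject_id = as.character(subject_id),
         events = data.frame(start = start, end = end, code = code,
                             stringsAsFactors = FALSE)),
    class = "pa_eventlog"
  )
}

#' @export
print.pa_eventlog <- function(x, ...) {
  cat(sprintf("<pa_eventlog> subject %s, %d events\n",
              x$subject_id, nrow(x$events)))
  invisible(x)
}

#' Read a raw accelerometer stream from CSV
#'
#' Expects a header row and columns \code{timestamp,x,y,z}; timestamps
#' ISO-8601, accelerations in g.  The first timestamp becomes the recording
#' start; the declared sampling rate is trusted for sample spacing.
#'
#' @param path CSV file path.
#' @param subject_id Subject identifier to attach.
#' @inheritParams recording
#' @return A \code{pa_recording}.
#' @export
read_recording <- function(path, subject_id, placement, sample_rate_hz) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "x", "y", "z")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop("recording file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ts <- .parse_iso_time(df$timestamp)
  if (is.unsorted(as.numeric(ts), strictly = FALSE)) {
    stop("non-monotone timestamps in ", path, call. = FALSE)
  }
  samples <- cbind(x = df$x, y = df$y, z = df$z)
  if (!all(is.finite(samples))) {
    stop("non-finite acceleration value in ", path, call. = FALSE)
  }
  recording(subject_id, placement, sample_rate_hz, ts[1L], samples)
}

#' Write a recording to CSV
#'
#' @param rec A \code{pa_recording}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_recording <- function(rec, path) {
  ts <- as.POSIXct(sample_times(rec), tz = "UTC", origin = "1970-01-01")
  df <- data.frame(timestamp = .format_iso_time(ts),
                   x = rec$samples[, "x"], y = rec$samples[, "y"],
                   z = rec$samples[, "z"])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a direct-observation event log from CSV
#'
#' Expects a header row and columns \code{start,end,code}.  Events may be
#' given in any order and are returned sorted by start time; overlapping
#' events or codes outside \code{\link{event_codes}} are errors.
#'
#' @param path CSV file path.
#' @param subject_id Subject identifier to attach.
#' @return A \code{pa_eventlog}.
#' @export
read_eventlog <- function(path, subject_id) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("start", "end", "code")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop("event-log file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  eventlog(subject_id, df$start, df$end, df$code)
}

#' Write an event log to CSV
#'
#' @param log A \code{pa_eventlog}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_eventlog <- function(log, path) {
  df <- data.frame(start = .format_iso_time(log$events$start),
                   end = .format_iso_time(log$events$end),
                   code = log$events$code)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assign observation codes to accelerometer samples
#'
#' Each sample receives the code of the event whose half-open interval
#' \code{[start, end)} contains its timestamp, or \code{"UNLABELED"} when no
#' event covers it.
#'
#' @param rec A \code{pa_recording}.
#' @param log A \code{pa_eventlog} for the same subject.
#' @return Character vector of per-sample codes, length \code{nrow(rec$samples)}.
#' @export
annotate_samples <- function(rec, log) {
  if (!identical(rec$subject_id, log$subject_id)) {
    stop("recording subject '", rec$subject_id,
         "' does not match event-log subject '", log$subject_id, "'",
         call. = FALSE)
  }
  t <- sample_times(rec)
  starts <- as.numeric(log$events$start)
  ends <- as.numeric(log$events$end)
  labels <- rep.int(UNLABELED, length(t))
  # events are sorted and disjoint: findInterval on starts locates the
  # candidate event; membership then only needs the end check
  idx <- findInterval(t, starts)
  inside <- idx >= 1L & t < ends[pmax(idx, 1L)]
  labels[inside] <- log$events$code[idx[inside]]
  labels
}
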