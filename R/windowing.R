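# Non-overlapping fixed-duration segmentation with majority-rule labels.
#
# The label of a window is the code covering a strict majority (>50%) of its
# samples.  Exact 50/50 ties have no strict majority and are excluded rather
# than broken arbitrarily.  Windows whose majority code is OUT_OF_VIEW or
# UNLABELED are kept in the sequence (so lag/lead indexing stays contiguous)
# but carry the EXCLUDED label and never enter training or evaluation.

#' Segment an annotated recording into labelled windows
#'
#' Windows tile the recording from the first sample in steps of
#' \code{duration_s * sample_rate_hz} samples; a trailing partial window is
#' dropped.  Each window gets the code covering the strict majority of its
#' samples, the fraction of samples that code covers, and a mixed flag set
#' when more than one distinct non-UNLABELED code occurs inside the window.
#'
#' @param rec A \code{pa_recording}.
#' @param labels Per-sample code vector from \code{\link{annotate_samples}}.
#' @param duration_s Window duration in seconds (study values: 1, 5, 10, 15).
#' @return A \code{pa_windows} object: a list with the window sample matrix
#'   boundaries and a data frame \code{$info} holding one row per window with
#'   columns \code{window_index} (0-based), \code{label} (an activity class or
#'   \code{"EXCLUDED"}), \code{mixed}, and \code{label_fraction}.
#' @export
segment_windows <- function(rec, labels, duration_s) {
  if (!is.numeric(duration_s) || length(duration_s) != 1L || duration_s <= 0) {
    stop("duration_s must be a single positive number", call. = FALSE)
  }
  n <- nrow(rec$samples)
  if (length(labels) != n) {
    stop("labels length must equal the number of samples", call. = FALSE)
  }
  win_len <- round(duration_s * rec$sample_rate_hz)
  if (win_len < 1L) {
    stop("duration_s * sample_rate_hz must be at least 1 sample",
         call. = FALSE)
  }
  n_win <- n %/% win_len
  if (n_win == 0L) {
    return(structure(list(rec = rec, win_len = win_len,
                          duration_s = duration_s,
                          info = data.frame(window_index = integer(0),
                                            label = character(0),
                                            mixed = logical(0),
                                            label_fraction = numeric(0))),
                     class = "pa_windows"))
  }
  label <- character(n_win)
  mixed <- logical(n_win)
  frac <- numeric(n_win)
  for (w in seq_len(n_win)) {
    sel <- labels[((w - 1L) * win_len + 1L):(w * win_len)]
    counts <- table(sel)
    top <- which.max(counts)
    top_code <- names(counts)[top]
    frac[w] <- as.numeric(counts[top]) / win_len
    label[w] <- if (frac[w] <= 0.5 ||
                    top_code %in% c(UNLABELED, "OUT_OF_VIEW")) {
      EXCLUDED
    } else {
      top_code
    }
    mixed[w] <- sum(names(counts) != UNLABELED) > 1L
  }
  structure(list(rec = rec, win_len = win_len, duration_s = duration_s,
                 info = data.frame(window_index = seq_len(n_win) - 1L,
                                   label = label, mixed = mixed,
                                   label_fraction = frac,
                                   stringsAsFactors = FALSE)),
            class = "pa_windows")
}

#' @export
print.pa_windows <- function(x, ...) {
  cat(sprintf("<pa_windows> %d windows of %g s (%d samples each), %d usable\n",
              nrow(x$info), x$duration_s, x$win_len,
              sum(x$info$label != EXCLUDED)))
  invisible(x)
}

#' Extract one window's tri-axial sample block
#'
#' @param windows A \code{pa_windows}.
#' @param window_index 0-based window index.
#' @return Numeric matrix (win_len x 3) of the window's samples.
#' @export
window_samples <- function(windows, window_index) {
  w <- window_index + 1L
  if (w < 1L || w > nrow(windows$info)) {
    stop("window_index out of range", call. = FALSE)
  }
  windows$rec$samples[((w - 1L) * windows$win_len + 1L):
                        (w * windows$win_len), , drop = FALSE]
}

#' Fraction of usable windows containing multiple activity codes
#'
#' The denominator counts windows with a usable (non-EXCLUDED) label; the
#' numerator those among them flagged as mixed.
#'
#' @param windows A \code{pa_windows} (or its \code{$info} data frame).
#' @return A single number in \[0, 1\].
#' @export
mixed_fraction <- function(windows) {
  info <- if (inherits(windows, "pa_windows")) windows$info else windows
  keep <- info$label != EXCLUDED
  if (!any(keep)) stop("no usable windows", call. = FALSE)
  mean(info$mixed[keep])
}
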