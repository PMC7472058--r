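# Window-level feature extraction.
#
# Twenty base features are computed from the vector magnitude (VM) of each
# window (the three cross-axis correlations are the exception: they need the
# raw axes, which are retained for that purpose).  Five temporal features
# summarise VM variability in the neighbouring windows.  All SD-type
# quantities use the population convention (divide by N).

#' Per-sample vector magnitude
#'
#' Collapses a tri-axial sample block to its Euclidean norm,
#' \eqn{VM_i = \sqrt{x_i^2 + y_i^2 + z_i^2}}.
#'
#' @param samples Numeric matrix with columns x, y, z (in g).
#' @return Numeric vector of the same length as \code{nrow(samples)}.
#' @export
vector_magnitude <- function(samples) {
  samples <- as.matrix(samples)
  if (nrow(samples) == 0L) stop("samples must be non-empty", call. = FALSE)
  sqrt(rowSums(samples^2))
}

.pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

#' Names of the base window features
#'
#' @return Character vector of the 20 base feature names, in table order.
#' @export
base_feature_names <- function() {
  c("vm_mean", "vm_sd", "vm_min", "vm_max", "vm_iqr",
    "vm_p10", "vm_p25", "vm_p50", "vm_p75", "vm_p95",
    "vm_cv", "vm_sum", "vm_power", "vm_p2p", "vm_median_crossings",
    "corr_xy", "corr_xz", "corr_yz", "dom_freq_hz", "dom_freq_mag")
}

#' Names of the lag/lead temporal features
#'
#' @return Character vector of the 5 temporal feature names.
#' @export
temporal_feature_names <- function() {
  c("sd_lag1", "sd_lag2", "sd_lead1", "sd_lead2", "sd_5win")
}

#' Dominant frequency of a VM signal in the 0.25-5 Hz band
#'
#' The mean is removed, the signal zero-padded (to at least 1024 points and a
#' power of two, so the band is resolvable even for 1 s windows) and the
#' discrete Fourier transform taken; the returned frequency is the location
#' of the maximum spectral magnitude within \eqn{[0.25, 5]} Hz, ties broken
#' toward the lower frequency.  A constant signal has zero spectral magnitude
#' everywhere and reports the band's lower edge.
#'
#' @param vm Numeric VM vector (length >= 2).
#' @param rate Sampling rate in Hz.
#' @return Named numeric vector \code{c(dom_freq_hz =, dom_freq_mag =)}.
#' @export
dominant_frequency <- function(vm, rate) {
  n <- length(vm)
  if (n < 2L) stop("vm must have at least 2 samples", call. = FALSE)
  if (rate < 10) {
    warning("sampling rate below 10 Hz: the 0.25-5 Hz band is only ",
            "partially resolvable", call. = FALSE)
  }
  nfft <- max(1024L, 2L^ceiling(log2(n)))
  padded <- c(vm - mean(vm), numeric(nfft - n))
  spec <- Mod(stats::fft(padded))[seq_len(nfft %/% 2L + 1L)]
  freqs <- (seq_along(spec) - 1L) * rate / nfft
  band <- which(freqs >= 0.25 & freqs <= 5.0)
  if (length(band) == 0L) {
    return(c(dom_freq_hz = 0.25, dom_freq_mag = 0))
  }
  mags <- spec[band]
  best <- band[which.max(mags)]      # which.max: first max = lowest frequency
  mag <- spec[best]
  if (mag <= .Machine$double.eps * nfft) {
    return(c(dom_freq_hz = 0.25, dom_freq_mag = 0))
  }
  c(dom_freq_hz = freqs[best], dom_freq_mag = mag)
}

.safe_cor <- function(a, b) {
  if (.pop_sd(a) == 0 || .pop_sd(b) == 0) return(0)
  stats::cor(a, b)
}

#' Base time- and frequency-domain features of one window
#'
#' Computes, on the window's VM: mean, SD, minimum, maximum, interquartile
#' range, the 10th/25th/50th/75th/95th percentiles (linear interpolation),
#' coefficient of variation (SD/mean, 0 when the mean is 0), signal sum, mean
#' signal power, peak-to-peak amplitude and median crossings; the Pearson
#' correlations of the raw axis pairs; and the dominant frequency in the
#' 0.25-5 Hz band with its spectral magnitude.  Median crossings count
#' adjacent sample pairs strictly straddling the window median.
#'
#' @param samples Numeric matrix (win_len x 3) of raw tri-axial samples.
#' @param rate Sampling rate in Hz.
#' @return Named numeric vector with the 20 entries of
#'   \code{\link{base_feature_names}}.
#' @export
base_features <- function(samples, rate) {
  samples <- as.matrix(samples)
  if (nrow(samples) < 2L) {
    stop("a window needs at least 2 samples", call. = FALSE)
  }
  vm <- vector_magnitude(samples)
  m <- mean(vm)
  s <- .pop_sd(vm)
  qs <- stats::quantile(vm, c(0.10, 0.25, 0.50, 0.75, 0.95), names = FALSE,
                        type = 7)
  med <- stats::median(vm)
  d <- vm - med
  crossings <- sum(d[-length(d)] * d[-1L] < 0)
  dom <- dominant_frequency(vm, rate)
  c(vm_mean = m,
    vm_sd = s,
    vm_min = min(vm),
    vm_max = max(vm),
    vm_iqr = qs[4L] - qs[2L],
    vm_p10 = qs[1L], vm_p25 = qs[2L], vm_p50 = qs[3L], vm_p75 = qs[4L],
    vm_p95 = qs[5L],
    vm_cv = if (m == 0) 0 else s / m,
    vm_sum = sum(vm),
    vm_power = mean(vm^2),
    vm_p2p = max(vm) - min(vm),
    vm_median_crossings = crossings,
    corr_xy = .safe_cor(samples[, 1L], samples[, 2L]),
    corr_xz = .safe_cor(samples[, 1L], samples[, 3L]),
    corr_yz = .safe_cor(samples[, 2L], samples[, 3L]),
    dom)
}

#' Lag/lead temporal features for a chronological window sequence
#'
#' For each window, returns the VM standard deviation of the windows one and
#' two positions earlier (lag) and later (lead), plus the population SD over
#' five per-window VM means centred on the current window (lag 2 through
#' lead 2).  Edge windows replicate the nearest existing window, so the first
#' window's lag features equal its own SD.
#'
#' @param win_mean Per-window VM means, in window order.
#' @param win_sd Per-window VM standard deviations, in window order.
#' @param win_msq Per-window VM mean squares; required only for the
#'   \code{"pooled"} variant.
#' @param five_window \code{"means"} (default): \code{sd_5win} is the
#'   population SD of the five per-window VM means.  \code{"pooled"}: the
#'   population SD of the raw VM samples pooled across the five windows.
#' @return Numeric matrix (n windows x 5) with columns
#'   \code{\link{temporal_feature_names}}.
#' @export
temporal_features <- function(win_mean, win_sd, win_msq = NULL,
                              five_window = c("means", "pooled")) {
  five_window <- match.arg(five_window)
  n <- length(win_mean)
  if (n < 1L) stop("window sequence must be non-empty", call. = FALSE)
  if (length(win_sd) != n) {
    stop("win_mean and win_sd must have equal length", call. = FALSE)
  }
  clamp <- function(i) pmin(pmax(i, 1L), n)
  i <- seq_len(n)
  neigh <- cbind(clamp(i - 2L), clamp(i - 1L), i, clamp(i + 1L), clamp(i + 2L))
  sd5 <- if (five_window == "means") {
    apply(neigh, 1L, function(ix) .pop_sd(win_mean[ix]))
  } else {
    if (is.null(win_msq)) {
      stop("win_msq is required for the pooled five-window SD", call. = FALSE)
    }
    # pooled population SD over equal-length windows from per-window moments
    apply(neigh, 1L, function(ix) {
      mu <- mean(win_mean[ix])
      sqrt(max(mean(win_msq[ix]) - mu^2, 0))
    })
  }
  out <- cbind(sd_lag1 = win_sd[clamp(i - 1L)],
               sd_lag2 = win_sd[clamp(i - 2L)],
               sd_lead1 = win_sd[clamp(i + 1L)],
               sd_lead2 = win_sd[clamp(i + 2L)],
               sd_5win = sd5)
  rownames(out) <- NULL
  out
}

# Base + temporal features for every window of one annotated recording.
# Temporal features use chronological neighbours even when a neighbour is
# EXCLUDED (the signal still exists); filtering happens afterwards.
.window_feature_frame <- function(rec, log, window_s, include_temporal,
                                  five_window = "means") {
  labels <- annotate_samples(rec, log)
  wins <- segment_windows(rec, labels, window_s)
  n_win <- nrow(wins$info)
  if (n_win == 0L) {
    return(NULL)
  }
  vm_all <- vector_magnitude(rec$samples)
  feats <- matrix(NA_real_, n_win, length(base_feature_names()),
                  dimnames = list(NULL, base_feature_names()))
  win_msq <- numeric(n_win)
  for (w in seq_len(n_win)) {
    rows <- ((w - 1L) * wins$win_len + 1L):(w * wins$win_len)
    feats[w, ] <- base_features(rec$samples[rows, , drop = FALSE],
                                rec$sample_rate_hz)
    win_msq[w] <- mean(vm_all[rows]^2)
  }
  if (include_temporal) {
    feats <- cbind(feats,
                   temporal_features(feats[, "vm_mean"], feats[, "vm_sd"],
                                     win_msq, five_window))
  }
  cbind(data.frame(subject_id = rec$subject_id, placement = rec$placement,
                   window_index = wins$info$window_index,
                   label = wins$info$label, mixed = wins$info$mixed,
                   stringsAsFactors = FALSE),
        as.data.frame(feats))
}

#' Build the window-level feature table for a cohort
#'
#' Runs annotation, segmentation and feature extraction for every subject and
#' returns one row per usable (non-EXCLUDED) window.  For the combined
#' \code{"hip_wrist"} placement the hip and wrist feature blocks computed on
#' the shared window grid are concatenated with placement-prefixed names;
#' windows usable at only one placement are dropped.
#'
#' @param sessions List of sessions, each a list with elements \code{hip} and
#'   \code{wrist} (\code{pa_recording}; a single placement may be absent if
#'   not requested) and \code{log} (\code{pa_eventlog}).
#' @param window_s Window duration in seconds.
#' @param placement \code{"hip"}, \code{"wrist"} or \code{"hip_wrist"}.
#' @param include_temporal Add the five lag/lead features?
#' @param five_window Variant of the five-window SD; see
#'   \code{\link{temporal_features}}.
#' @return Data frame with columns \code{subject_id}, \code{placement},
#'   \code{window_index}, \code{label}, \code{mixed}, then the feature
#'   columns (20 or 25 per placement).
#' @export
build_feature_table <- function(sessions, window_s,
                                placement = c("hip", "wrist", "hip_wrist"),
                                include_temporal = TRUE,
                                five_window = "means") {
  placement <- match.arg(placement)
  single <- function(pl) {
    frames <- lapply(sessions, function(s) {
      rec <- s[[pl]]
      if (is.null(rec)) {
        stop("session for subject '", s$log$subject_id,
             "' has no ", pl, " recording", call. = FALSE)
      }
      .window_feature_frame(rec, s$log, window_s, include_temporal,
                            five_window)
    })
    do.call(rbind, frames)
  }
  if (placement != "hip_wrist") {
    tab <- single(placement)
    return(tab[tab$label != EXCLUDED, , drop = FALSE])
  }
  hip <- single("hip")
  wrist <- single("wrist")
  feat_cols <- setdiff(names(hip),
                       c("subject_id", "placement", "window_index", "label",
                         "mixed"))
  key_h <- paste(hip$subject_id, hip$window_index)
  key_w <- paste(wrist$subject_id, wrist$window_index)
  usable <- intersect(key_h[hip$label != EXCLUDED],
                      key_w[wrist$label != EXCLUDED])
  hi <- hip[match(usable, key_h), , drop = FALSE]
  wi <- wrist[match(usable, key_w), , drop = FALSE]
  dropped <- sum(hip$label != EXCLUDED) + sum(wrist$label != EXCLUDED) -
    2L * length(usable)
  if (dropped > 0L) {
    message(dropped, " single-placement windows dropped for the combined table")
  }
  out <- cbind(data.frame(subject_id = hi$subject_id,
                          placement = "hip_wrist",
                          window_index = hi$window_index,
                          label = hi$label, mixed = hi$mixed | wi$mixed,
                          stringsAsFactors = FALSE),
               stats::setNames(hi[feat_cols], paste0("hip_", feat_cols)),
               stats::setNames(wi[feat_cols], paste0("wrist_", feat_cols)))
  rownames(out) <- NULL
  out
}

#' Column names of the feature block of a feature table
#'
#' @param table A feature table from \code{\link{build_feature_table}}.
#' @return Character vector of feature column names.
#' @export
feature_columns <- function(table) {
  setdiff(names(table),
          c("subject_id", "placement", "window_index", "label", "mixed"))
}
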