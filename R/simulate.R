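# Bout-structured free-play simulator.
#
# Behaviour is a semi-Markov chain over the five activity classes with
# exponential bout durations, emulating the short intermittent activity
# bursts typical of preschool free play.  Signals are gravity plus a
# class-specific sinusoid (periodic locomotion) or irregular noise, with a
# subject-level amplitude random effect so leave-one-subject-out evaluation
# is non-trivial.  The wrist stream adds extra noise and random-phase bursts
# during sedentary/light bouts, mimicking uninstructed arm movements.

#' Simulator configuration
#'
#' Defaults describe a 20 min free-play session sampled at 100 Hz with
#' short intermittent bouts.  Class signal parameters (VM level above the
#' 1 g gravity baseline, white-noise SD, locomotion frequency and amplitude)
#' are chosen so the five classes are separable but neighbouring classes
#' overlap: light vs moderate-vigorous play differ mainly in noise energy,
#' walking (about 2 Hz) and running (about 3 Hz) in step frequency and
#' amplitude.
#'
#' @param n_subjects Number of simulated children.
#' @param session_s Session length in seconds (default 1200 = 20 min).
#' @param rate_hz Sampling rate in Hz (default 100).
#' @param class_params Data frame with one row per activity class and columns
#'   \code{class}, \code{level_g}, \code{noise_g}, \code{freq_hz}
#'   (\code{NA} = aperiodic), \code{amp_g}, \code{bout_mean_s}.
#' @param transition Optional 5 x 5 nonnegative matrix of class transition
#'   weights (rows = from); the diagonal is ignored.  Default: weights decay
#'   with the vigour distance between classes, so bouts of similar intensity
#'   cluster in time.
#' @param p_out_of_view Probability that a bout is coded OUT_OF_VIEW by the
#'   observer (the signal continues underneath).
#' @param wrist_extra_noise Additional white-noise SD (g) on the wrist axes.
#' @param wrist_burst_rate Poisson rate (per second) of short random wrist
#'   bursts during SED and LIGHT_AG bouts.
#' @param subject_sd Log-scale SD of the per-subject amplitude multiplier.
#' @param obs_jitter_s SD (seconds) of the observer's transition-timing
#'   error: observed event boundaries wander around the true bout
#'   boundaries, as human video coders mark transitions with latency.
#'   Mislabels a thin margin of samples at each transition, so it mainly
#'   degrades short prediction windows.
#' @param seed Integer master seed; each subject draws from a seed derived
#'   from it.
#' @return A \code{pa_sim_config} list.
#' @export
sim_config <- function(n_subjects = 15L, session_s = 1200, rate_hz = 100,
                       class_params = default_class_params(),
                       transition = NULL, p_out_of_view = 0.04,
                       wrist_extra_noise = 0.08, wrist_burst_rate = 0.1,
                       subject_sd = 0.2, obs_jitter_s = 0.3, seed = 1L) {
  stopifnot(n_subjects >= 1L, session_s > 0, rate_hz > 0,
            p_out_of_view >= 0, p_out_of_view < 1, wrist_extra_noise >= 0,
            obs_jitter_s >= 0)
  cls <- activity_classes()
  if (!identical(sort(class_params$class), sort(cls))) {
    stop("class_params must have one row per activity class", call. = FALSE)
  }
  class_params <- class_params[match(cls, class_params$class), ]
  f <- class_params$freq_hz
  if (any(!is.na(f) & (f < 0.25 | f > 5))) {
    stop("locomotion frequencies must lie in [0.25, 5] Hz", call. = FALSE)
  }
  if (is.null(transition)) {
    # behaviour has intensity persistence: transitions favour classes of
    # similar vigour (a running child shifts to active play far more often
    # than straight to sitting), so nearby bouts carry related intensity
    rank <- c(SED = 1, LIGHT_AG = 2, WALK = 3, MV_AG = 4, RUN = 5)
    transition <- outer(rank[cls], rank[cls],
                        function(a, b) exp(-abs(a - b) / 0.8))
    dimnames(transition) <- list(cls, cls)
    diag(transition) <- 0
  }
  if (any(transition < 0) || all(transition == 0)) {
    stop("transition weights must be nonnegative and not all zero",
         call. = FALSE)
  }
  structure(list(n_subjects = as.integer(n_subjects), session_s = session_s,
                 rate_hz = rate_hz, class_params = class_params,
                 transition = transition, p_out_of_view = p_out_of_view,
                 wrist_extra_noise = wrist_extra_noise,
                 wrist_burst_rate = wrist_burst_rate,
                 subject_sd = subject_sd, obs_jitter_s = obs_jitter_s,
                 seed = as.integer(seed)),
            class = "pa_sim_config")
}

#' Default class signal and bout parameters
#'
#' @return Data frame of per-class simulator parameters; see
#'   \code{\link{sim_config}}.
#' @export
default_class_params <- function() {
  data.frame(
    class = c("SED", "LIGHT_AG", "MV_AG", "WALK", "RUN"),
    level_g = c(1.00, 1.03, 1.10, 1.05, 1.15),
    noise_g = c(0.02, 0.10, 0.21, 0.10, 0.15),
    freq_hz = c(NA, NA, NA, 2.0, 3.0),
    amp_g = c(0, 0, 0, 0.22, 0.40),
    bout_mean_s = c(30, 18, 10, 8, 6),
    stringsAsFactors = FALSE
  )
}

.subject_seed <- function(cfg, i) {
  (cfg$seed %% 100000L) * 10000L + i * 37L
}

# smooth (AR(1)) body-acceleration noise with stationary SD `sd` and a
# correlation time of ~0.25 s; real acceleration is band-limited, so a 1 s
# window holds far fewer effective samples than raw samples
.ar_noise <- function(n, sd, rate) {
  if (sd == 0 || n == 0L) return(numeric(n))
  phi <- exp(-1 / (0.25 * rate))
  innov <- stats::rnorm(n, 0, sd * sqrt(1 - phi^2))
  as.numeric(stats::filter(innov, phi, method = "recursive",
                           init = stats::rnorm(1L, 0, sd)))
}

#' Simulate one subject's observed bout sequence
#'
#' Draws a semi-Markov chain over the activity classes with exponential bout
#' durations (mean \code{bout_mean_s} per class), truncated at the session
#' end.  Each bout is independently recoded OUT_OF_VIEW with probability
#' \code{p_out_of_view}: the child keeps moving, the observer just cannot
#' see them, so the signal underneath retains the true class.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @param subject_id Subject identifier.
#' @param start_time Session start (\code{POSIXct} or ISO-8601 string).
#' @return List with \code{log} (a \code{pa_eventlog} of observed codes) and
#'   \code{true_bouts} (data frame of onset/offset seconds and the true
#'   generating class per bout).
#' @export
simulate_bouts <- function(cfg, subject_id,
                           start_time = "2026-01-01T09:00:00.000") {
  if (is.character(start_time)) start_time <- .parse_iso_time(start_time)
  cls <- activity_classes()
  params <- cfg$class_params
  t <- 0
  state <- sample(cls, 1L)
  onset <- numeric(0); offset <- numeric(0); code <- character(0)
  while (t < cfg$session_s) {
    dur <- stats::rexp(1L, 1 / params$bout_mean_s[match(state, cls)])
    dur <- max(dur, 1 / cfg$rate_hz)
    end <- min(t + dur, cfg$session_s)
    onset <- c(onset, t); offset <- c(offset, end); code <- c(code, state)
    t <- end
    w <- cfg$transition[state, ]
    # a zero row means the chain has nowhere to go: stay in the same class
    state <- if (sum(w) == 0) state else sample(cls, 1L, prob = w)
  }
  observed <- code
  oov <- stats::runif(length(code)) < cfg$p_out_of_view
  observed[oov] <- "OUT_OF_VIEW"
  # snap bout boundaries to the sample grid so observation codes and samples
  # agree exactly at the edges
  snap <- function(x) round(x * cfg$rate_hz) / cfg$rate_hz
  onset <- snap(onset); offset <- snap(offset)
  keep <- offset > onset
  onset <- onset[keep]; offset <- offset[keep]
  code <- code[keep]; observed <- observed[keep]
  # human coders mark transitions with some latency: the OBSERVED event
  # boundaries wander around the true ones, so samples near a transition
  # can carry the neighbouring code (the signal itself follows the true
  # bouts).  Sorting keeps the jittered boundaries ordered.
  obs_onset <- onset
  if (cfg$obs_jitter_s > 0 && length(onset) > 1L) {
    interior <- onset[-1L] + stats::rnorm(length(onset) - 1L, 0,
                                          cfg$obs_jitter_s)
    obs_onset <- c(0, snap(sort(pmin(pmax(interior, 0), cfg$session_s))))
  }
  obs_offset <- c(obs_onset[-1L], cfg$session_s)
  keep_o <- obs_offset > obs_onset
  t0 <- as.numeric(start_time)
  log <- eventlog(subject_id,
                  as.POSIXct(t0 + obs_onset[keep_o], tz = "UTC",
                             origin = "1970-01-01"),
                  as.POSIXct(t0 + obs_offset[keep_o], tz = "UTC",
                             origin = "1970-01-01"),
                  observed[keep_o])
  list(log = log,
       true_bouts = data.frame(onset = onset, offset = offset, class = code,
                               stringsAsFactors = FALSE))
}

#' Synthesise an accelerometer stream for a bout sequence
#'
#' Per bout: a gravity baseline of \code{level_g} on the z axis, a
#' class-specific sinusoid for locomotion classes (on z, with a half-amplitude
#' quadrature component on x, small per-bout frequency jitter and random
#' phase), and white noise at the class noise SD on every axis.  Vigour is
#' non-stationary: a lognormal per-bout multiplier and a slowly drifting
#' within-bout envelope (about a 2 s timescale) modulate both the noise and
#' the locomotion amplitude, so a window much shorter than the envelope
#' timescale sees a momentary vigour level rather than the class average.
#' The wrist
#' placement adds \code{wrist_extra_noise} and, during SED/LIGHT_AG bouts,
#' short random-phase bursts of arm movement.  All amplitudes are scaled by
#' the subject's random-effect multiplier.
#'
#' @param true_bouts Data frame from \code{\link{simulate_bouts}} (onset,
#'   offset, class in seconds from session start).
#' @param cfg A \code{\link{sim_config}}.
#' @param subject_id Subject identifier.
#' @param placement \code{"hip"} or \code{"wrist"}.
#' @param subject_amp Per-subject amplitude multiplier.
#' @param start_time Session start.
#' @return A \code{pa_recording}.
#' @export
synthesize_signal <- function(true_bouts, cfg, subject_id,
                              placement = c("hip", "wrist"),
                              subject_amp = 1,
                              start_time = "2026-01-01T09:00:00.000") {
  placement <- match.arg(placement)
  cls <- activity_classes()
  params <- cfg$class_params
  n <- round(cfg$session_s * cfg$rate_hz)
  tt <- (seq_len(n) - 1L) / cfg$rate_hz
  x <- numeric(n); y <- numeric(n); z <- numeric(n)
  extra <- if (placement == "wrist") cfg$wrist_extra_noise else 0
  for (b in seq_len(nrow(true_bouts))) {
    sel <- which(tt >= true_bouts$onset[b] & tt < true_bouts$offset[b])
    if (length(sel) == 0L) next
    k <- match(true_bouts$class[b], cls)
    ns <- length(sel)
    # vigorous activities-and-games are often trunk/leg dominated (climbing,
    # riding, spinning): the wrist sees them at much reduced intensity, so
    # per-window wrist features barely separate MV_AG from LIGHT_AG and the
    # wrist model must lean on temporal context
    lvl <- params$level_g[k]
    cls_noise <- params$noise_g[k]
    if (placement == "wrist" && true_bouts$class[b] == "MV_AG") {
      lvl <- 1 + (lvl - 1) * 0.5
      cls_noise <- cls_noise * 0.6
    }
    # bouts of the same class differ in vigour: lognormal per-bout multiplier
    bout_mult <- exp(stats::rnorm(1L, 0, 0.15))
    # within-bout vigour drifts on a ~2 s timescale: a 1 s window sees a
    # momentary level while a 10 s window averages over the envelope, so
    # short windows estimate class character with much more variance
    nk <- max(2L, ceiling(ns / cfg$rate_hz / 2) + 1L)
    env <- stats::approx(seq(0, by = 2, length.out = nk),
                         exp(stats::rnorm(nk, 0, 0.6)),
                         xout = (seq_len(ns) - 1L) / cfg$rate_hz,
                         rule = 2)$y
    noise_sd <- sqrt(cls_noise^2 + extra^2) * subject_amp * bout_mult
    z[sel] <- lvl + .ar_noise(ns, noise_sd, cfg$rate_hz) * env
    x[sel] <- .ar_noise(ns, noise_sd, cfg$rate_hz) * env
    y[sel] <- .ar_noise(ns, noise_sd, cfg$rate_hz) * env
    if (!is.na(params$freq_hz[k])) {
      f0 <- params$freq_hz[k] + stats::runif(1L, -0.15, 0.15)
      # cadence wanders cycle to cycle (AR drift, ~1 s timescale): a long
      # window still shows the mean cadence, a 1 s window a noisy pitch
      drift <- .ar_noise(ns, 0.2, cfg$rate_hz * 5)
      f_inst <- pmax(f0 * (1 + drift), 0.3)
      phase <- stats::runif(1L, 0, 2 * pi) +
        cumsum(2 * pi * f_inst / cfg$rate_hz)
      amp <- params$amp_g[k] * subject_amp * bout_mult * env
      if (placement == "wrist") {
        # children often walk or run while holding objects: the wrist then
        # stops swinging for a few seconds while the trunk keeps its rhythm
        n_hold <- stats::rpois(1L, 0.2 * ns / cfg$rate_hz)
        for (j in seq_len(n_hold)) {
          at <- sample(ns, 1L)
          hl <- min(ns - at + 1L,
                    max(1L, round(stats::runif(1L, 2, 8) * cfg$rate_hz)))
          amp[at:(at + hl - 1L)] <- amp[at:(at + hl - 1L)] * 0.15
        }
      }
      z[sel] <- z[sel] + amp * sin(phase)
      x[sel] <- x[sel] + 0.5 * amp * cos(phase)
    }
    if (placement == "wrist" &&
        true_bouts$class[b] %in% c("SED", "LIGHT_AG")) {
      # fidgeting: short bursts of arm movement the hip does not see
      n_burst <- stats::rpois(1L, cfg$wrist_burst_rate * ns / cfg$rate_hz)
      for (j in seq_len(n_burst)) {
        at <- sample(ns, 1L)
        len <- min(ns - at + 1L, max(1L, round(stats::runif(1L, 1, 4) *
                                                 cfg$rate_hz)))
        idx <- sel[at:(at + len - 1L)]
        bf <- stats::runif(1L, 1.0, 3.5)
        z[idx] <- z[idx] + stats::runif(1L, 0.3, 0.8) * subject_amp *
          sin(2 * pi * bf * tt[idx] + stats::runif(1L, 0, 2 * pi))
      }
    }
  }
  recording(subject_id, placement, cfg$rate_hz, start_time, cbind(x, y, z))
}

#' Simulate a cohort of free-play sessions
#'
#' Generates independent subjects, each with a hip recording, a wrist
#' recording on the same clock, and a ground-truth observation log.  Every
#' subject draws from its own seed derived from the master seed, so the
#' cohort is reproducible and subjects are independent.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @return List of sessions (\code{hip}, \code{wrist}, \code{log},
#'   \code{true_bouts}, \code{subject_amp}); names are the subject ids.
#' @export
make_cohort <- function(cfg) {
  sessions <- vector("list", cfg$n_subjects)
  ids <- sprintf("S%02d", seq_len(cfg$n_subjects))
  for (i in seq_len(cfg$n_subjects)) {
    set.seed(.subject_seed(cfg, i))
    amp <- exp(stats::rnorm(1L, 0, cfg$subject_sd))
    bouts <- simulate_bouts(cfg, ids[i])
    hip <- synthesize_signal(bouts$true_bouts, cfg, ids[i], "hip", amp)
    wrist <- synthesize_signal(bouts$true_bouts, cfg, ids[i], "wrist", amp)
    sessions[[i]] <- list(hip = hip, wrist = wrist, log = bouts$log,
                          true_bouts = bouts$true_bouts, subject_amp = amp)
  }
  names(sessions) <- ids
  sessions
}

#' Write a simulated cohort to CSV files
#'
#' One \code{<id>_hip.csv} and \code{<id>_wrist.csv} recording plus one
#' \code{<id>_events.csv} event log per subject, in the package interchange
#' formats.
#'
#' @param sessions Cohort from \code{\link{make_cohort}}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(sessions, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in sessions) {
    id <- s$log$subject_id
    write_recording(s$hip, file.path(dir, paste0(id, "_hip.csv")))
    write_recording(s$wrist, file.path(dir, paste0(id, "_wrist.csv")))
    write_eventlog(s$log, file.path(dir, paste0(id, "_events.csv")))
  }
  invisible(dir)
}
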