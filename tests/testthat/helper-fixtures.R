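# Shared fixture builders.  Everything is generated in code; no data files.

T0 <- "2026-01-01T09:00:00.000"
t0s <- function() as.numeric(paplay:::.parse_iso_time(T0))

# recording whose samples are given directly (matrix or 3 vectors)
mk_rec <- function(samples, rate = 10, subject = "S01", placement = "hip",
                   start = T0) {
  recording(subject, placement, rate, start, samples)
}

# event log from (offset_start_s, offset_end_s, code) triples
mk_log <- function(spans, subject = "S01", start = T0) {
  t0 <- t0s()
  eventlog(subject,
           as.POSIXct(t0 + vapply(spans, `[[`, numeric(1), 1L),
                      tz = "UTC", origin = "1970-01-01"),
           as.POSIXct(t0 + vapply(spans, `[[`, numeric(1), 2L),
                      tz = "UTC", origin = "1970-01-01"),
           vapply(spans, `[[`, character(1), 3L))
}

# constant-ish recording covering n_s seconds at `rate`
mk_flat_rec <- function(n_s, rate = 10, value = 1, ...) {
  n <- round(n_s * rate)
  mk_rec(cbind(x = rep(0, n), y = rep(0, n), z = rep(value, n)),
         rate = rate, ...)
}

# a random gap-free event log covering [0, total_s) with bout lengths
# drawn from `bout_range` seconds, codes cycling over the classes randomly
random_log <- function(total_s, bout_range = c(2, 12), rate = 10,
                       subject = "S01") {
  t <- 0
  spans <- list()
  while (t < total_s) {
    len <- round(stats::runif(1, bout_range[1], bout_range[2]) * rate) / rate
    end <- min(t + max(len, 1 / rate), total_s)
    spans[[length(spans) + 1L]] <-
      list(t, end, sample(activity_classes(), 1))
    t <- end
  }
  mk_log(spans, subject = subject)
}

# tiny feature table with two perfectly separable classes (disjoint vm_mean)
separable_table <- function(n_per_class = 100, seed = 42,
                            classes = c("SED", "RUN"),
                            subjects = c("A", "B")) {
  set.seed(seed)
  rows <- lapply(seq_along(classes), function(k) {
    base <- 10 * k    # disjoint ranges
    data.frame(subject_id = rep(subjects, length.out = n_per_class),
               placement = "hip",
               window_index = seq_len(n_per_class) - 1L,
               label = classes[k], mixed = FALSE,
               vm_mean = base + stats::runif(n_per_class),
               vm_sd = stats::runif(n_per_class),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
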