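# Independent brute-force oracles, written from the feature definitions with
# direct loops and explicit formulas.  They deliberately share no code with
# the package implementation.

oracle_mean <- function(v) sum(v) / length(v)

oracle_popsd <- function(v) {
  m <- oracle_mean(v)
  acc <- 0
  for (xi in v) acc <- acc + (xi - m)^2
  sqrt(acc / length(v))
}

# linear-interpolation percentile on sorted order statistics
oracle_pctl <- function(v, p) {
  s <- sort(v)
  n <- length(s)
  h <- (n - 1) * p
  lo <- floor(h)
  if (lo + 2L > n) return(s[n])
  s[lo + 1L] + (h - lo) * (s[lo + 2L] - s[lo + 1L])
}

oracle_median_crossings <- function(v) {
  m <- oracle_pctl(v, 0.5)
  k <- 0L
  for (i in seq_len(length(v) - 1L)) {
    if ((v[i] - m) * (v[i + 1L] - m) < 0) k <- k + 1L
  }
  k
}

oracle_cor <- function(a, b) {
  ma <- oracle_mean(a); mb <- oracle_mean(b)
  sa2 <- sum((a - ma)^2); sb2 <- sum((b - mb)^2)
  if (sa2 == 0 || sb2 == 0) return(0)
  sum((a - ma) * (b - mb)) / sqrt(sa2 * sb2)
}

# direct DFT restricted to the 0.25-5 Hz band of the zero-padded grid
oracle_domfreq <- function(vm, rate) {
  n <- length(vm)
  nfft <- max(1024, 2^ceiling(log2(n)))
  xd <- vm - oracle_mean(vm)
  ks <- 0:(nfft %/% 2)
  freqs <- ks * rate / nfft
  band <- which(freqs >= 0.25 & freqs <= 5.0)
  best_mag <- -1; best_f <- NA_real_
  for (j in band) {
    k <- ks[j]
    ang <- -2 * pi * k * (0:(n - 1)) / nfft
    mag <- sqrt(sum(xd * cos(ang))^2 + sum(xd * sin(ang))^2)
    if (mag > best_mag + 1e-12) { best_mag <- mag; best_f <- freqs[j] }
  }
  if (best_mag <= .Machine$double.eps * nfft) {
    return(c(dom_freq_hz = 0.25, dom_freq_mag = 0))
  }
  c(dom_freq_hz = best_f, dom_freq_mag = best_mag)
}

oracle_base_features <- function(samples, rate) {
  vm <- numeric(nrow(samples))
  for (i in seq_len(nrow(samples))) {
    vm[i] <- sqrt(samples[i, 1]^2 + samples[i, 2]^2 + samples[i, 3]^2)
  }
  m <- oracle_mean(vm)
  s <- oracle_popsd(vm)
  dom <- oracle_domfreq(vm, rate)
  c(vm_mean = m, vm_sd = s, vm_min = min(vm), vm_max = max(vm),
    vm_iqr = oracle_pctl(vm, 0.75) - oracle_pctl(vm, 0.25),
    vm_p10 = oracle_pctl(vm, 0.10), vm_p25 = oracle_pctl(vm, 0.25),
    vm_p50 = oracle_pctl(vm, 0.50), vm_p75 = oracle_pctl(vm, 0.75),
    vm_p95 = oracle_pctl(vm, 0.95),
    vm_cv = if (m == 0) 0 else s / m,
    vm_sum = sum(vm), vm_power = sum(vm^2) / length(vm),
    vm_p2p = max(vm) - min(vm),
    vm_median_crossings = oracle_median_crossings(vm),
    corr_xy = oracle_cor(samples[, 1], samples[, 2]),
    corr_xz = oracle_cor(samples[, 1], samples[, 3]),
    corr_yz = oracle_cor(samples[, 2], samples[, 3]),
    dom)
}

# temporal features by direct index clamping on per-window summaries
oracle_temporal <- function(win_mean, win_sd) {
  n <- length(win_mean)
  cl <- function(i) min(max(i, 1L), n)
  out <- matrix(NA_real_, n, 5,
                dimnames = list(NULL, c("sd_lag1", "sd_lag2", "sd_lead1",
                                        "sd_lead2", "sd_5win")))
  for (i in seq_len(n)) {
    five <- c(win_mean[cl(i - 2L)], win_mean[cl(i - 1L)], win_mean[i],
              win_mean[cl(i + 1L)], win_mean[cl(i + 2L)])
    out[i, ] <- c(win_sd[cl(i - 1L)], win_sd[cl(i - 2L)],
                  win_sd[cl(i + 1L)], win_sd[cl(i + 2L)],
                  oracle_popsd(five))
  }
  out
}

# hand computation of per-class metrics from a count matrix
oracle_f_scores <- function(cm) {
  k <- nrow(cm)
  prec <- numeric(k); rec <- numeric(k); f <- numeric(k)
  for (c in seq_len(k)) {
    tp <- cm[c, c]
    rs <- sum(cm[c, ]); cs <- sum(cm[, c])
    prec[c] <- if (rs > 0) tp / rs else 0
    rec[c] <- if (cs > 0) tp / cs else 0
    f[c] <- if (prec[c] + rec[c] > 0) {
      2 * prec[c] * rec[c] / (prec[c] + rec[c])
    } else 0
  }
  support <- colSums(cm)
  keep <- support > 0
  list(precision = prec, recall = rec, f = f,
       weighted_f = sum(f[keep] * support[keep]) / sum(support[keep]))
}

oracle_kappa <- function(a, b) {
  codes <- unique(c(a, b))
  n <- length(a)
  po <- sum(a == b) / n
  pe <- 0
  for (cd in codes) pe <- pe + (sum(a == cd) / n) * (sum(b == cd) / n)
  (po - pe) / (1 - pe)
}
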