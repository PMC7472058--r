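test_that("vector magnitude is the per-sample Euclidean norm", {
  expect_equal(vector_magnitude(matrix(c(3, 4, 0), 1)), 5)
  expect_equal(vector_magnitude(matrix(c(0, 0, 1), 1)), 1)
  expect_equal(vector_magnitude(matrix(c(0, 0, 0), 1)), 0)
  m <- rbind(c(1, 2, 2), c(2, 3, 6))
  expect_equal(vector_magnitude(m), c(3, 7))
})

test_that("constant windows give degenerate features and conventions hold", {
  sam <- cbind(x = rep(0, 40), y = rep(0, 40), z = rep(1, 40))
  f <- base_features(sam, 10)
  expect_equal(unname(f["vm_mean"]), 1)
  expect_equal(unname(f["vm_sd"]), 0)
  expect_equal(unname(f["vm_iqr"]), 0)
  expect_equal(unname(f["vm_p2p"]), 0)
  expect_equal(unname(f["vm_median_crossings"]), 0)
  expect_equal(unname(f["vm_cv"]), 0)
  expect_equal(unname(f["corr_xy"]), 0)   # zero-variance axis convention
  expect_equal(unname(f["dom_freq_mag"]), 0)
  expect_equal(unname(f["dom_freq_hz"]), 0.25)  # low-frequency tie-break
})

test_that("dominant frequency finds pure tones within resolution", {
  rate <- 100
  tt <- (0:999) / rate
  for (f0 in c(2, 3)) {
    vm <- 1.2 + sin(2 * pi * f0 * tt)
    d <- dominant_frequency(vm, rate)
    expect_lt(abs(d["dom_freq_hz"] - f0), rate / 1024 + 1e-9)
  }
  # band contract on noise
  set.seed(1)
  for (i in 1:20) {
    d <- dominant_frequency(rnorm(100), rate)
    expect_gte(unname(d["dom_freq_hz"]), 0.25)
    expect_lte(unname(d["dom_freq_hz"]), 5.0)
  }
  expect_warning(dominant_frequency(rnorm(20), 5), "below 10 Hz")
})

test_that("base features match the brute-force oracle on random windows", {
  set.seed(99)
  for (i in 1:50) {
    n <- sample(c(10, 50, 100, 150), 1)
    sam <- cbind(x = rnorm(n, 0, 0.5), y = rnorm(n, 0, 0.5),
                 z = 1 + rnorm(n, 0, 0.5))
    rate <- sample(c(10, 50, 100), 1)
    got <- base_features(sam, rate)
    want <- oracle_base_features(sam, rate)
    expect_equal(got[base_feature_names()], want[base_feature_names()],
                 tolerance = 1e-9)
  }
})

test_that("percentile and amplitude identities hold on arbitrary input", {
  set.seed(5)
  for (i in 1:25) {
    sam <- matrix(rnorm(150, 0, 2), ncol = 3)
    f <- base_features(sam, 50)
    expect_true(f["vm_min"] <= f["vm_p10"] && f["vm_p10"] <= f["vm_p25"] &&
                  f["vm_p25"] <= f["vm_p50"] && f["vm_p50"] <= f["vm_p75"] &&
                  f["vm_p75"] <= f["vm_p95"] && f["vm_p95"] <= f["vm_max"])
    expect_equal(unname(f["vm_iqr"]), unname(f["vm_p75"] - f["vm_p25"]))
    expect_equal(unname(f["vm_p2p"]), unname(f["vm_max"] - f["vm_min"]))
    expect_true(all(abs(f[c("corr_xy", "corr_xz", "corr_yz")]) <= 1 + 1e-12))
  }
})

test_that("features scale as expected under sample scaling", {
  set.seed(8)
  sam <- cbind(rnorm(100, 0, 0.3), rnorm(100, 0, 0.3), 1 + rnorm(100, 0, 0.3))
  c0 <- 3.7
  f1 <- base_features(sam, 100)
  f2 <- base_features(sam * c0, 100)
  for (nm in c("vm_mean", "vm_sd", "vm_sum", "vm_p2p")) {
    expect_equal(unname(f2[nm]), unname(c0 * f1[nm]), tolerance = 1e-9)
  }
  expect_equal(unname(f2["vm_power"]), unname(c0^2 * f1["vm_power"]),
               tolerance = 1e-9)
  for (nm in c("vm_cv", "vm_median_crossings", "corr_xy", "corr_xz",
               "corr_yz", "dom_freq_hz")) {
    expect_equal(unname(f2[nm]), unname(f1[nm]), tolerance = 1e-9)
  }
})

test_that("temporal features use replication padding and the n = 5 formula", {
  # constant VM everywhere -> all five features 0
  tf <- temporal_features(rep(2, 6), rep(0, 6))
  expect_true(all(tf == 0))

  # interior window of means (1..5): sd_5win = population SD = sqrt(2)
  tf <- temporal_features(1:5, rep(0.3, 5))
  expect_equal(unname(tf[3, "sd_5win"]), sqrt(2), tolerance = 1e-12)

  # first window replicates itself for lag features
  sds <- c(0.7, 0.2, 0.4, 0.9, 0.1)
  tf <- temporal_features(1:5, sds)
  expect_equal(unname(tf[1, "sd_lag1"]), 0.7)
  expect_equal(unname(tf[1, "sd_lag2"]), 0.7)
  expect_equal(unname(tf[5, "sd_lead1"]), 0.1)
  expect_equal(unname(tf[2, "sd_lag1"]), 0.7)
  expect_equal(unname(tf[2, "sd_lag2"]), 0.7)

  # oracle equivalence on random sequences
  set.seed(31)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    wm <- runif(n); ws <- runif(n)
    expect_equal(temporal_features(wm, ws), oracle_temporal(wm, ws),
                 tolerance = 1e-12)
  }
})

test_that("time reversal swaps lag and lead features", {
  set.seed(12)
  wm <- runif(9); ws <- runif(9)
  fwd <- temporal_features(wm, ws)
  bwd <- temporal_features(rev(wm), rev(ws))
  rbwd <- bwd[9:1, ]
  expect_equal(unname(fwd[, "sd_lag1"]), unname(rbwd[, "sd_lead1"]))
  expect_equal(unname(fwd[, "sd_lag2"]), unname(rbwd[, "sd_lead2"]))
  expect_equal(unname(fwd[, "sd_lead1"]), unname(rbwd[, "sd_lag1"]))
  expect_equal(unname(fwd[, "sd_5win"]), unname(rbwd[, "sd_5win"]))
})

test_that("pooled five-window variant equals the SD of concatenated samples", {
  set.seed(44)
  wins <- replicate(7, rnorm(20, 1, 0.4), simplify = FALSE)
  wm <- vapply(wins, mean, numeric(1))
  ws <- vapply(wins, oracle_popsd, numeric(1))
  msq <- vapply(wins, function(v) mean(v^2), numeric(1))
  tf <- temporal_features(wm, ws, msq, five_window = "pooled")
  pooled <- unlist(wins[2:6])
  expect_equal(unname(tf[4, "sd_5win"]), oracle_popsd(pooled),
               tolerance = 1e-12)
})

test_that("feature tables have the documented shape", {
  set.seed(3)
  cfg <- sim_config(n_subjects = 2, session_s = 60, rate_hz = 20,
                    p_out_of_view = 0, seed = 5)
  co <- make_cohort(cfg)
  base <- build_feature_table(co, 10, "hip", include_temporal = FALSE)
  expect_length(feature_columns(base), 20L)
  ll <- build_feature_table(co, 10, "hip", include_temporal = TRUE)
  expect_length(feature_columns(ll), 25L)
  both <- build_feature_table(co, 10, "hip_wrist", include_temporal = TRUE)
  expect_length(feature_columns(both), 50L)
  expect_true(all(grepl("^(hip|wrist)_", feature_columns(both))))
  expect_true(all(ll$label %in% activity_classes()))

  # no exclusions, 60 s at 10 s windows -> 6 windows per subject
  one <- mk_flat_rec(60, rate = 10)
  lab_log <- mk_log(list(list(0, 60, "SED")))
  sess <- list(list(hip = one, log = lab_log))
  tab <- build_feature_table(sess, 10, "hip", include_temporal = FALSE)
  expect_equal(nrow(tab), 6L)
})
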