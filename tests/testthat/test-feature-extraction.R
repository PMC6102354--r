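test_that("R-peak detection recovers clean synthetic beats", {
  set.seed(30)
  x <- synth_ecg(120, 512, mean_hr = 60, noise = 0.02)
  xf <- filter_ecg(as.numeric(x), 512)
  b <- detect_r_peaks(xf, 512)
  expect_equal(length(b), length(attr(x, "beat_times")), tolerance = 0)
  expect_true(all(diff(b) >= 0.25))              # refractory period
  expect_length(detect_r_peaks(rep(0, 5120), 512), 0)
})

test_that("recovered mean heart rate tracks the generator across seeds", {
  errs <- vapply(1:8, function(s) {
    set.seed(s)
    hr <- runif(1, 55, 95)
    x <- synth_ecg(90, 512, hr, lf_amp = 0.01, hf_amp = 0.02,
                   ibi_noise = 0.01, noise = 0.02)
    b <- detect_r_peaks(filter_ecg(as.numeric(x), 512), 512)
    abs(60 / mean(diff(b)) - hr)
  }, numeric(1))
  expect_lt(max(errs), 1)
})

test_that("ECG features match hand values for constant inter-beat intervals", {
  beats <- seq(0.5, 119.5, by = 1)
  x <- rep(0, 120 * 256)
  f <- ecg_features(x, beats, 256)
  expect_equal(unname(f["hr_mean"]), 60)
  expect_equal(unname(f["ibi_std"]), 0)
})

test_that("LF/HF ratio separates slow from fast IBI modulation", {
  set.seed(31)
  x <- synth_ecg(240, 512, 60, lf_amp = 0.03, hf_amp = 0, ibi_noise = 0.002)
  xf <- filter_ecg(as.numeric(x), 512)
  f <- ecg_features(xf, detect_r_peaks(xf, 512), 512)
  expect_gt(unname(f["lf_hf_ratio"]), 5)
  x <- synth_ecg(240, 512, 60, lf_amp = 0, hf_amp = 0.03, ibi_noise = 0.002,
                 hf_freq = 0.30)
  xf <- filter_ecg(as.numeric(x), 512)
  f <- ecg_features(xf, detect_r_peaks(xf, 512), 512)
  expect_lt(unname(f["lf_hf_ratio"]), 0.2)
})

test_that("missing-data paths flag ECG features as NA", {
  f <- ecg_features(rep(0, 1024), numeric(0), 256)
  expect_true(is.na(f["hr_mean"]))
  expect_true(is.na(f["lf_hf_ratio"]))
})

test_that("respiration features recover rate and period variability", {
  r <- synth_resp(240, 128, 15)
  f <- respiration_features(filter_lowband(r, 128), 128)
  expect_equal(unname(f["rr_mean"]), 15, tolerance = 0.3 / 15)
  expect_lt(unname(f["rr_rmssd"]), 0.05)
  # alternating 3 s / 5 s breaths: RMSSD of successive differences = 2 s
  cyc <- function(p, rate) sin(2 * pi * seq(0, p * rate - 1) / (p * rate))
  x <- unlist(rep(list(cyc(3, 128), cyc(5, 128)), 20))
  f2 <- respiration_features(x, 128)
  expect_equal(unname(f2["rr_rmssd"]), 2, tolerance = 0.03)
})

test_that("skin-temperature features follow mean and ramp", {
  x <- rep(33, 120 * 64)
  f <- st_features(x, 64)
  expect_equal(unname(f), c(33, 0))
  t <- seq(0, 120, length.out = 120 * 64)
  up <- st_features(33 + 0.5 * t / 120, 64)
  expect_equal(unname(up["st_delta"]), 0.5, tolerance = 0.02)
  dn <- st_features(33 - 0.5 * t / 120, 64)
  expect_equal(unname(dn["st_delta"]), -unname(up["st_delta"]),
               tolerance = 1e-9)
  expect_error(st_features(rep(33, 10), 64), "2 s")
})

test_that("tonic/phasic decomposition reconstructs exactly and isolates pulses", {
  set.seed(32)
  g <- synth_gsr(120, 64, tonic_level = 2, tonic_slope = 0.003,
                 scr_times = c(30, 70), scr_amps = c(0.5, 0.4), noise = 0.002)
  d <- gsr_decompose(g, 64)
  expect_equal(max(abs(g - (d$tonic + d$phasic))), 0)
  expect_gt(max(d$phasic[(25 * 64):(40 * 64)]) -
              min(d$phasic[(25 * 64):(30 * 64)]), 0.9 * 0.5)
  # pure slope: phasic stays near zero
  g2 <- synth_gsr(120, 64, 2, 0.005)
  d2 <- gsr_decompose(g2, 64)
  expect_lt(max(abs(d2$phasic)), 0.02)
})

test_that("SCR scoring recovers injected responses", {
  set.seed(33)
  mk <- function(times, amps) {
    g <- synth_gsr(150, 64, 2, 0, scr_times = times, scr_amps = amps,
                   noise = 0.002)
    scr_score(gsr_decompose(filter_lowband(g, 64), 64)$phasic, 64)
  }
  f <- mk(c(15, 45, 75, 105, 135), rep(0.5, 5))
  expect_equal(unname(f["scr_count"]), 5)
  expect_equal(unname(f["scr_amp_mean"]), 0.5, tolerance = 0.1)
  expect_lt(unname(f["scr_amp_std"]), 0.03)
  f2 <- mk(c(40, 100), c(0.2, 0.4))
  expect_equal(unname(f2["scr_count"]), 2)
  expect_equal(unname(f2["scr_amp_mean"]), 0.3, tolerance = 0.05)
  f0 <- scr_score(rep(0, 64 * 60), 64)
  expect_equal(unname(f0["scr_count"]), 0)
  expect_true(is.na(f0["scr_amp_mean"]))
  expect_error(scr_score(rnorm(100), 64, min_amp = 0), "positive")
})

test_that("rate-dependent features are stable under resampling", {
  set.seed(34)
  x512 <- synth_ecg(90, 512, 72, ibi_noise = 0.005, noise = 0.01)
  x256 <- as.numeric(x512)[seq(1, length(x512), by = 2)]
  f1 <- ecg_features(filter_ecg(as.numeric(x512), 512),
                     detect_r_peaks(filter_ecg(as.numeric(x512), 512), 512), 512)
  f2 <- ecg_features(filter_ecg(x256, 256),
                     detect_r_peaks(filter_ecg(x256, 256), 256), 256)
  expect_equal(unname(f1["hr_mean"]), unname(f2["hr_mean"]),
               tolerance = 0.01)
  r <- synth_resp(240, 128, 14)
  r64 <- r[seq(1, length(r), by = 2)]
  rf1 <- respiration_features(filter_lowband(r, 128), 128)
  rf2 <- respiration_features(filter_lowband(r64, 64), 64)
  expect_equal(unname(rf1["rr_mean"]), unname(rf2["rr_mean"]),
               tolerance = 0.01)
})

test_that("kinematics features compute the documented 24 statistics", {
  n <- 600
  kin <- matrix(1, n, 8, dimnames = list(NULL, c(
    "throttle", "lane_number", "lat_pos", "road_offset",
    "long_vel", "vert_vel", "slip_front", "slip_rear")))
  f <- kinematics_features(kin)
  expect_length(f, 24)
  expect_true(all(f[grepl("_std$|_fluct$", names(f))] == 0))
  kin[, "lane_number"] <- rep(c(0, 1), n / 2)
  f2 <- kinematics_features(kin)
  expect_equal(unname(f2["lane_number_fluct"]), 1)
  expect_error(kinematics_features(kin[, -1]), "throttle")
})

test_that("characteristics encoding is 20-long and session-constant", {
  st <- tiny_study(n_participants = 3, seed = 35)
  v1 <- encode_characteristics(st$questionnaires, 2, 1)
  expect_length(v1, 20)
  v2 <- encode_characteristics(st$questionnaires, 2, 1)
  expect_identical(v1, v2)
  expect_error(encode_characteristics(st$questionnaires, 99, 1),
               "participant")
  # drowsy sessions carry shifted negative affect into the feature vector
  ses <- st$questionnaires$sessions
  dsess <- ses$session[ses$participant == 1 & ses$drowsy == 1][1]
  asess <- ses$session[ses$participant == 1 & ses$drowsy == 0][1]
  vd <- encode_characteristics(st$questionnaires, 1, dsess)
  va <- encode_characteristics(st$questionnaires, 1, asess)
  expect_false(vd["staq_negative_affect"] == va["staq_negative_affect"])
})

test_that("assembled feature table has the 61-column contract", {
  feats <- fixture("tiny_feats", function() {
    extract_features(tiny_study(seed = 3))
  })
  fs <- feature_sets()
  expect_length(fs$physio, 17)
  expect_length(fs$kinematics, 24)
  expect_length(fs$characteristics, 20)
  expect_length(unlist(fs), 61)
  expect_true(all(unlist(fs) %in% names(feats)))
  expect_equal(sum(feats$role == "scenario"), 2 * 4 * 8)
  expect_equal(sum(feats$role == "baseline"), 2 * 4)
  # characteristics identical across the 8 scenarios of a session
  one <- feats[feats$role == "scenario" & feats$participant == 1 &
                 feats$session == 1, fs$characteristics]
  expect_true(all(vapply(one, function(v) length(unique(v)) == 1L,
                         logical(1))))
})
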