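test_that("default factorial design enumerates the full study", {
  sch <- session_schedule(study_design())
  expect_equal(sum(sch$role == "scenario"), 672)
  expect_equal(sum(sch$role == "baseline"), 84)
  # every session: one baseline then 8 scenarios covering all triples once
  by_sess <- split(sch, list(sch$participant, sch$session))
  for (s in by_sess[1:10]) {
    expect_equal(s$role[order(s$segment)],
                 c("baseline", rep("scenario", 8)))
    triples <- s[s$role == "scenario", c("town", "snowy", "phone")]
    expect_equal(nrow(unique(triples)), 8)
  }
  # drowsy flag constant within session, exactly half the sessions drowsy
  agg <- unique(sch[, c("participant", "session", "drowsy")])
  expect_equal(nrow(agg), 84)
  expect_true(all(tapply(agg$drowsy, agg$participant, sum) == 2))
})

test_that("invalid designs are rejected with the offending field named", {
  expect_error(study_design(scenario_duration = -1), "scenario_duration")
  expect_error(study_design(physio_rate = 0), "physio_rate")
  expect_error(study_design(n_sessions = 3), "n_sessions")
  expect_error(effect_config(scr_rate = 0), "scr_rate")
  expect_error(effect_config(snow_friction_factor = 1.5),
               "snow_friction_factor")
})

test_that("simulation is deterministic given the seed", {
  s1 <- tiny_study(seed = 7)
  s2 <- tiny_study(seed = 7)
  expect_identical(s1$schedule, s2$schedule)
  expect_identical(s1$questionnaires, s2$questionnaires)
  r1 <- scenario_recording(s1, 1, 1, 1)
  r2 <- scenario_recording(s2, 1, 1, 1)
  expect_identical(r1$physio, r2$physio)
  expect_identical(r1$kinematics, r2$kinematics)
  s3 <- tiny_study(seed = 8)
  expect_false(identical(s3$schedule$seg_seed, s1$schedule$seg_seed))
})

test_that("ECG synthesis places beats at the requested rate", {
  set.seed(1)
  x <- synth_ecg(120, 256, mean_hr = 60)
  expect_equal(length(attr(x, "beat_times")), 120, tolerance = 0,
               ignore_attr = TRUE)
  expect_error(synth_ecg(1, 256, mean_hr = 40), "2 beats")
  expect_error(synth_ecg(60, 256, mean_hr = 250), "30, 200")
})

test_that("LF-only IBI modulation yields LF-dominant spectrum (periodogram oracle)", {
  set.seed(2)
  x <- synth_ecg(240, 256, 60, lf_amp = 0.03, hf_amp = 0, ibi_noise = 0.001)
  bt <- attr(x, "beat_times")
  ibi <- diff(bt)
  lf <- oracle_band_power(bt[-1], ibi, 0.04, 0.15)
  hf <- oracle_band_power(bt[-1], ibi, 0.15, 0.40)
  expect_gt(lf / hf, 1)
})

test_that("artifact power raises the mean absolute ECG gradient", {
  set.seed(3)
  x0 <- synth_ecg(120, 256, 60, noise = 0.02, artifact_power = 0)
  set.seed(3)
  x1 <- synth_ecg(120, 256, 60, noise = 0.02, artifact_power = 0.5)
  expect_gt(mean(abs(diff(as.numeric(x1)))), mean(abs(diff(as.numeric(x0)))))
})

test_that("GSR synthesis validates inputs and recovers by construction", {
  expect_error(synth_gsr(60, 64, scr_times = 10, scr_amps = -1),
               "non-negative")
  expect_error(synth_gsr(60, 64, scr_times = 70, scr_amps = 1),
               "duration")
  set.seed(4)
  g <- synth_gsr(60, 64, tonic_level = 2, tonic_slope = 0.01, noise = 0)
  expect_equal(g[1], 2, tolerance = 1e-9)
  expect_gt(mean(g[3777:3840]) - mean(g[1:64]), 0)   # positive drift
})

test_that("dense traffic roughly quadruples lane-number variability", {
  set.seed(5)
  eff <- effect_config()
  s_town <- replicate(60, sd(synth_kinematics(
    240, 60, list(phone = 0, town = 1, snowy = 0), eff)[, "lane_number"]))
  s_light <- replicate(60, sd(synth_kinematics(
    240, 60, list(phone = 0, town = 0, snowy = 0), eff)[, "lane_number"]))
  ratio <- mean(s_town) / mean(s_light)
  expect_gt(ratio, 2.2)
  expect_lt(ratio, 6.5)
})

test_that("slip channels stay in [0, 1] and are near zero in clear weather", {
  set.seed(6)
  k <- synth_kinematics(120, 60, list(phone = 0, town = 0, snowy = 0),
                        effect_config())
  for (ch in c("slip_front", "slip_rear")) {
    expect_true(all(k[, ch] >= 0 & k[, ch] <= 1))
    expect_lt(mean(k[, ch]), 0.05)
  }
  set.seed(6)
  ks <- synth_kinematics(120, 60, list(phone = 0, town = 0, snowy = 1),
                         effect_config())
  expect_gt(mean(ks[, "slip_rear"]), mean(k[, "slip_rear"]))
})

test_that("zero kinematics noise gives constant channels", {
  eff <- effect_config(noise = list(ecg = 0, ibi = 0, resp = 0, gsr = 0,
                                    st = 0, kin = 0))
  k <- synth_kinematics(30, 60, list(phone = 0, town = 1, snowy = 1), eff)
  f <- kinematics_features(k)
  expect_true(all(f[grepl("_fluct$", names(f))] == 0))
  expect_true(all(f[grepl("_std$", names(f))] == 0))
})

test_that("drowsy sessions shift STAQ affect and start hour", {
  st <- tiny_study(n_participants = 8, seed = 11)
  ses <- st$questionnaires$sessions
  expect_gt(mean(ses$staq_negative_affect[ses$drowsy == 1]),
            mean(ses$staq_negative_affect[ses$drowsy == 0]))
  expect_lt(mean(ses$start_hour[ses$drowsy == 1]),
            mean(ses$start_hour[ses$drowsy == 0]))
})

test_that("phone scenarios raise NASA-TLX subscale scores", {
  st <- tiny_study(n_participants = 8, seed = 12)
  tlx <- st$questionnaires$tlx
  for (sub in c("tlx_mental", "tlx_effort", "tlx_overall"))
    expect_gt(mean(tlx[[sub]][tlx$phone == 1]),
              mean(tlx[[sub]][tlx$phone == 0]))
})

test_that("null effect configuration decouples labels from questionnaires", {
  st <- tiny_study(n_participants = 10, seed = 13,
                   effects = effect_config(null = TRUE))
  ses <- st$questionnaires$sessions
  d <- abs(mean(ses$start_hour[ses$drowsy == 1]) -
             mean(ses$start_hour[ses$drowsy == 0]))
  expect_lt(d, 2)    # same distribution; difference is sampling noise
  tlx <- st$questionnaires$tlx
  expect_lt(abs(mean(tlx$tlx_overall[tlx$phone == 1]) -
                  mean(tlx$tlx_overall[tlx$phone == 0])), 5)
})
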