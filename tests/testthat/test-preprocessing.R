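rms <- function(x) sqrt(mean(x^2))

test_that("low-band filter preserves DC and slow components", {
  x <- rep(3.2, 2048)
  expect_equal(filter_lowband(x, 512), x, tolerance = 1e-6)
  t <- seq(0, 4, by = 1 / 512)
  s1 <- sin(2 * pi * 1 * t)
  y <- filter_lowband(s1, 512)
  expect_lt(abs(rms(y) - rms(s1)) / rms(s1), 0.05)
})

test_that("low-band filter attenuates above the pass band (FFT oracle)", {
  t <- seq(0, 4, by = 1 / 512)
  s100 <- sin(2 * pi * 100 * t)
  y <- filter_lowband(s100, 512)
  expect_lt(rms(y), 0.1 * rms(s100))
  expect_error(filter_lowband(rnorm(100), 50), "60 Hz")
})

test_that("ECG filter removes mains interference and drift", {
  t <- seq(0, 4, by = 1 / 512)
  s60 <- sin(2 * pi * 60 * t)
  expect_lt(rms(filter_ecg(s60, 512)), 0.1 * rms(s60))
  drift <- seq(0, 2, length.out = length(t))
  y <- filter_ecg(drift, 512)
  core <- y[513:(length(y) - 512)]          # trim filter edges
  expect_lt(max(abs(core)), 0.05 * 2)
  expect_equal(filter_ecg(rep(0, 2048), 512), rep(0, 2048), tolerance = 1e-9)
  expect_error(filter_ecg(rnorm(100), 100), "notch")
})

test_that("ECG filter preserves the QRS band", {
  t <- seq(0, 4, by = 1 / 512)
  s15 <- sin(2 * pi * 15 * t)
  y <- filter_ecg(s15, 512)
  expect_gt(rms(y), 0.9 * rms(s15))
})

test_that("filtering is zero-phase and near-idempotent", {
  set.seed(20)
  t <- seq(0, 10, by = 1 / 512)
  x <- sin(2 * pi * 0.5 * t) + 0.1 * rnorm(length(t))
  y1 <- filter_lowband(x, 512)
  y2 <- filter_lowband(y1, 512)
  expect_lt(abs(rms(y2) - rms(y1)) / rms(y1), 0.01)
  # zero-phase: peak of a slow sine stays put
  s <- sin(2 * pi * 0.5 * t)
  expect_lt(abs(which.max(filter_lowband(s, 512)) - which.max(s)), 5)
})

test_that("epoching returns one epoch per segment row and conserves samples", {
  st <- tiny_study(seed = 2)
  sig <- session_signals(st, 1, 1)
  recs <- epoch_segments(sig$physio, sig$segments, sig$physio_rate,
                         sig$kinematics)
  expect_length(recs, 9)
  expect_equal(vapply(recs, function(r) r$role, ""),
               c("baseline", rep("scenario", 8)))
  total <- sum(vapply(recs, function(r) nrow(r$physio), integer(1)))
  expect_equal(total, nrow(sig$physio))
  # concatenated epochs reproduce the covered samples exactly
  cat_ecg <- unlist(lapply(recs, function(r) r$physio[, "ecg"]))
  expect_identical(unname(cat_ecg), unname(sig$physio[, "ecg"]))
})

test_that("epoching rejects bad segment tables", {
  phys <- matrix(rnorm(512 * 10), ncol = 1,
                 dimnames = list(NULL, "ecg"))
  seg <- data.frame(segment = 1, role = "scenario", start_s = 0, end_s = 20,
                    phone = 0, drowsy = 0, town = 0, snowy = 0)
  expect_error(epoch_segments(phys, seg, 512), "out of recording range")
  seg2 <- data.frame(segment = 1:2, role = "scenario",
                     start_s = c(0, 3), end_s = c(5, 8),
                     phone = 0, drowsy = 0, town = 0, snowy = 0)
  expect_error(epoch_segments(phys, seg2, 512), "overlapping")
  empty <- seg[0, ]
  expect_equal(epoch_segments(phys, empty, 512), list())
})
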