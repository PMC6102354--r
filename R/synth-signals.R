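# Stationary Ornstein-Uhlenbeck path on a regular grid via the exact AR(1)
# discretisation; sd_stat = 0 gives the constant mean path.
ou_process <- function(n, dt, mu, sd_stat, tau) {
  if (sd_stat <= 0) return(rep(mu, n))
  a <- exp(-dt / tau)
  e <- stats::rnorm(n, 0, sd_stat * sqrt(1 - a^2))
  e[1L] <- stats::rnorm(1, 0, sd_stat)
  mu + as.numeric(stats::filter(e, a, method = "recursive"))
}

# Binary telegraph path: exponential holding times, switching rate per
# second; starts in state 0 (right lane).
telegraph_process <- function(n, rate_hz, switch_rate) {
  dur <- n / rate_hz
  if (switch_rate <= 0) return(rep(0L, n))
  tt <- 0; times <- 0
  repeat {
    tt <- tt + stats::rexp(1, switch_rate)
    if (tt > dur) break
    times <- c(times, tt)
  }
  states <- (seq_along(times) - 1L) %% 2L
  tg <- (seq_len(n) - 1L) / rate_hz
  states[findInterval(tg, times)]
}

#' Synthesize an ECG-like waveform with controlled heart-rate variability
#'
#' Places narrow QRS-like Gaussian pulses at inter-beat intervals
#' \eqn{IBI_k = 60/\mathrm{mean\_hr} + lf\_amp\,\sin(2\pi f_{LF} t_k) +
#' hf\_amp\,\sin(2\pi f_{HF} t_k) + \epsilon}, so that the low- and
#' high-frequency content of the heart-rate-variability spectrum is known
#' exactly.  `artifact_power` injects broadband noise bursts emulating
#' motion artifacts.  This is deliberately schematic plumbing (no PQRST
#' morphology): its purpose is that every downstream extractor can be
#' validated by parameter recovery.
#'
#' @param duration seconds.
#' @param rate sampling rate, Hz.
#' @param mean_hr mean heart rate in beats/min, within \[30, 200\].
#' @param lf_amp,hf_amp amplitudes (s) of the sinusoidal IBI modulation at
#'   `lf_freq` and `hf_freq`.
#' @param artifact_power standard deviation (mV) of broadband artifact
#'   bursts (about 6 bursts/min of ~0.5 s).
#' @param ibi_noise white IBI jitter sd (s).
#' @param noise baseline white noise sd (mV).
#' @param lf_freq,hf_freq modulation frequencies, Hz (defaults 0.10 and
#'   0.25).
#' @return Numeric waveform (mV) with attribute `beat_times` holding the
#'   true beat times in seconds.
#' @export
synth_ecg <- function(duration, rate, mean_hr, lf_amp = 0, hf_amp = 0,
                      artifact_power = 0, ibi_noise = 0, noise = 0,
                      lf_freq = 0.10, hf_freq = 0.25) {
  if (mean_hr < 30 || mean_hr > 200)
    stop("'mean_hr' must lie in [30, 200]", call. = FALSE)
  if (duration < 2 * 60 / mean_hr)
    stop("'duration' is shorter than 2 beats", call. = FALSE)
  n <- round(duration * rate)
  x <- stats::rnorm(n, 0, noise)
  beats <- numeric(0)
  tt <- 0.3
  base_ibi <- 60 / mean_hr
  while (tt < duration) {
    beats <- c(beats, tt)
    ibi <- base_ibi + lf_amp * sin(2 * pi * lf_freq * tt) +
      hf_amp * sin(2 * pi * hf_freq * tt) +
      stats::rnorm(1, 0, ibi_noise)
    tt <- tt + max(0.3, ibi)
  }
  # QRS-like pulse: 8 ms Gaussian, 1 mV
  half <- round(0.032 * rate)
  ku <- (-half:half) / rate
  kernel <- exp(-0.5 * (ku / 0.008)^2)
  for (b in beats) {
    i0 <- round(b * rate) + 1L
    idx <- (i0 - half):(i0 + half)
    keep <- idx >= 1L & idx <= n
    x[idx[keep]] <- x[idx[keep]] + kernel[keep]
  }
  if (artifact_power > 0) {
    n_bursts <- stats::rpois(1, 6 * duration / 60)
    if (n_bursts > 0) {
      starts <- stats::runif(n_bursts, 0, duration)
      for (bs in starts) {
        len <- round(stats::runif(1, 0.3, 0.8) * rate)
        i0 <- min(round(bs * rate) + 1L, n)
        idx <- i0:min(i0 + len, n)
        x[idx] <- x[idx] + stats::rnorm(length(idx), 0, artifact_power)
      }
    }
  }
  attr(x, "beat_times") <- beats
  x
}

#' Synthesize a respiration-like waveform with known breath periods
#'
#' Concatenates one sinusoidal cycle per breath, each breath period drawn
#' as `60/rate_bpm` plus Gaussian jitter, so the extractor's cycle counts
#' and period statistics can be checked against the generating values.
#'
#' @param duration seconds.
#' @param rate sampling rate, Hz.
#' @param rate_bpm mean breathing rate, breaths/min.
#' @param period_jitter sd (s) of the per-breath period.
#' @param amp amplitude (a.u.).
#' @param noise additive white noise sd.
#' @return Numeric waveform with attribute `breath_periods` (s).
#' @export
synth_resp <- function(duration, rate, rate_bpm, period_jitter = 0,
                       amp = 1, noise = 0) {
  if (rate_bpm <= 0) stop("'rate_bpm' must be positive", call. = FALSE)
  n <- round(duration * rate)
  base <- 60 / rate_bpm
  periods <- numeric(0)
  total <- 0
  while (total < duration + base) {
    p <- max(0.5, base + stats::rnorm(1, 0, period_jitter))
    periods <- c(periods, p)
    total <- total + p
  }
  x <- numeric(0)
  for (p in periods) {
    np <- round(p * rate)
    x <- c(x, amp * sin(2 * pi * seq(0, np - 1) / np))
  }
  x <- x[seq_len(n)]
  x + stats::rnorm(n, 0, noise)
}

#' Synthesize a skin-temperature trace
#'
#' @param duration,rate seconds and Hz.
#' @param level baseline temperature, degrees C.
#' @param slope linear drift, degrees C per second.
#' @param noise white noise sd.
#' @return Numeric waveform (degrees C).
#' @export
synth_st <- function(duration, rate, level = 33, slope = 0, noise = 0) {
  n <- round(duration * rate)
  t <- (seq_len(n) - 1) / rate
  level + slope * t + stats::rnorm(n, 0, noise)
}

#' Synthesize a skin-conductance (GSR) waveform
#'
#' A linear tonic trend plus one bi-exponential skin-conductance response
#' (fast ~1 s rise, slow ~4 s decay time constant) of stated amplitude per
#' requested event time, plus white noise.  Mirrors the canonical
#' description of electrodermal activity: conductance rises rapidly and
#' recovers smoothly with sweat-gland activity.
#'
#' @param duration,rate seconds and Hz.
#' @param tonic_level tonic conductance at t = 0, uS.
#' @param tonic_slope tonic drift, uS/s.
#' @param scr_times event onset times (s), each within \[0, duration).
#' @param scr_amps peak amplitudes (uS), non-negative, one per event.
#' @param noise white noise sd (uS).
#' @return Numeric waveform (uS).
#' @export
synth_gsr <- function(duration, rate, tonic_level = 2, tonic_slope = 0,
                      scr_times = numeric(0), scr_amps = numeric(0),
                      noise = 0) {
  if (length(scr_times) != length(scr_amps))
    stop("'scr_times' and 'scr_amps' must have the same length", call. = FALSE)
  if (any(scr_amps < 0))
    stop("'scr_amps' must be non-negative", call. = FALSE)
  if (length(scr_times) && (any(scr_times < 0) || any(scr_times >= duration)))
    stop("'scr_times' must lie within [0, duration)", call. = FALSE)
  n <- round(duration * rate)
  t <- (seq_len(n) - 1) / rate
  x <- tonic_level + tonic_slope * t + stats::rnorm(n, 0, noise)
  if (length(scr_times)) {
    ku <- seq(0, 20, by = 1 / rate)
    kernel <- exp(-ku / 4) - exp(-ku / 0.7)
    kernel <- kernel / max(kernel)
    for (i in seq_along(scr_times)) {
      i0 <- round(scr_times[i] * rate) + 1L
      idx <- i0:min(i0 + length(kernel) - 1L, n)
      x[idx] <- x[idx] + scr_amps[i] * kernel[seq_along(idx)]
    }
  }
  x
}

kinematics_channel_names <- function() {
  c("throttle", "lane_number", "lat_pos", "road_offset",
    "long_vel", "vert_vel", "slip_front", "slip_rear")
}

#' Synthesize the 8 vehicle-kinematics channels for one scenario
#'
#' Throttle, lateral lane position, road offset, longitudinal and vertical
#' velocity are mean-reverting (Ornstein-Uhlenbeck) noise processes; lane
#' number is a binary 0/1 telegraph process whose switching rate scales
#' with the dense-traffic condition (quadratically in
#' `town_lane_std_mult`, which reproduces the target ratio of lane-number
#' standard deviations at the default base rate of 0.0875 switches/min);
#' tire-slip channels sit near zero in clear weather and gain mean and
#' variance in snow, scaled by how far `snow_friction_factor` falls below
#' 1.  All slip values are clipped to \[0, 1\].  With the kinematics noise
#' level set to 0 the generator is deterministic and every channel is
#' constant.
#'
#' @param duration,rate seconds and Hz (default design rate 60 Hz).
#' @param labels list with binary `phone`, `town`, `snowy` entries.
#' @param effects an `hds_effects`.
#' @param lat_offset baseline lateral lane-keeping offset of this scenario
#'   (m), emulating between-scenario driver drift.
#' @param response_scale idiosyncratic scaling of this driver/scenario's
#'   response to snow (slip and throttle elevation); 1 = nominal.
#' @return Numeric matrix `round(duration*rate)` x 8 with the channel names
#'   `throttle`, `lane_number`, `lat_pos`, `road_offset`, `long_vel`,
#'   `vert_vel`, `slip_front`, `slip_rear`.
#' @export
synth_kinematics <- function(duration, rate, labels, effects,
                             lat_offset = 0, response_scale = 1) {
  stopifnot(inherits(effects, "hds_effects"))
  n <- round(duration * rate)
  dt <- 1 / rate
  nk <- effects$noise$kin
  phone <- labels$phone %||% 0L
  town <- labels$town %||% 0L
  snowy <- labels$snowy %||% 0L

  thr_mult <- 1 + (effects$snowy$throttle_sd_mult - 1) * response_scale
  thr_sd <- 0.05 * nk * if (snowy == 1) thr_mult else 1
  throttle <- pmin(pmax(ou_process(n, dt, 0.3, thr_sd, 5), 0), 1)

  base_switch <- 0.0875 / 60                       # per second
  mult <- if (town == 1) effects$town_lane_std_mult^2 else 1
  lane <- if (nk > 0) telegraph_process(n, rate, base_switch * mult)
          else rep(0L, n)

  lat_mu <- lat_offset + phone * effects$phone$lat_pos_mean
  lat_pos <- ou_process(n, dt, lat_mu, 0.15 * nk, 3)
  road_offset <- (lane - 0.5) * 3.7 + lat_pos +
    stats::rnorm(n, 0, 0.02 * nk)
  long_vel <- ou_process(n, dt, 25, 1.5 * nk, 10)
  vert_vel <- ou_process(n, dt, 0, 0.05 * nk, 1)

  snow_scale <- (1 - effects$snow_friction_factor) / 0.4
  slip_chan <- function(frac) {
    base <- abs(ou_process(n, dt, 0, 0.01 * nk, 0.5))
    extra <- if (snowy == 1)
      frac * snow_scale * response_scale * (effects$snowy$slip_mean +
        ou_process(n, dt, 0, effects$snowy$slip_sd * nk, 1))
    else 0
    pmin(pmax(base + extra, 0), 1)
  }
  out <- cbind(throttle = throttle, lane_number = as.numeric(lane),
               lat_pos = lat_pos, road_offset = road_offset,
               long_vel = long_vel, vert_vel = vert_vel,
               slip_front = slip_chan(0.6), slip_rear = slip_chan(1))
  colnames(out) <- kinematics_channel_names()
  out
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[1])) b else a
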