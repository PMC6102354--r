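# Local maxima with a minimum separation (greedy, highest first) and an
# optional absolute height floor.
find_peaks <- function(x, min_dist = 1L, min_height = -Inf) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- which(x[2:(n - 1L)] >= x[1:(n - 2L)] &
                  x[2:(n - 1L)] > x[3:n]) + 1L
  cand <- cand[x[cand] >= min_height]
  if (!length(cand)) return(integer(0))
  cand <- cand[order(x[cand], decreasing = TRUE)]
  keep <- logical(0)
  sel <- integer(0)
  for (i in cand) {
    if (!length(sel) || all(abs(sel - i) >= min_dist)) sel <- c(sel, i)
  }
  sort(sel)
}

#' Detect R peaks in a conditioned ECG signal
#'
#' Derivative-square-moving-average energy detector: the filtered ECG is
#' differentiated and squared, smoothed with a 60 ms moving average, and
#' peaks of the resulting energy envelope above an adaptive threshold
#' (a multiple of the envelope's median, which is robust both to the
#' noise floor and to artifact bursts) are taken as beats.  A 250 ms
#' refractory period is enforced and each detection is refined to the
#' sample of maximal absolute ECG amplitude nearby.
#'
#' @param x ECG signal, already high-pass and notch filtered.
#' @param rate sampling rate, Hz.
#' @return Monotone increasing beat times in seconds (possibly empty).
#' @export
detect_r_peaks <- function(x, rate) {
  n <- length(x)
  if (n < rate) return(numeric(0))
  d <- diff(x)
  sq <- d * d
  w <- max(3L, round(0.06 * rate))
  ma <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 2))
  ma[is.na(ma)] <- 0
  # median-based floor: robust to both the noise floor and artifact bursts
  thr <- 8 * stats::median(ma)
  if (thr <= 0) return(numeric(0))
  refr <- max(1L, round(0.25 * rate))
  pk <- find_peaks(ma, min_dist = refr, min_height = thr)
  if (!length(pk)) return(numeric(0))
  # refine to the local extremum of the raw amplitude
  half <- round(0.05 * rate)
  half <- as.integer(half)
  ref <- vapply(pk, function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    lo + which.max(abs(x[lo:hi])) - 1L
  }, integer(1))
  ref <- sort(unique(ref))
  # refractory on the refined times
  keep <- c(TRUE, diff(ref) >= refr)
  (ref[keep] - 1L) / rate
}

# Power spectrum of the inter-beat-interval series: cubic interpolation of
# the unevenly sampled IBI sequence onto a 4 Hz grid, linear detrend, Hann
# window, periodogram with trapezoid band integration.
ibi_band_power <- function(beat_times, resample_rate = 4) {
  if (length(beat_times) < 5L)
    return(list(lf = NA_real_, hf = NA_real_))
  ibi <- diff(beat_times)
  tm <- beat_times[-1L]
  grid <- seq(min(tm), max(tm), by = 1 / resample_rate)
  if (length(grid) < 16L) return(list(lf = NA_real_, hf = NA_real_))
  y <- stats::spline(tm, ibi, xout = grid)$y
  y <- stats::residuals(stats::lm.fit(cbind(1, grid), y))
  m <- length(y)
  win <- 0.5 * (1 - cos(2 * pi * seq(0, m - 1) / (m - 1)))
  yw <- y * win
  sp <- stats::fft(yw)
  # one-sided PSD in s^2/Hz, window power compensated
  nf <- floor(m / 2) + 1L
  psd <- (Mod(sp[1:nf])^2) / (resample_rate * sum(win^2))
  psd[2:(nf - 1L)] <- 2 * psd[2:(nf - 1L)]
  freq <- (0:(nf - 1L)) * resample_rate / m
  band <- function(lo, hi) {
    idx <- which(freq >= lo & freq <= hi)
    if (length(idx) < 2L) return(0)
    sum(diff(freq[idx]) * (psd[idx][-1] + psd[idx][-length(idx)]) / 2)
  }
  list(lf = band(0.04, 0.15), hf = band(0.15, 0.40))
}

#' Seven ECG features: time-domain heart-rate statistics and the
#' heart-rate-variability band powers
#'
#' Computes the mean heart rate (60 / mean inter-beat interval), the
#' standard deviation of inter-beat intervals, the median and the mean
#' absolute value of the ECG first difference (expressed per second so the
#' values are invariant to resampling; the first and last second of the
#' epoch are excluded so zero-phase filter edges cannot leak in), and the
#' low-frequency (0.04-0.15 Hz) and high-frequency (0.15-0.4 Hz) powers of
#' the inter-beat-interval spectrum plus their ratio.  The IBI series is
#' resampled at 4 Hz by cubic interpolation before the periodogram.
#'
#' @param x conditioned ECG signal.
#' @param beats beat times in seconds, as from [detect_r_peaks()].
#' @param rate sampling rate, Hz.
#' @return Named numeric vector: `hr_mean`, `ibi_std`, `ecg_grad_median`,
#'   `ecg_grad_absmean`, `lf_power`, `hf_power`, `lf_hf_ratio`.  Features
#'   that cannot be computed (fewer than 2 beats, zero HF power) are `NA`.
#' @export
ecg_features <- function(x, beats, rate) {
  out <- c(hr_mean = NA_real_, ibi_std = NA_real_,
           ecg_grad_median = NA_real_, ecg_grad_absmean = NA_real_,
           lf_power = NA_real_, hf_power = NA_real_, lf_hf_ratio = NA_real_)
  n <- length(x)
  trim <- round(rate)
  if (n > 2 * trim + 2) {
    g <- diff(x[(trim + 1L):(n - trim)]) * rate
    out["ecg_grad_median"] <- stats::median(g)
    out["ecg_grad_absmean"] <- mean(abs(g))
  }
  if (length(beats) >= 2L) {
    ibi <- diff(beats)
    out["hr_mean"] <- 60 / mean(ibi)
    out["ibi_std"] <- stats::sd(ibi)
    bp <- ibi_band_power(beats)
    out["lf_power"] <- bp$lf
    out["hf_power"] <- bp$hf
    if (is.finite(bp$hf) && bp$hf > 0)
      out["lf_hf_ratio"] <- bp$lf / bp$hf
  }
  out
}
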