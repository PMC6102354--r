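#' Respiration features: breathing rate and breath-period variability
#'
#' Breath cycles are delimited by upward zero crossings of the smoothed
#' (1 Hz low-pass), mean-centred respiration signal, with a minimum cycle
#' length of 1 s and a peak-prominence floor relative to the signal spread
#' (crossing at the start of each cycle measures the breath period itself,
#' unlike peak-to-peak intervals which mix adjacent periods).  The mean
#' respiration rate is
#' 60 / (mean breath period) in breaths/min; its standard deviation is
#' taken across 1-min windows (each window's rate from the breath periods
#' whose midpoints fall in it); the RMSSD is the root-mean-square of
#' successive breath-period differences, in seconds.
#'
#' @param x respiration signal, low-band filtered.
#' @param rate sampling rate, Hz.
#' @return Named numeric vector `rr_mean`, `rr_std`, `rr_rmssd`; all `NA`
#'   when fewer than 3 breath cycles are detected (`rr_std` additionally
#'   requires at least two 1-min windows).
#' @export
respiration_features <- function(x, rate) {
  out <- c(rr_mean = NA_real_, rr_std = NA_real_, rr_rmssd = NA_real_)
  n <- length(x)
  if (n < 4 * rate) return(out)
  bf <- signal::butter(2, min(0.9, 1 / (rate / 2)), "low")
  xs <- filtfilt_padded(bf, x - mean(x), round(4 * rate))
  s <- stats::sd(xs)
  if (!is.finite(s) || s < 1e-8) return(out)
  up <- which(xs[-length(xs)] <= 0 & xs[-1] > 0)
  if (length(up) >= 2L) {
    # enforce minimum cycle length and a real peak within each cycle
    keep <- up[1]
    for (i in up[-1])
      if ((i - keep[length(keep)]) / rate >= 1 &&
          max(xs[keep[length(keep)]:i]) >= 0.3 * s)
        keep <- c(keep, i)
    up <- keep
  }
  if (length(up) < 4L) return(out)  # >= 3 complete cycles
  # refine each crossing on the raw centred signal (the smoother shifts
  # crossings slightly when adjacent breaths have different lengths)
  xc <- x - mean(x)
  w <- max(1L, as.integer(round(0.3 * rate)))
  bt <- vapply(up, function(i) {
    lo <- max(1L, i - w); hi <- min(n - 1L, i + w)
    seg <- lo:hi
    cross <- seg[xc[seg] <= 0 & xc[seg + 1L] > 0]
    j <- if (length(cross)) cross[which.min(abs(cross - i))] else i
    sig <- if (length(cross)) xc else xs
    (j - 1 + (-sig[j]) / (sig[j + 1L] - sig[j])) / rate
  }, numeric(1))
  periods <- diff(bt)
  out["rr_mean"] <- 60 / mean(periods)
  if (length(periods) >= 2L)
    out["rr_rmssd"] <- sqrt(mean(diff(periods)^2))
  mid <- bt[-length(bt)] + periods / 2
  win <- floor(mid / 60)
  if (length(unique(win)) >= 2L) {
    wr <- tapply(periods, win, function(p) 60 / mean(p))
    out["rr_std"] <- stats::sd(wr)
  }
  out
}

#' Skin-temperature features
#'
#' Mean temperature over the epoch and the drift, defined as the mean of
#' the last second minus the mean of the first second.
#'
#' @param x skin-temperature signal (degrees C), low-band filtered.
#' @param rate sampling rate, Hz.
#' @return Named numeric vector `st_mean`, `st_delta`.
#' @export
st_features <- function(x, rate) {
  if (length(x) < 2 * rate)
    stop("epoch must be at least 2 s long", call. = FALSE)
  sec <- round(rate)
  c(st_mean = mean(x),
    st_delta = mean(x[(length(x) - sec + 1L):length(x)]) - mean(x[1:sec]))
}

# 0.05 Hz zero-phase Butterworth smoother at a decimated rate, evaluated
# back on the original grid.
tonic_smooth <- function(xb, fs_d) {
  nb <- length(xb)
  bf <- signal::butter(2, 0.05 / (fs_d / 2), "low")
  filtfilt_padded(bf, xb, ceiling(fs_d / 0.05 * 3))
}

#' Decompose skin conductance into tonic and phasic components
#'
#' The tonic (slow, sweat-level) component is a 0.05 Hz zero-phase low-pass
#' estimate computed on a de-pulsed copy of the signal: the decimated
#' signal is smoothed, positive excursions (candidate skin-conductance
#' responses) are subtracted, and the smoothing is repeated (3 iterations),
#' which stops response pulses from leaking into the tonic level.  The
#' phasic component is defined as the residual, so
#' `tonic + phasic == input` exactly by construction.
#'
#' @param x skin-conductance signal (uS), low-band filtered.
#' @param rate sampling rate, Hz.
#' @return List with numeric vectors `tonic` and `phasic`, each the length
#'   of `x`.
#' @export
gsr_decompose <- function(x, rate) {
  n <- length(x)
  dec <- max(1L, floor(rate / 4))
  nb <- floor(n / dec)
  if (nb < 8L) {
    tonic <- rep(mean(x), n)
    return(list(tonic = tonic, phasic = x - tonic))
  }
  xb <- colMeans(matrix(x[seq_len(nb * dec)], nrow = dec))
  fs_d <- rate / dec
  xw <- xb
  for (i in 1:3) {
    ton <- tonic_smooth(xw, fs_d)
    xw <- xb - pmax(xb - ton, 0)
  }
  ton <- tonic_smooth(xw, fs_d)
  tb <- (seq_len(nb) - 0.5) * dec / rate
  tg <- (seq_len(n) - 1) / rate
  tonic <- stats::approx(tb, ton, xout = tg, rule = 2)$y
  list(tonic = tonic, phasic = x - tonic)
}

#' Score skin-conductance responses on the phasic component
#'
#' A response is a trough-to-peak excursion of the (lightly smoothed)
#' phasic signal with amplitude of at least `min_amp` and a rise time of at
#' most 5 s.
#'
#' @param phasic phasic skin conductance (uS), from [gsr_decompose()].
#' @param rate sampling rate, Hz.
#' @param min_amp minimum trough-to-peak amplitude in uS (default 0.05).
#' @return Named numeric vector `scr_count`, `scr_amp_mean`, `scr_amp_std`;
#'   the amplitude statistics are `NA` when no response qualifies
#'   (`scr_amp_std` needs at least 2).
#' @export
scr_score <- function(phasic, rate, min_amp = 0.05) {
  if (min_amp <= 0) stop("'min_amp' must be positive", call. = FALSE)
  n <- length(phasic)
  out <- c(scr_count = 0, scr_amp_mean = NA_real_, scr_amp_std = NA_real_)
  if (n < rate) return(out)
  bf <- signal::butter(2, min(0.9, 1 / (rate / 2)), "low")
  xs <- filtfilt_padded(bf, phasic, round(4 * rate))
  pk <- find_peaks(xs, min_dist = round(rate / 2))
  if (!length(pk)) return(out)
  amps <- numeric(0)
  for (i in pk) {
    lo <- max(1L, i - round(5 * rate))
    seg <- xs[lo:i]
    tr <- lo + which.min(seg) - 1L
    a <- xs[i] - xs[tr]
    if (a >= min_amp && (i - tr) / rate <= 5) amps <- c(amps, a)
  }
  out["scr_count"] <- length(amps)
  if (length(amps) >= 1L) out["scr_amp_mean"] <- mean(amps)
  if (length(amps) >= 2L) out["scr_amp_std"] <- stats::sd(amps)
  out
}

physio_feature_names <- function() {
  c("rr_mean", "rr_std", "rr_rmssd", "st_mean", "st_delta",
    "gsr_tonic_mean", "gsr_tonic_delta", "scr_count", "scr_amp_mean",
    "scr_amp_std", "hr_mean", "ibi_std", "ecg_grad_median",
    "ecg_grad_absmean", "lf_power", "hf_power", "lf_hf_ratio")
}

#' Extract the 17 physiological features of one epoch
#'
#' Assembles the respiration (3), skin-temperature (2), skin-conductance
#' (5: tonic mean and first-to-last-second tonic difference, response
#' count, response amplitude mean and spread) and ECG (7) features from an
#' already-filtered 4-channel epoch.
#'
#' @param physio matrix with columns `ecg`, `resp`, `gsr`, `st` (filtered).
#' @param rate sampling rate, Hz.
#' @param min_scr_amp minimum skin-conductance response amplitude, uS.
#' @return Named numeric vector of length 17 (order fixed as in
#'   `physio_feature_names()`); unavailable features are `NA`.
#' @export
physio_features <- function(physio, rate, min_scr_amp = 0.05) {
  stopifnot(all(c("ecg", "resp", "gsr", "st") %in% colnames(physio)))
  rr <- respiration_features(physio[, "resp"], rate)
  st <- st_features(physio[, "st"], rate)
  gd <- gsr_decompose(physio[, "gsr"], rate)
  sec <- round(rate)
  nt <- length(gd$tonic)
  gsr_f <- c(gsr_tonic_mean = mean(gd$tonic),
             gsr_tonic_delta = mean(gd$tonic[(nt - sec + 1L):nt]) -
               mean(gd$tonic[1:sec]))
  scr <- scr_score(gd$phasic, rate, min_scr_amp)
  beats <- detect_r_peaks(physio[, "ecg"], rate)
  ecg <- ecg_features(physio[, "ecg"], beats, rate)
  out <- c(rr, st, gsr_f, scr, ecg)
  out[physio_feature_names()]
}
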