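# Zero-phase (forward-backward) filtering with even reflection padding so
# long-time-constant filters do not ring at the epoch edges.
filtfilt_padded <- function(filt, x, pad) {
  n <- length(x)
  pad <- min(n - 1L, as.integer(pad))
  if (pad < 1L) return(signal::filtfilt(filt, x))
  xp <- c(2 * x[1] - rev(x[2:(pad + 1L)]), x,
          2 * x[n] - rev(x[(n - pad):(n - 1L)]))
  signal::filtfilt(filt, xp)[(pad + 1L):(pad + n)]
}

#' Low-band filter for respiration, skin conductance and skin temperature
#'
#' The slow channels are cleaned with a 0-30 Hz band: since the lower
#' corner is DC, this is realised as a 4th-order Butterworth 30 Hz low-pass
#' applied forward and backward (zero-phase), so event timings are not
#' shifted and DC (the tonic level the features need) is preserved.
#'
#' @param x numeric signal.
#' @param rate sampling rate, Hz; must exceed 60 Hz (twice the corner) for
#'   the band to be defined.
#' @return Filtered signal, same length.
#' @export
filter_lowband <- function(x, rate) {
  if (rate <= 60)
    stop("'rate' must exceed 60 Hz: a 30 Hz pass band is undefined below twice the corner frequency",
         call. = FALSE)
  bf <- signal::butter(4, 30 / (rate / 2), "low")
  filtfilt_padded(bf, x, round(rate))
}

#' ECG conditioning filter: 5 Hz high-pass plus 60 Hz notch
#'
#' Removes baseline wander (4th-order Butterworth high-pass, 5 Hz corner)
#' and mains interference (second-order IIR notch at 60 Hz, quality factor
#' 30), both applied zero-phase.  The QRS energy band (5-30 Hz) that the
#' R-peak detector and gradient features rely on passes unchanged.
#'
#' @param x numeric ECG signal (mV).
#' @param rate sampling rate, Hz; must exceed 120 Hz so the 60 Hz notch is
#'   below Nyquist.
#' @return Filtered signal, same length.
#' @export
filter_ecg <- function(x, rate) {
  if (rate <= 120)
    stop("'rate' must exceed 120 Hz for a 60 Hz notch to be defined",
         call. = FALSE)
  hp <- signal::butter(4, 5 / (rate / 2), "high")
  y <- filtfilt_padded(hp, x, round(rate))
  # RBJ biquad notch, f0 = 60 Hz, Q = 30
  w0 <- 2 * pi * 60 / rate
  alpha <- sin(w0) / (2 * 30)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  filtfilt_padded(signal::Arma(b = b / a[1], a = a / a[1]), y, round(rate))
}

#' Slice continuous session recordings into baseline and scenario epochs
#'
#' @param physio numeric matrix (or data frame) of physiological channels
#'   sampled at `physio_rate`; rows are samples from the session start.
#' @param segments data frame with columns `segment`, `role`, `start_s`,
#'   `end_s` and the condition labels `phone`, `drowsy`, `town`, `snowy`.
#' @param physio_rate sampling rate of `physio`, Hz.
#' @param kinematics optional named list of per-segment kinematics matrices
#'   (names = segment ids), or a single data frame with a `t_s` column from
#'   which scenario spans are cut.
#' @param kinematics_rate sampling rate of the kinematics channels, Hz.
#' @return A list of `hds_recording` objects, one per segment row, each
#'   holding the physiological samples with start time `start_s` (inclusive)
#'   to `end_s` (exclusive).  Baseline epochs are flagged by `role`.
#' @export
epoch_segments <- function(physio, segments, physio_rate,
                           kinematics = NULL, kinematics_rate = 60) {
  physio <- as.matrix(physio)
  if (nrow(segments) == 0L) return(list())
  need <- c("segment", "role", "start_s", "end_s")
  if (!all(need %in% names(segments)))
    stop("'segments' must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  span <- nrow(physio) / physio_rate
  bad <- which(segments$start_s < 0 | segments$end_s > span + 1e-9 |
                 segments$end_s <= segments$start_s)
  if (length(bad))
    stop("segment rows out of recording range: ",
         paste(bad, collapse = ", "), call. = FALSE)
  ord <- order(segments$start_s)
  st <- segments$start_s[ord]; en <- segments$end_s[ord]
  olap <- which(st[-1] < en[-length(en)] - 1e-9)
  if (length(olap))
    stop("overlapping segment rows: ",
         paste(sort(ord[c(olap, olap + 1L)]), collapse = ", "), call. = FALSE)
  t_phys <- (seq_len(nrow(physio)) - 1) / physio_rate
  kin_df <- if (is.data.frame(kinematics)) kinematics else NULL
  out <- vector("list", nrow(segments))
  for (i in seq_len(nrow(segments))) {
    row <- segments[i, ]
    idx <- which(t_phys >= row$start_s - 1e-9 & t_phys < row$end_s - 1e-9)
    kin <- NULL
    if (row$role == "scenario") {
      if (!is.null(kin_df)) {
        kidx <- which(kin_df$t_s >= row$start_s - 1e-9 &
                        kin_df$t_s < row$end_s - 1e-9)
        if (length(kidx))
          kin <- as.matrix(kin_df[kidx, setdiff(names(kin_df), "t_s")])
      } else if (!is.null(kinematics)) {
        kin <- kinematics[[as.character(row$segment)]]
      }
    }
    out[[i]] <- structure(list(
      physio = physio[idx, , drop = FALSE], kinematics = kin,
      physio_rate = physio_rate, kinematics_rate = kinematics_rate,
      role = row$role,
      labels = list(phone = row$phone, drowsy = row$drowsy,
                    town = row$town, snowy = row$snowy),
      participant = row$participant %||% NA_integer_,
      session = row$session %||% NA_integer_,
      segment = row$segment), class = "hds_recording")
  }
  out
}

# Filter the four physiological channels of a continuous session matrix.
filter_physio <- function(physio, rate) {
  physio <- as.matrix(physio)
  out <- physio
  if ("ecg" %in% colnames(physio))
    out[, "ecg"] <- filter_ecg(physio[, "ecg"], rate)
  for (ch in intersect(c("resp", "gsr", "st"), colnames(physio)))
    out[, ch] <- filter_lowband(physio[, ch], rate)
  out
}
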