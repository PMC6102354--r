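#' Names of the 61 model features, by feature set
#'
#' @return Named list with character vectors `physio` (17), `kinematics`
#'   (24) and `characteristics` (20).
#' @export
feature_sets <- function() {
  list(physio = physio_feature_names(),
       kinematics = kinematics_feature_names(),
       characteristics = characteristics_feature_names())
}

# One feature row from an epoched (already filtered) recording.
recording_features <- function(rec, questionnaires = NULL,
                               min_scr_amp = 0.05) {
  pf <- physio_features(rec$physio, rec$physio_rate, min_scr_amp)
  kf <- stats::setNames(rep(NA_real_, 24), kinematics_feature_names())
  if (!is.null(rec$kinematics)) kf <- kinematics_features(rec$kinematics)
  cf <- stats::setNames(rep(NA_real_, 20), characteristics_feature_names())
  if (!is.null(questionnaires) && !is.na(rec$participant))
    cf <- encode_characteristics(questionnaires, rec$participant, rec$session)
  meta <- data.frame(participant = rec$participant, session = rec$session,
                     segment = rec$segment, role = rec$role,
                     phone = rec$labels$phone %||% NA_integer_,
                     drowsy = rec$labels$drowsy %||% NA_integer_,
                     town = rec$labels$town %||% NA_integer_,
                     snowy = rec$labels$snowy %||% NA_integer_)
  cbind(meta, as.data.frame(as.list(c(pf, kf, cf))))
}

#' Extract the feature table of one continuous session
#'
#' Filters the physiological channels of the whole session recording (the
#' filters see the continuous signal, so epoch boundaries carry no filter
#' transients), slices it into baseline and scenario epochs, and computes
#' the 17 physiological features per epoch, the 24 kinematics features per
#' scenario, and the 20 session-constant driver-characteristics features.
#'
#' @param physio continuous session physiology matrix/data frame with
#'   columns `ecg`, `resp`, `gsr`, `st`.
#' @param segments segments table (see [epoch_segments()]).
#' @param physio_rate,kinematics_rate sampling rates, Hz.
#' @param kinematics per-segment kinematics list or data frame with `t_s`.
#' @param questionnaires optional `hds_questionnaires` for the
#'   characteristics block.
#' @param min_scr_amp skin-conductance response threshold, uS.
#' @return Data frame with one row per segment: identifiers, `role`, the
#'   four condition labels, and the 61 features (kinematics and
#'   characteristics are `NA` on baseline rows where absent).
#' @export
extract_session_features <- function(physio, segments, physio_rate,
                                     kinematics = NULL, kinematics_rate = 60,
                                     questionnaires = NULL,
                                     min_scr_amp = 0.05) {
  pf <- filter_physio(physio, physio_rate)
  recs <- epoch_segments(pf, segments, physio_rate, kinematics,
                         kinematics_rate)
  do.call(rbind, lapply(recs, recording_features,
                        questionnaires = questionnaires,
                        min_scr_amp = min_scr_amp))
}

#' Extract the full feature table of a simulated study
#'
#' Runs the filtering, epoching and feature extraction of every session of
#' the study; with the default design this yields 21 x 4 x 8 = 672
#' scenario rows plus 84 baseline rows carrying the per-session baseline
#' physiology needed for normalization.
#'
#' @param study an `hds_study`.
#' @param participants optional subset of participants.
#' @param min_scr_amp skin-conductance response threshold, uS.
#' @param verbose print a progress line per participant.
#' @return Data frame as in [extract_session_features()], all sessions
#'   stacked.
#' @export
extract_features <- function(study, participants = NULL,
                             min_scr_amp = 0.05, verbose = FALSE) {
  stopifnot(inherits(study, "hds_study"))
  if (is.null(participants))
    participants <- seq_len(study$design$n_participants)
  out <- vector("list", length(participants) * study$design$n_sessions)
  k <- 0L
  for (p in participants) {
    if (verbose) message("participant ", p)
    for (s in seq_len(study$design$n_sessions)) {
      sig <- session_signals(study, p, s)
      k <- k + 1L
      out[[k]] <- extract_session_features(
        sig$physio, sig$segments, sig$physio_rate, sig$kinematics,
        sig$kinematics_rate, study$questionnaires, min_scr_amp)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write or read a feature table as CSV
#'
#' One row per segment; columns are the identifiers, `role`, the four
#' condition labels and the 61 features with stable names.
#'
#' @param features feature table data frame.
#' @param path CSV path.
#' @return `path` (write) or the feature table (read).
#' @export
write_features <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) utils::read.csv(path)
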