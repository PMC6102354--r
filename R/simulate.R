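# Per-participant physiological baselines, deterministic given the design
# seed: resting heart rate, skin-conductance level, breathing rate and
# skin temperature differ between people.
participant_physio <- function(design, p) {
  seeds <- design_seeds(design)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seeds$participant[p])
  list(hr = 70 + stats::rnorm(1, 0, 5),
       gsr_level = pmax(0.5, 2 + stats::rnorm(1, 0, 0.5)),
       resp_bpm = 15 + stats::rnorm(1, 0, 1),
       st_level = 33 + stats::rnorm(1, 0, 0.5))
}

# Map a schedule row (condition labels + role) to the generator parameters
# of the four physiological channels.
segment_params <- function(design, effects, row, pp) {
  phone <- if (row$role == "scenario") row$phone else 0L
  town <- if (row$role == "scenario") row$town else 0L
  snowy <- if (row$role == "scenario") row$snowy else 0L
  drowsy <- row$drowsy
  dur <- row$end_s - row$start_s
  nz <- effects$noise
  list(
    duration = dur,
    ecg = list(mean_hr = pp$hr, lf_amp = 0.01 + town * effects$town$ibi_lf_amp,
               hf_amp = 0.02,
               artifact_power = 0.05 + phone * effects$phone$ecg_artifact_power,
               ibi_noise = nz$ibi, noise = nz$ecg,
               lf_freq = effects$mayer_freq, hf_freq = effects$resp_freq),
    resp = list(rate_bpm = pp$resp_bpm + phone * effects$phone$resp_rate,
                period_jitter = 0.15, noise = nz$resp),
    gsr = list(tonic_level = pp$gsr_level +
                 snowy * effects$snowy$gsr_tonic_mean,
               tonic_slope = drowsy * effects$drowsy$gsr_tonic_slope,
               scr_rate = effects$scr_rate,
               scr_amp_mean = 0.4,
               scr_amp_sd = if (town == 1) effects$town$scr_amp_sd else 0.10,
               noise = nz$gsr),
    st = list(level = pp$st_level, noise = nz$st),
    labels = list(phone = phone, drowsy = drowsy, town = town, snowy = snowy)
  )
}

# Generate the four physiological channels for one segment under its own
# seed.  Returns an n x 4 matrix (ecg, resp, gsr, st).
gen_segment_physio <- function(design, effects, row, pp) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(row$seg_seed)
  par <- segment_params(design, effects, row, pp)
  # condition-independent between-segment wander of the physiological state
  wd <- effects$wander
  par$ecg$mean_hr <- min(200, max(30, par$ecg$mean_hr +
                                    stats::rnorm(1, 0, wd$hr)))
  par$ecg$artifact_power <- par$ecg$artifact_power *
    exp(stats::rnorm(1, 0, wd$artifact_log))
  par$resp$rate_bpm <- max(6, par$resp$rate_bpm + stats::rnorm(1, 0, wd$resp))
  par$gsr$tonic_level <- max(0.2, par$gsr$tonic_level +
                               stats::rnorm(1, 0, wd$gsr_level))
  par$gsr$tonic_slope <- par$gsr$tonic_slope + stats::rnorm(1, 0, wd$gsr_slope)
  par$st$level <- par$st$level + stats::rnorm(1, 0, wd$st)
  dur <- par$duration
  rate <- design$physio_rate
  ecg <- do.call(synth_ecg, c(list(duration = dur, rate = rate), par$ecg))
  resp <- do.call(synth_resp, c(list(duration = dur, rate = rate), par$resp))
  n_scr <- stats::rpois(1, par$gsr$scr_rate * dur / 60)
  scr_times <- sort(stats::runif(n_scr, 0, dur * 0.95))
  scr_amps <- pmax(stats::rnorm(n_scr, par$gsr$scr_amp_mean,
                                par$gsr$scr_amp_sd), 0.06)
  gsr <- synth_gsr(dur, rate, par$gsr$tonic_level, par$gsr$tonic_slope,
                   scr_times, scr_amps, par$gsr$noise)
  st <- synth_st(dur, rate, par$st$level,
                 slope = stats::rnorm(1, 0, 5e-4), noise = par$st$noise)
  out <- cbind(ecg = as.numeric(ecg), resp = resp, gsr = gsr, st = st)
  attr(out, "beat_times") <- attr(ecg, "beat_times")
  attr(out, "scr_times") <- scr_times
  attr(out, "scr_amps") <- scr_amps
  out
}

gen_segment_kinematics <- function(design, effects, row) {
  if (row$role != "scenario") return(NULL)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(row$seg_seed + 1L)
  wd <- effects$wander
  synth_kinematics(row$end_s - row$start_s, design$kinematics_rate,
                   list(phone = row$phone, town = row$town, snowy = row$snowy),
                   effects,
                   lat_offset = stats::rnorm(1, 0, wd$lat_pos),
                   response_scale = min(2, max(0.05,
                     stats::rnorm(1, 1, wd$response))))
}

#' Simulate a complete synthetic driving study
#'
#' Builds the full study object: the factorial segment schedule (with
#' seeded drowsy-session assignment and scenario orders), the simulated
#' questionnaire battery, and deterministic per-segment seeds from which
#' the raw physiological and kinematics recordings of any segment can be
#' generated on demand (see [session_signals()] and
#' [scenario_recording()]).  Raw signals are materialised lazily because a
#' full-scale study (21 x 4 sessions of 36 min at 512 Hz) does not fit
#' comfortably in memory as a single object.
#'
#' @param design an `hds_design`.
#' @param effects an `hds_effects`.
#' @return An object of class `hds_study` with elements `design`,
#'   `effects`, `schedule` and `questionnaires`.
#' @export
#' @examples
#' study <- simulate_study(study_design(n_participants = 1,
#'                                      scenario_duration = 20,
#'                                      baseline_duration = 20),
#'                         effect_config())
#' nrow(study$schedule)
simulate_study <- function(design = study_design(),
                           effects = effect_config()) {
  stopifnot(inherits(design, "hds_design"), inherits(effects, "hds_effects"))
  schedule <- session_schedule(design)
  q <- simulate_questionnaires(design, effects, schedule)
  structure(list(design = design, effects = effects, schedule = schedule,
                 questionnaires = q),
            class = "hds_study")
}

#' @export
print.hds_study <- function(x, ...) {
  n_sc <- sum(x$schedule$role == "scenario")
  n_bl <- sum(x$schedule$role == "baseline")
  cat("Synthetic driving study:", n_sc, "scenario segments,",
      n_bl, "baselines\n")
  print(x$design)
  invisible(x)
}

#' Materialise the raw recording of one segment
#'
#' @param study an `hds_study`.
#' @param participant,session,segment segment address; `segment = 0` is the
#'   baseline.
#' @return A list of class `hds_recording` with the physiology matrix
#'   (`ecg`, `resp`, `gsr`, `st` columns at `physio_rate`), the kinematics
#'   matrix (8 channels at `kinematics_rate`; `NULL` for baselines), the
#'   condition labels, and the segment address.  Generation is
#'   deterministic: the same study object always yields the same samples.
#' @export
scenario_recording <- function(study, participant, session, segment) {
  stopifnot(inherits(study, "hds_study"))
  row <- study$schedule[study$schedule$participant == participant &
                          study$schedule$session == session &
                          study$schedule$segment == segment, ]
  if (nrow(row) != 1L)
    stop("no such segment: participant ", participant, ", session ",
         session, ", segment ", segment, call. = FALSE)
  row <- as.list(row)
  pp <- participant_physio(study$design, participant)
  physio <- gen_segment_physio(study$design, study$effects, row, pp)
  kin <- gen_segment_kinematics(study$design, study$effects, row)
  structure(list(physio = physio, kinematics = kin,
                 physio_rate = study$design$physio_rate,
                 kinematics_rate = study$design$kinematics_rate,
                 role = row$role,
                 labels = list(phone = row$phone, drowsy = row$drowsy,
                               town = row$town, snowy = row$snowy),
                 participant = participant, session = session,
                 segment = segment),
            class = "hds_recording")
}

#' Materialise the continuous signals of one session
#'
#' Concatenates the baseline and scenario segments of a session into one
#' continuous 4-channel physiology matrix (as recorded by a single
#' amplifier run) and a list of per-scenario kinematics matrices.
#'
#' @param study an `hds_study`.
#' @param participant,session session address.
#' @return A list with `physio` (matrix), `kinematics` (named list indexed
#'   by segment number), `segments` (the schedule rows of this session) and
#'   the two sampling rates.
#' @export
session_signals <- function(study, participant, session) {
  stopifnot(inherits(study, "hds_study"))
  seg <- study$schedule[study$schedule$participant == participant &
                          study$schedule$session == session, ]
  if (nrow(seg) == 0L)
    stop("no such session: participant ", participant, ", session ",
         session, call. = FALSE)
  seg <- seg[order(seg$segment), ]
  pp <- participant_physio(study$design, participant)
  phys <- vector("list", nrow(seg))
  kin <- list()
  for (i in seq_len(nrow(seg))) {
    row <- as.list(seg[i, ])
    phys[[i]] <- gen_segment_physio(study$design, study$effects, row, pp)
    if (row$role == "scenario")
      kin[[as.character(row$segment)]] <-
        gen_segment_kinematics(study$design, study$effects, row)
  }
  list(physio = do.call(rbind, phys), kinematics = kin,
       segments = seg, physio_rate = study$design$physio_rate,
       kinematics_rate = study$design$kinematics_rate)
}

#' Write a simulated study to disk in the portable CSV layout
#'
#' One directory per participant/session (`p01/s1/`, ...) containing
#' `physio.csv` (`t_s`, `ecg`, `resp`, `gsr`, `st`), `kinematics.csv`
#' (`t_s` plus the 8 channels, scenario spans only), `segments.csv`
#' (segment id, role, start/end seconds and the four condition labels) and
#' `questionnaires.json`; a top-level `manifest.json` records the design
#' and effect configuration.  The same layout is accepted for user-supplied
#' data by [read_session()].
#'
#' @param study an `hds_study`.
#' @param dir output directory (created if needed).
#' @param participants optional subset of participants to write.
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir, participants = NULL) {
  stopifnot(inherits(study, "hds_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  design <- study$design
  if (is.null(participants)) participants <- seq_len(design$n_participants)
  manifest <- list(design = unclass(design),
                   effects = unclass(study$effects),
                   generator = "hdstate synthetic study")
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  q <- study$questionnaires
  for (p in participants) {
    for (s in seq_len(design$n_sessions)) {
      sdir <- file.path(dir, sprintf("p%02d", p), sprintf("s%d", s))
      dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
      sig <- session_signals(study, p, s)
      tp <- (seq_len(nrow(sig$physio)) - 1) / sig$physio_rate
      utils::write.csv(data.frame(t_s = tp, sig$physio),
                       file.path(sdir, "physio.csv"), row.names = FALSE)
      seg <- sig$segments
      kin_rows <- lapply(seq_len(nrow(seg)), function(i) {
        m <- sig$kinematics[[as.character(seg$segment[i])]]
        if (is.null(m)) return(NULL)
        tk <- seg$start_s[i] + (seq_len(nrow(m)) - 1) / sig$kinematics_rate
        data.frame(t_s = tk, m)
      })
      utils::write.csv(do.call(rbind, kin_rows),
                       file.path(sdir, "kinematics.csv"), row.names = FALSE)
      utils::write.csv(seg[, c("segment", "role", "start_s", "end_s",
                               "phone", "drowsy", "town", "snowy")],
                       file.path(sdir, "segments.csv"), row.names = FALSE)
      qs <- list(
        participant = as.list(q$participants[q$participants$participant == p, ]),
        session = as.list(q$sessions[q$sessions$participant == p &
                                       q$sessions$session == s, ]),
        tlx = q$tlx[q$tlx$participant == p & q$tlx$session == s, ])
      jsonlite::write_json(qs, file.path(sdir, "questionnaires.json"),
                           auto_unbox = TRUE, digits = NA, dataframe = "rows")
    }
  }
  invisible(dir)
}

#' Read one session directory in the portable CSV layout
#'
#' @param dir a session directory as written by [write_study()].
#' @return A list with `physio`, `kinematics`, `segments` data frames and
#'   `questionnaires` (parsed JSON list), or `NULL` entries for missing
#'   optional files.
#' @export
read_session <- function(dir) {
  need <- file.path(dir, c("physio.csv", "segments.csv"))
  missing <- need[!file.exists(need)]
  if (length(missing))
    stop("missing session files: ", paste(basename(missing), collapse = ", "),
         call. = FALSE)
  kin_path <- file.path(dir, "kinematics.csv")
  q_path <- file.path(dir, "questionnaires.json")
  list(physio = utils::read.csv(file.path(dir, "physio.csv")),
       kinematics = if (file.exists(kin_path)) utils::read.csv(kin_path),
       segments = utils::read.csv(file.path(dir, "segments.csv")),
       questionnaires = if (file.exists(q_path))
         jsonlite::read_json(q_path, simplifyVector = TRUE))
}
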