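#' Define the factorial layout of a simulated driving study
#'
#' The default layout mirrors a within-subject driving-simulator protocol:
#' 21 participants, each completing 4 sessions (exactly half of them under
#' mild sleep deprivation, "drowsy"), each session consisting of one 4-min
#' resting baseline followed by 8 driving scenarios that enumerate all
#' 2x2x2 combinations of traffic density (town/highway), weather
#' (snowy/clear) and cell-phone use, presented in seeded random order.
#'
#' @param n_participants number of participants (default 21).
#' @param n_sessions sessions per participant; must be even so that exactly
#'   half can be flagged drowsy (default 4).
#' @param scenarios_per_session scenarios after the baseline; must be a
#'   multiple of 8 so each block enumerates the full factorial (default 8).
#' @param scenario_duration scenario length in seconds (default 240).
#' @param baseline_duration baseline length in seconds (default 240).
#' @param physio_rate sampling rate of the physiological channels in Hz
#'   (default 512).
#' @param kinematics_rate sampling rate of the vehicle-kinematics channels
#'   in Hz (default 60).
#' @param seed integer seed governing every random choice derived from the
#'   design (session order, scenario order, per-segment signal seeds).
#' @return An object of class `hds_design`.
#' @export
#' @examples
#' d <- study_design(n_participants = 2, scenario_duration = 30,
#'                   baseline_duration = 30)
#' d$n_participants
study_design <- function(n_participants = 21L,
                         n_sessions = 4L,
                         scenarios_per_session = 8L,
                         scenario_duration = 240,
                         baseline_duration = 240,
                         physio_rate = 512,
                         kinematics_rate = 60,
                         seed = 1L) {
  num_fields <- list(n_participants = n_participants, n_sessions = n_sessions,
                     scenarios_per_session = scenarios_per_session,
                     scenario_duration = scenario_duration,
                     baseline_duration = baseline_duration,
                     physio_rate = physio_rate, kinematics_rate = kinematics_rate)
  for (nm in names(num_fields)) {
    v <- num_fields[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("'", nm, "' must be a positive number", call. = FALSE)
  }
  if (n_sessions %% 2 != 0)
    stop("'n_sessions' must be even (half the sessions are flagged drowsy)",
         call. = FALSE)
  if (scenarios_per_session %% 8 != 0)
    stop("'scenarios_per_session' must be a multiple of 8 (full factorial blocks)",
         call. = FALSE)
  structure(list(
    n_participants = as.integer(n_participants),
    n_sessions = as.integer(n_sessions),
    scenarios_per_session = as.integer(scenarios_per_session),
    scenario_duration = scenario_duration,
    baseline_duration = baseline_duration,
    physio_rate = physio_rate,
    kinematics_rate = kinematics_rate,
    seed = as.integer(seed)
  ), class = "hds_design")
}

#' @export
print.hds_design <- function(x, ...) {
  cat("Study design:", x$n_participants, "participants x", x$n_sessions,
      "sessions x", x$scenarios_per_session, "scenarios\n")
  cat("  scenario", x$scenario_duration, "s, baseline", x$baseline_duration,
      "s; physio", x$physio_rate, "Hz, kinematics", x$kinematics_rate,
      "Hz; seed", x$seed, "\n")
  invisible(x)
}

#' Condition-effect configuration for the synthetic study
#'
#' Collects every knob that couples the experimental conditions (cell-phone
#' use, sleep deprivation, dense town traffic, snowy weather) to the
#' generated signals and questionnaire scores.  Defaults are chosen so that
#' each condition perturbs the signals it is known to act on: phone use
#' raises respiration rate, ECG motion-artifact power and the mean lateral
#' lane position; drowsiness shifts mood-questionnaire affect scores, the
#' session start hour, and adds a slow tonic skin-conductance drift; dense
#' traffic multiplies the lane-change rate (calibrated so the observed
#' standard deviation of the lane number roughly quadruples), adds 0.1 Hz
#' inter-beat-interval modulation and widens the spread of skin-conductance
#' response amplitudes; snow elevates rear-tire-slip and throttle
#' variability and the tonic skin-conductance level.
#'
#' Setting `null = TRUE` zeroes every condition effect (multipliers to 1,
#' shifts to 0, identical start-hour distributions) so that labels and
#' signals are statistically independent, which is the configuration used
#' for chance-level calibration.
#'
#' @param scr_rate spontaneous skin-conductance responses per minute in
#'   neutral scenarios (default 3).
#' @param mayer_freq frequency of the low-frequency (Mayer-wave band)
#'   inter-beat modulation in Hz (default 0.10).
#' @param resp_freq neutral breathing frequency in Hz (default 0.25,
#'   i.e. 15 breaths/min).
#' @param snow_friction_factor tire-road friction in snow as a fraction of
#'   the clear-weather value, in (0, 1] (default 0.60).
#' @param town_lane_std_mult target multiplier for the standard deviation of
#'   the lane number in dense traffic (default 4; the lane switching rate is
#'   scaled by its square, which reproduces the target ratio at the default
#'   base rate).
#' @param phone,drowsy,town,snowy named lists of per-cause effect entries;
#'   see Details for the recognised names.  Pass modified copies of the
#'   defaults to strengthen, weaken or remove individual effects.
#' @param noise named list of channel noise levels.
#' @param wander named list of condition-independent between-segment
#'   variability levels: a driver's heart rate, breathing rate,
#'   skin-conductance level/slope, skin temperature, artifact level,
#'   lane-keeping offset, and the idiosyncratic scaling of the snow
#'   response drift from scenario to scenario regardless of condition.
#'   This wander is what keeps single conditions from being trivially
#'   separable; it is retained under `null = TRUE` (it carries no label
#'   information).
#' @return An object of class `hds_effects`.
#' @details Recognised per-cause entries (additive shifts unless stated):
#'   `phone`: `resp_rate` (breaths/min), `ecg_artifact_power`,
#'   `lat_pos_mean` (m), `tlx_all` (points on the 0-100 scale).
#'   `drowsy`: `staq_negative_affect`, `staq_positive_affect`,
#'   `staq_activated`, `staq_inactivated` (points on the 1-5 scale),
#'   `gsr_tonic_slope` (uS/s), `start_hour_mean` / `alert_start_hour_mean`
#'   (h), `tlx_frustration`, `tlx_performance`.
#'   `town`: `ibi_lf_amp` (s), `scr_amp_sd` (uS, replaces the neutral
#'   spread), `tlx_temporal`.
#'   `snowy`: `slip_mean` (added slip level), `slip_sd`,
#'   `throttle_sd_mult` (multiplicative), `gsr_tonic_mean` (uS),
#'   `tlx_mental`, `tlx_minor` (added to the remaining subscales).
#' @export
effect_config <- function(scr_rate = 3,
                          mayer_freq = 0.10,
                          resp_freq = 0.25,
                          snow_friction_factor = 0.60,
                          town_lane_std_mult = 4,
                          phone = list(resp_rate = 3,
                                       ecg_artifact_power = 0.30,
                                       lat_pos_mean = 0.15,
                                       tlx_all = 15),
                          drowsy = list(staq_negative_affect = 1.0,
                                        staq_positive_affect = -0.8,
                                        staq_activated = -0.6,
                                        staq_inactivated = 0.8,
                                        gsr_tonic_slope = 0.002,
                                        start_hour_mean = 6,
                                        alert_start_hour_mean = 13,
                                        start_hour_sd = 0.75,
                                        alert_start_hour_sd = 2,
                                        tlx_frustration = 6,
                                        tlx_performance = 5),
                          town = list(ibi_lf_amp = 0.025,
                                      scr_amp_sd = 0.30,
                                      tlx_temporal = 4),
                          snowy = list(slip_mean = 0.13,
                                       slip_sd = 0.07,
                                       throttle_sd_mult = 2,
                                       gsr_tonic_mean = 0.3,
                                       tlx_mental = 6,
                                       tlx_minor = 3),
                          noise = list(ecg = 0.02, ibi = 0.01, resp = 0.05,
                                       gsr = 0.005, st = 0.005, kin = 1),
                          wander = list(hr = 2, resp = 1.2, gsr_level = 0.3,
                                        gsr_slope = 5e-4, st = 0.2,
                                        artifact_log = 0.5, lat_pos = 0.12,
                                        response = 0.5),
                          null = FALSE) {
  for (nm in c("scr_rate", "mayer_freq", "resp_freq")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v <= 0)
      stop("'", nm, "' must be strictly positive", call. = FALSE)
  }
  if (!is.numeric(snow_friction_factor) || snow_friction_factor <= 0 ||
      snow_friction_factor > 1)
    stop("'snow_friction_factor' must lie in (0, 1]", call. = FALSE)
  if (isTRUE(null)) {
    town_lane_std_mult <- 1
    phone <- list(resp_rate = 0, ecg_artifact_power = 0, lat_pos_mean = 0,
                  tlx_all = 0)
    drowsy <- list(staq_negative_affect = 0, staq_positive_affect = 0,
                   staq_activated = 0, staq_inactivated = 0,
                   gsr_tonic_slope = 0, start_hour_mean = 13,
                   alert_start_hour_mean = 13, start_hour_sd = 2,
                   alert_start_hour_sd = 2, tlx_frustration = 0,
                   tlx_performance = 0)
    town <- list(ibi_lf_amp = 0, scr_amp_sd = 0.10, tlx_temporal = 0)
    snowy <- list(slip_mean = 0, slip_sd = 0, throttle_sd_mult = 1,
                  gsr_tonic_mean = 0, tlx_mental = 0, tlx_minor = 0)
  }
  structure(list(scr_rate = scr_rate, mayer_freq = mayer_freq,
                 resp_freq = resp_freq,
                 snow_friction_factor = snow_friction_factor,
                 town_lane_std_mult = town_lane_std_mult,
                 phone = phone, drowsy = drowsy, town = town, snowy = snowy,
                 noise = noise, wander = wander, null = isTRUE(null)),
            class = "hds_effects")
}

#' @export
print.hds_effects <- function(x, ...) {
  cat("Condition-effect configuration",
      if (x$null) "(null: all effects removed)" else "(default effects)", "\n")
  cat("  SCR rate", x$scr_rate, "/min; LF modulation", x$mayer_freq,
      "Hz; breathing", x$resp_freq, "Hz; snow friction",
      x$snow_friction_factor, "\n")
  invisible(x)
}

# Deterministic per-segment and per-participant seed streams, drawn once
# from the design's master seed so any segment can be regenerated in
# isolation.
design_seeds <- function(design) {
  n_seg <- design$n_participants * design$n_sessions *
    (design$scenarios_per_session + 1L)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(design$seed)
  list(segment = sample.int(2147483646L, n_seg),
       participant = sample.int(2147483646L, design$n_participants),
       session = sample.int(2147483646L,
                            design$n_participants * design$n_sessions),
       schedule = sample.int(2147483646L, 1L))
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
  invisible(NULL)
}

# All 8 combinations of (town, snowy, phone), fixed reference order.
scenario_factorial <- function() {
  g <- expand.grid(phone = 0:1, snowy = 0:1, town = 0:1)
  g[, c("town", "snowy", "phone")]
}

#' Build the segment schedule implied by a study design
#'
#' Enumerates every baseline and scenario segment of the study: which
#' sessions are drowsy (exactly half per participant, in seeded random
#' order), the seeded random presentation order of the 8 factorial
#' scenarios within each session, and the start/end time of each segment on
#' the session clock.
#'
#' @param design an `hds_design`.
#' @return A data frame with one row per segment and columns `participant`,
#'   `session`, `segment` (0 = baseline), `role`, `phone`, `drowsy`,
#'   `town`, `snowy`, `start_s`, `end_s`, and `seg_seed`.
#' @export
session_schedule <- function(design) {
  stopifnot(inherits(design, "hds_design"))
  seeds <- design_seeds(design)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seeds$schedule)
  fac <- scenario_factorial()
  nsc <- design$scenarios_per_session
  blocks <- nsc / 8L
  rows <- vector("list", design$n_participants * design$n_sessions)
  k <- 0L
  seg_idx <- 0L
  for (p in seq_len(design$n_participants)) {
    drowsy_sessions <- sample(seq_len(design$n_sessions),
                              design$n_sessions / 2L)
    for (s in seq_len(design$n_sessions)) {
      ord <- unlist(lapply(seq_len(blocks), function(b) sample.int(8L)))
      sc <- fac[ord, , drop = FALSE]
      seg <- data.frame(
        participant = p, session = s, segment = 0:nsc,
        role = c("baseline", rep("scenario", nsc)),
        phone = c(NA_integer_, sc$phone),
        drowsy = as.integer(s %in% drowsy_sessions),
        town = c(NA_integer_, sc$town),
        snowy = c(NA_integer_, sc$snowy),
        stringsAsFactors = FALSE)
      seg$start_s <- c(0, design$baseline_duration +
                         (seq_len(nsc) - 1L) * design$scenario_duration)
      seg$end_s <- seg$start_s +
        c(design$baseline_duration, rep(design$scenario_duration, nsc))
      seg$seg_seed <- seeds$segment[seg_idx + seq_len(nsc + 1L)]
      seg_idx <- seg_idx + nsc + 1L
      k <- k + 1L
      rows[[k]] <- seg
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
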