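# Truncated-normal draw by clamping; adequate for bounded questionnaire
# scales where the mass near the bounds is small.
rnorm_clamped <- function(n, mean, sd, lo, hi) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

#' Simulate the questionnaire battery of the study
#'
#' Generates per-participant demographics (age, gender, dominant hand,
#' driving experience, height, weight, glasses), Big-Five personality
#' scores (IPIP, 10-50 per trait), a perceived-stress score (PSS-10,
#' 0-40), per-session mood scores (STAQ: negative affect, positive affect,
#' activated, inactivated; 1-5) and per-scenario workload scores
#' (NASA-TLX: six subscales plus overall, 0-100).
#'
#' Condition coupling follows `effects`: drowsy sessions shift the STAQ
#' affect scores and the session start hour; phone scenarios raise all six
#' TLX subscales; dense traffic raises temporal demand; snow raises mental
#' demand and, mildly, the remaining subscales.  The TLX overall score is
#' the subscale mean plus noise, so subscale shifts propagate to it.
#'
#' @param design an `hds_design`.
#' @param effects an `hds_effects`.
#' @param schedule optional precomputed `session_schedule(design)`.
#' @return A list of class `hds_questionnaires` with data frames
#'   `participants` (demographics + IPIP + PSS-10), `sessions` (STAQ and
#'   start hour, one row per participant x session) and `tlx` (one row per
#'   scenario with the four condition labels).
#' @export
simulate_questionnaires <- function(design, effects,
                                    schedule = session_schedule(design)) {
  stopifnot(inherits(design, "hds_design"), inherits(effects, "hds_effects"))
  seeds <- design_seeds(design)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))

  np <- design$n_participants
  set.seed(seeds$participant[1L])
  participants <- data.frame(
    participant = seq_len(np),
    age = round(rnorm_clamped(np, 25.1, 8.7, 18, 65)),
    gender = stats::rbinom(np, 1L, 6 / 21),            # 1 = female
    dominant_hand = stats::rbinom(np, 1L, 0.1),        # 1 = left
    height = round(stats::rnorm(np, 172, 9)),
    glasses = stats::rbinom(np, 1L, 0.3)
  )
  participants$weight <- round(rnorm_clamped(np, 22.5, 2.5, 17, 35) *
                                 (participants$height / 100)^2)
  participants$driving_experience <-
    pmax(0, round(participants$age - 16 - stats::rexp(np, 1 / 2)))
  for (tr in c("extraversion", "neuroticism", "agreeableness",
               "openness", "conscientiousness"))
    participants[[paste0("ipip_", tr)]] <- round(rnorm_clamped(np, 33, 6, 10, 50))
  participants$pss10 <- round(rnorm_clamped(np, 15, 6, 0, 40))

  dr <- effects$drowsy
  ses <- unique(schedule[, c("participant", "session", "drowsy")])
  rownames(ses) <- NULL
  n_ses <- nrow(ses)
  set.seed(seeds$session[1L])
  hour_mean <- ifelse(ses$drowsy == 1, dr$start_hour_mean,
                      dr$alert_start_hour_mean)
  hour_sd <- ifelse(ses$drowsy == 1, dr$start_hour_sd,
                    dr$alert_start_hour_sd)
  ses$start_hour <- round(rnorm_clamped(n_ses, hour_mean, hour_sd, 0, 23), 1)
  staq_shift <- function(nm) ses$drowsy * dr[[paste0("staq_", nm)]]
  ses$staq_negative_affect <-
    rnorm_clamped(n_ses, 2.0 + staq_shift("negative_affect"), 0.4, 1, 5)
  ses$staq_positive_affect <-
    rnorm_clamped(n_ses, 3.5 + staq_shift("positive_affect"), 0.4, 1, 5)
  ses$staq_activated <-
    rnorm_clamped(n_ses, 3.0 + staq_shift("activated"), 0.4, 1, 5)
  ses$staq_inactivated <-
    rnorm_clamped(n_ses, 2.5 + staq_shift("inactivated"), 0.4, 1, 5)

  sc <- schedule[schedule$role == "scenario",
                 c("participant", "session", "segment",
                   "phone", "drowsy", "town", "snowy")]
  rownames(sc) <- NULL
  n_sc <- nrow(sc)
  set.seed(seeds$session[min(2L, length(seeds$session))])
  subj_int <- stats::rnorm(np, 0, 8)[sc$participant]
  ph <- effects$phone; tw <- effects$town; sn <- effects$snowy
  shift <- list(
    mental   = sc$phone * ph$tlx_all + sc$snowy * sn$tlx_mental,
    physical = sc$phone * ph$tlx_all + sc$snowy * sn$tlx_minor,
    temporal = sc$phone * ph$tlx_all + sc$town * tw$tlx_temporal +
      sc$snowy * sn$tlx_minor,
    performance = sc$phone * ph$tlx_all + sc$drowsy * dr$tlx_performance +
      sc$snowy * sn$tlx_minor,
    effort   = sc$phone * ph$tlx_all + sc$snowy * sn$tlx_minor,
    frustration = sc$phone * ph$tlx_all + sc$drowsy * dr$tlx_frustration
  )
  for (nm in names(shift))
    sc[[paste0("tlx_", nm)]] <-
      round(rnorm_clamped(n_sc, 40 + subj_int + shift[[nm]], 12, 0, 100), 1)
  sub_cols <- paste0("tlx_", names(shift))
  sc$tlx_overall <- round(rnorm_clamped(
    n_sc, rowMeans(sc[, sub_cols]), 4, 0, 100), 1)

  structure(list(participants = participants, sessions = ses, tlx = sc),
            class = "hds_questionnaires")
}
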