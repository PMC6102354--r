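characteristics_feature_names <- function() {
  c("age", "gender", "dominant_hand", "driving_experience", "height",
    "weight", "ipip_extraversion", "ipip_neuroticism", "ipip_agreeableness",
    "ipip_openness", "ipip_conscientiousness", "pss10",
    "staq_negative_affect", "staq_positive_affect", "staq_activated",
    "staq_inactivated", "bmi", "glasses", "session_start_hour",
    "session_ordinal")
}

#' Encode the 20 driver-characteristics features for one session
#'
#' Six demographics (age, gender coded 0/1, dominant hand coded 0/1,
#' driving experience in years, height, weight), the five IPIP personality
#' traits, the PSS-10 stress score, the four per-session STAQ mood scores,
#' and four derived extras: body-mass index, a glasses-worn flag, the
#' session start hour and the session ordinal.  The vector is constant
#' across all scenarios of the session by construction.
#'
#' @param questionnaires an `hds_questionnaires` object (or a list with
#'   compatible `participants` and `sessions` data frames).
#' @param participant,session session address.
#' @return Named numeric vector of length 20.
#' @export
encode_characteristics <- function(questionnaires, participant, session) {
  pq <- questionnaires$participants
  sq <- questionnaires$sessions
  prow <- pq[pq$participant == participant, ]
  srow <- sq[sq$participant == participant & sq$session == session, ]
  if (nrow(prow) != 1L)
    stop("no questionnaire record for participant ", participant,
         call. = FALSE)
  if (nrow(srow) != 1L)
    stop("no session questionnaire record for participant ", participant,
         ", session ", session, call. = FALSE)
  out <- c(
    age = prow$age, gender = prow$gender, dominant_hand = prow$dominant_hand,
    driving_experience = prow$driving_experience, height = prow$height,
    weight = prow$weight,
    ipip_extraversion = prow$ipip_extraversion,
    ipip_neuroticism = prow$ipip_neuroticism,
    ipip_agreeableness = prow$ipip_agreeableness,
    ipip_openness = prow$ipip_openness,
    ipip_conscientiousness = prow$ipip_conscientiousness,
    pss10 = prow$pss10,
    staq_negative_affect = srow$staq_negative_affect,
    staq_positive_affect = srow$staq_positive_affect,
    staq_activated = srow$staq_activated,
    staq_inactivated = srow$staq_inactivated,
    bmi = prow$weight / (prow$height / 100)^2,
    glasses = prow$glasses,
    session_start_hour = srow$start_hour,
    session_ordinal = session)
  out[characteristics_feature_names()]
}
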