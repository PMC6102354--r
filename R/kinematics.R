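kinematics_feature_names <- function() {
  as.vector(t(outer(kinematics_channel_names(),
                    c("mean", "std", "fluct"), paste, sep = "_")))
}

#' Extract the 24 vehicle-kinematics features of one scenario
#'
#' For each of the 8 kinematics channels (throttle, lane number, lateral
#' lane position, road offset, longitudinal velocity, vertical velocity,
#' front and rear tire slip): the mean, the standard deviation, and the
#' fluctuation, i.e. the mean absolute value of the first difference per
#' sample step.
#'
#' @param kin numeric matrix with the 8 named channels as columns.
#' @return Named numeric vector of length 24, ordered channel-major as
#'   `<channel>_mean`, `<channel>_std`, `<channel>_fluct`.
#' @export
kinematics_features <- function(kin) {
  chans <- kinematics_channel_names()
  missing <- setdiff(chans, colnames(kin))
  if (length(missing))
    stop("missing kinematics channel(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  out <- numeric(0)
  for (ch in chans) {
    v <- kin[, ch]
    out <- c(out, mean(v), stats::sd(v),
             if (length(v) > 1L) mean(abs(diff(v))) else 0)
  }
  names(out) <- kinematics_feature_names()
  out
}
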