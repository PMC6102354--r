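# Min-max scale a vector to [0, 1]; a degenerate (constant) vector maps to
# 0.5 with a warning naming the feature.
minmax_scale <- function(v, feature = "feature") {
  ok <- is.finite(v)
  if (!any(ok)) return(v)
  rng <- range(v[ok])
  if (diff(rng) == 0) {
    warning("degenerate range for '", feature, "': all values set to 0.5",
            call. = FALSE)
    v[ok] <- 0.5
    return(v)
  }
  (v - rng[1]) / diff(rng)
}

#' Session normalization of physiological features
#'
#' The paper-style two-step rule for one session: the session's baseline
#' value of the feature is subtracted from each scenario value, then the
#' result is min-max scaled with the session's own minimum and maximum
#' (scenarios only), so every output lies in \[0, 1\] with the session
#' minimum at 0 and maximum at 1.  The whole pipeline is invariant to
#' adding a constant to all raw values.
#'
#' @param values scenario feature values of one session.
#' @param baseline the session's baseline value of the feature.
#' @param feature feature name, used in degenerate-range warnings.
#' @return Normalized values in \[0, 1\] (0.5 everywhere if the session range
#'   is degenerate).
#' @export
normalize_physio <- function(values, baseline, feature = "feature") {
  minmax_scale(values - baseline, feature)
}

#' Session normalization of kinematics features
#'
#' Same min-max scaling as [normalize_physio()] but without a baseline
#' subtraction step (no baseline exists for vehicle kinematics).
#'
#' @param values scenario feature values of one session.
#' @param feature feature name for warnings.
#' @return Normalized values in \[0, 1\].
#' @export
normalize_kinematics <- function(values, feature = "feature") {
  minmax_scale(values, feature)
}

#' Normalize a full feature table
#'
#' Applies the session-wise normalization to every physiological feature
#' (baseline subtraction, then min-max within session) and every
#' kinematics feature (min-max within session), one session at a time so
#' no session ever reads another session's data.  Driver-characteristics
#' features are session-constant and are z-scored across the whole table
#' instead (configurable).
#'
#' @param features feature table from [extract_features()], including the
#'   baseline rows.
#' @param characteristics how to scale the characteristics block:
#'   `"zscore"` (default) or `"none"`.
#' @return The scenario rows of the table with all 61 features normalized;
#'   baseline rows are consumed by the physiological step and dropped.
#' @export
normalize_features <- function(features, characteristics = c("zscore", "none")) {
  characteristics <- match.arg(characteristics)
  fs <- feature_sets()
  sc <- features[features$role == "scenario", , drop = FALSE]
  if (nrow(sc) == 0L) return(sc)
  bl <- features[features$role == "baseline", , drop = FALSE]
  key <- interaction(sc$participant, sc$session, drop = TRUE)
  for (f in fs$physio) {
    out <- sc[[f]]
    for (k in levels(key)) {
      idx <- which(key == k)
      brow <- bl[bl$participant == sc$participant[idx[1]] &
                   bl$session == sc$session[idx[1]], f]
      b <- if (length(brow) && is.finite(brow[1])) brow[1] else 0
      out[idx] <- normalize_physio(sc[[f]][idx], b, feature = f)
    }
    sc[[f]] <- out
  }
  for (f in fs$kinematics) {
    out <- sc[[f]]
    for (k in levels(key)) {
      idx <- which(key == k)
      out[idx] <- normalize_kinematics(sc[[f]][idx], feature = f)
    }
    sc[[f]] <- out
  }
  if (characteristics == "zscore") {
    for (f in fs$characteristics) {
      v <- sc[[f]]
      s <- stats::sd(v, na.rm = TRUE)
      sc[[f]] <- if (is.finite(s) && s > 0) (v - mean(v, na.rm = TRUE)) / s
                 else 0
    }
  }
  attr(sc, "normalized") <- TRUE
  sc
}
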