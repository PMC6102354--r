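#' Impute missing feature values with the session median
#'
#' Features flagged missing on some epochs (e.g. amplitude statistics when
#' a scenario contains no skin-conductance response) are replaced by the
#' median of the same feature within the same session; if a whole session
#' is missing, the table-wide median; if the feature is missing everywhere,
#' 0.5 (the centre of the normalized scale).
#'
#' @param x numeric feature matrix.
#' @param session session key, one entry per row (participant x session).
#' @return Matrix with no missing values.
#' @export
impute_session_median <- function(x, session) {
  x <- as.matrix(x)
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    if (!anyNA(v)) next
    med <- stats::ave(v, session, FUN = function(z)
      stats::median(z, na.rm = TRUE))
    v[is.na(v)] <- med[is.na(v)]
    if (anyNA(v)) v[is.na(v)] <- stats::median(v, na.rm = TRUE)
    if (anyNA(v)) v[is.na(v)] <- 0.5
    x[, j] <- v
  }
  x
}

# Cross-validated accuracy for a list of specs, sharing the per-fold
# feature selection.  `folds` is a list of held-out row index vectors.
# selection = "inside": stepwise selection refit on each training fold;
# "outside": one selection on the full data (the optimistic variant);
# "none": use all columns.
cv_accuracy <- function(x, y, specs, folds, selection = "inside",
                        p_enter = 0.05, p_fallback = 0.1) {
  x <- as.matrix(x); y <- as.integer(y)
  if (selection == "outside") {
    sel_full <- stepwise_select(x, y, p_enter, p_fallback)$index
  }
  correct <- matrix(0, nrow = length(specs), ncol = length(folds))
  n_test <- vapply(folds, length, integer(1))
  for (f in seq_along(folds)) {
    test <- folds[[f]]
    train <- setdiff(seq_len(nrow(x)), test)
    cols <- switch(selection,
                   inside = stepwise_select(x[train, , drop = FALSE], y[train],
                                            p_enter, p_fallback)$index,
                   outside = sel_full,
                   none = seq_len(ncol(x)))
    for (s in seq_along(specs)) {
      pred <- if (length(cols) == 0L) {
        # an empty model carries no label information; the convention
        # assigns the positive class (the same neutral rule as an output
        # of exactly 0.5).  Predicting the training majority instead is
        # systematically anti-correlated with the held-out sample under
        # leave-one-out with balanced classes.
        rep(1L, length(test))
      } else {
        fit_predict(specs[[s]], x[train, cols, drop = FALSE], y[train],
                    x[test, cols, drop = FALSE])
      }
      correct[s, f] <- sum(pred == y[test])
    }
  }
  rowSums(correct) / sum(n_test)
}

#' Leave-one-out cross-validated accuracy
#'
#' One fold per sample (or per group when `groups` is given, e.g. one fold
#' per participant for leave-one-subject-out).  By default the stepwise
#' feature selection is refit inside every training fold, so no selection
#' information leaks from the held-out sample; `selection = "outside"`
#' reproduces the optimistic variant that selects once on the full data,
#' and `"none"` disables selection.
#'
#' @param spec an `hds_classifier_spec`.
#' @param x numeric feature matrix (normalized, no missing values).
#' @param y binary labels.
#' @param groups optional grouping vector; folds hold out whole groups.
#' @param selection `"inside"` (default), `"outside"` or `"none"`.
#' @param p_enter,p_fallback stepwise thresholds.
#' @return Accuracy in \[0, 1\]: the fraction of held-out samples predicted
#'   correctly over all folds.
#' @export
loocv <- function(spec, x, y, groups = NULL,
                  selection = c("inside", "outside", "none"),
                  p_enter = 0.05, p_fallback = 0.1) {
  selection <- match.arg(selection)
  x <- as.matrix(x)
  if (nrow(x) < 10L) stop("need at least 10 samples", call. = FALSE)
  folds <- if (is.null(groups)) as.list(seq_len(nrow(x)))
           else unname(split(seq_len(nrow(x)), groups))
  cv_accuracy(x, y, list(spec), folds, selection, p_enter, p_fallback)[1]
}
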