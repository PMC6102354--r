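#' The four causes of hazardous driver state
#'
#' @return Character vector: `phone`, `drowsy`, `town`, `snowy`.
#' @export
hds_causes <- function() c("phone", "drowsy", "town", "snowy")

#' All non-empty combinations of the three feature sets
#'
#' @return Named list of 7 character vectors drawn from `physio`,
#'   `characteristics`, `kinematics`.
#' @export
feature_set_combinations <- function() {
  sets <- c("physio", "characteristics", "kinematics")
  combos <- list()
  for (k in 1:3)
    combos <- c(combos, utils::combn(sets, k, simplify = FALSE))
  names(combos) <- vapply(combos, paste, "", collapse = "+")
  combos
}

# TRUE for columns that vary within at least one session.
session_varying <- function(x, session) {
  apply(x, 2, function(v) {
    any(tapply(v, session, function(z) length(unique(z)) > 1L))
  })
}

#' Run the full classification experiment matrix
#'
#' For every cause of hazardous driver state (phone, drowsy, town, snowy)
#' and every non-empty combination of the three feature sets (physiology,
#' driver characteristics, vehicle kinematics): impute missing values to
#' the session median, run the stepwise selection, cross-validate every
#' classifier in the menu (sharing the per-fold selection across
#' classifiers), and keep the best classifier per cell.  Under the
#' `"augmented"` scheme the true presence/absence bits of the other three
#' causes are appended to the candidate features before selection.
#' Characteristics-only cells are reported as not classifiable when the
#' selection returns no feature that varies within sessions while the
#' label does (the characteristics block is session-constant, so such
#' causes cannot be predicted from it).
#'
#' @param features normalized scenario feature table from
#'   [normalize_features()].
#' @param scheme `"independent"` (default) or `"augmented"`.
#' @param menu named list of `hds_classifier_spec`s (default the full
#'   study menu).
#' @param cv `"loo"` (leave-one-sample-out, default) or `"loso"`
#'   (leave-one-participant-out).
#' @param selection stepwise selection mode for cross-validation:
#'   `"inside"` every training fold (default) or `"outside"` once on the
#'   full data.
#' @param causes subset of causes to run (default all four).
#' @param combos subset of feature-set combinations (default all 7).
#' @param p_enter,p_fallback stepwise thresholds.
#' @return An object of class `hds_run_results`: a list of per-cell
#'   results, each with the cause, the feature sets, the scheme, the
#'   cross-validated accuracy of the best classifier (NA when not
#'   classifiable), the per-classifier accuracies, the best spec and the
#'   full-data selection path with entry p-values.
#' @export
run_matrix <- function(features, scheme = c("independent", "augmented"),
                       menu = default_classifier_menu(),
                       cv = c("loo", "loso"),
                       selection = c("inside", "outside"),
                       causes = hds_causes(),
                       combos = feature_set_combinations(),
                       p_enter = 0.05, p_fallback = 0.1) {
  scheme <- match.arg(scheme)
  cv <- match.arg(cv)
  selection <- match.arg(selection)
  fs <- feature_sets()
  session <- interaction(features$participant, features$session, drop = TRUE)
  folds <- if (cv == "loo") as.list(seq_len(nrow(features)))
           else unname(split(seq_len(nrow(features)), features$participant))
  results <- list()
  for (cause in causes) {
    y <- features[[cause]]
    others <- setdiff(hds_causes(), cause)
    for (ci in seq_along(combos)) {
      combo <- combos[[ci]]
      cols <- unlist(fs[combo], use.names = FALSE)
      x <- impute_session_median(as.matrix(features[, cols]), session)
      if (scheme == "augmented") {
        ind <- as.matrix(features[, others])
        colnames(ind) <- paste0("has_", others)
        x <- cbind(x, ind)
      }
      sel <- stepwise_select(x, y, p_enter, p_fallback, force_entry = TRUE)
      label_varies <- any(session_varying(matrix(y), session))
      classifiable <- TRUE
      if (label_varies) {
        sv <- session_varying(x, session)
        if (nrow(sel) == 0L || !any(sv[sel$index])) classifiable <- FALSE
      }
      cell <- list(cause = cause, feature_sets = combo,
                   combo = names(combos)[ci], scheme = scheme,
                   selected_features = sel, classifiable = classifiable,
                   accuracy = NA_real_, accuracies = NULL, best_spec = NULL)
      if (classifiable) {
        acc <- cv_accuracy(x, y, menu, folds, selection, p_enter, p_fallback)
        names(acc) <- names(menu)
        best <- which.max(acc)
        cell$accuracy <- acc[[best]]
        cell$accuracies <- acc
        cell$best_spec <- menu[[best]]
      }
      results[[paste(cause, names(combos)[ci], sep = ".")]] <- cell
    }
  }
  structure(list(cells = results, scheme = scheme, cv = cv,
                 selection = selection),
            class = "hds_run_results")
}

#' @export
print.hds_run_results <- function(x, ...) {
  cat("Classification run (", x$scheme, " scheme, ", x$cv,
      " cross-validation, selection ", x$selection, "): ",
      length(x$cells), " cells\n", sep = "")
  print(accuracy_table(x))
  invisible(x)
}

#' Accuracy table of a classification run
#'
#' @param results an `hds_run_results`.
#' @return Data frame with one row per feature-set combination and one
#'   column per cause; entries are best-classifier accuracies in percent,
#'   `NA` for not-classifiable cells.
#' @export
accuracy_table <- function(results) {
  stopifnot(inherits(results, "hds_run_results"))
  cells <- results$cells
  combos <- unique(vapply(cells, `[[`, "", "combo"))
  causes <- unique(vapply(cells, `[[`, "", "cause"))
  out <- matrix(NA_real_, length(combos), length(causes),
                dimnames = list(combos, causes))
  for (cell in cells)
    out[cell$combo, cell$cause] <- round(100 * cell$accuracy, 1)
  as.data.frame(out)
}

#' Format a p-value the way the study tables print it
#'
#' @param p numeric p-values.
#' @return Character vector: `"<0.001"` below that threshold, otherwise
#'   three decimals.
#' @export
format_pvalue <- function(p) {
  ifelse(p < 0.001, "<0.001", sprintf("%.3f", p))
}

#' Summarise a classification run: best classifier and best features
#'
#' For each cause, using the requested feature-set combination (default
#' all three sets): the best cross-validated accuracy, the winning
#' classifier, and the first three selected features with their stepwise
#' entry p-values.
#'
#' @param results an `hds_run_results`.
#' @param combo which feature-set combination to summarise (default
#'   `"physio+characteristics+kinematics"`).
#' @return Data frame with columns `cause`, `accuracy_pct`,
#'   `best_classifier`, `feature`, `p_value` (three rows per cause).
#' @export
report_best <- function(results, combo = "physio+characteristics+kinematics") {
  stopifnot(inherits(results, "hds_run_results"))
  rows <- list()
  for (cell in results$cells) {
    if (cell$combo != combo) next
    sel <- utils::head(cell$selected_features, 3)
    if (nrow(sel) == 0L)
      sel <- data.frame(feature = NA_character_, p_value = NA_real_)
    rows[[cell$cause]] <- data.frame(
      cause = cell$cause,
      accuracy_pct = round(100 * cell$accuracy, 1),
      best_classifier = if (is.null(cell$best_spec)) NA_character_
                        else cell$best_spec$label,
      feature = sel$feature,
      p_value = format_pvalue(sel$p_value),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write the human-readable and CSV report of a run
#'
#' Writes `accuracy_table.csv` (combinations x causes), `best_features.csv`
#' (per-cause best classifier and top-3 features) and a plain-text
#' `report.txt` into `dir`.  Empty result sets produce empty files and
#' return normally.
#'
#' @param results an `hds_run_results`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(results, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  at <- accuracy_table(results)
  utils::write.csv(at, file.path(dir, "accuracy_table.csv"))
  bt <- report_best(results)
  utils::write.csv(bt, file.path(dir, "best_features.csv"), row.names = FALSE)
  txt <- c(sprintf("Classification report (%s scheme, %s CV)",
                   results$scheme, results$cv),
           "", "Accuracy (%) by feature-set combination and cause:",
           utils::capture.output(print(at)), "",
           "Best classifier and features (all three sets):",
           utils::capture.output(print(bt)))
  writeLines(txt, file.path(dir, "report.txt"))
  invisible(dir)
}
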