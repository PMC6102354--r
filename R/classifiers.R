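#' Specify one classifier from the study menu
#'
#' The menu spans support vector machines with linear, quadratic or
#' medium-Gaussian kernels, logistic regression, decision trees of three
#' complexity levels, and an adaptively reweighted (boosted) ensemble of
#' depth-limited trees.
#'
#' @param family `"svm"`, `"logistic"`, `"tree"` or `"boosted_tree"`.
#' @param kernel SVM kernel: `"linear"`, `"quadratic"` or
#'   `"gaussian_medium"` (kernel scale `sqrt(p)` for `p` features); only
#'   valid (and required) for `family = "svm"`.
#' @param complexity tree complexity `"simple"`, `"medium"` or `"complex"`
#'   (maximum 4, 20 or 100 splits); only valid for the tree families
#'   (default `"medium"` for `"tree"`, `"simple"` for `"boosted_tree"`).
#' @param cost SVM regularization constant (default 1).
#' @param n_trees ensemble size for `"boosted_tree"` (default 30).
#' @return An object of class `hds_classifier_spec`.
#' @export
classifier_spec <- function(family = c("svm", "logistic", "tree", "boosted_tree"),
                            kernel = NULL, complexity = NULL,
                            cost = 1, n_trees = 30L) {
  family <- match.arg(family)
  if (family == "svm") {
    if (is.null(kernel)) stop("'kernel' is required for SVM", call. = FALSE)
    kernel <- match.arg(kernel, c("linear", "quadratic", "gaussian_medium"))
    if (!is.null(complexity))
      stop("'complexity' applies only to tree families", call. = FALSE)
  } else {
    if (!is.null(kernel))
      stop("'kernel' applies only to SVM", call. = FALSE)
    if (family %in% c("tree", "boosted_tree")) {
      if (is.null(complexity))
        complexity <- if (family == "tree") "medium" else "simple"
      complexity <- match.arg(complexity, c("simple", "medium", "complex"))
    } else if (!is.null(complexity)) {
      stop("'complexity' applies only to tree families", call. = FALSE)
    }
  }
  label <- switch(family,
                  svm = paste0("SVM (", sub("_", " ", kernel), ")"),
                  logistic = "LR",
                  tree = paste0("DT (", complexity, ")"),
                  boosted_tree = "Ensemble boosted DT")
  structure(list(family = family, kernel = kernel, complexity = complexity,
                 cost = cost, n_trees = as.integer(n_trees), label = label),
            class = "hds_classifier_spec")
}

#' @export
print.hds_classifier_spec <- function(x, ...) {
  cat("Classifier:", x$label, "\n")
  invisible(x)
}

#' The full classifier menu of the study
#'
#' @return Named list of `hds_classifier_spec` objects: three SVM kernels,
#'   logistic regression, three decision-tree complexities and the boosted
#'   tree ensemble.
#' @export
default_classifier_menu <- function() {
  list(svm_linear = classifier_spec("svm", kernel = "linear"),
       svm_quadratic = classifier_spec("svm", kernel = "quadratic"),
       svm_gaussian = classifier_spec("svm", kernel = "gaussian_medium"),
       logistic = classifier_spec("logistic"),
       tree_simple = classifier_spec("tree", complexity = "simple"),
       tree_medium = classifier_spec("tree", complexity = "medium"),
       tree_complex = classifier_spec("tree", complexity = "complex"),
       boosted_tree = classifier_spec("boosted_tree"))
}

max_splits_for <- function(complexity) {
  switch(complexity, simple = 4L, medium = 20L, complex = 100L)
}

# Grow a classification tree and prune it back to at most `max_splits`
# splits using the complexity-pruning path.
fit_pruned_tree <- function(df, max_splits, weights = NULL) {
  ctrl <- rpart::rpart.control(cp = 0, minsplit = 8, minbucket = 4,
                               xval = 0, maxcompete = 0, maxsurrogate = 0)
  fit <- rpart::rpart(y ~ ., data = df, method = "class", weights = weights,
                      control = ctrl)
  cpt <- fit$cptable
  ok <- cpt[, "nsplit"] <= max_splits
  if (!all(ok)) {
    row <- max(which(ok))
    cp_cut <- if (row < nrow(cpt))
      sqrt(cpt[row, "CP"] * cpt[row + 1L, "CP"]) else cpt[row, "CP"]
    fit <- rpart::prune(fit, cp = cp_cut)
  }
  fit
}

# AdaBoost.M1 over depth-limited classification trees; deterministic.
fit_adaboost <- function(x, y, n_trees, maxdepth = 3L) {
  n <- nrow(x)
  df <- data.frame(x)
  df$y <- factor(y, levels = c(0, 1))
  w <- rep(1 / n, n)
  trees <- list(); alphas <- numeric(0)
  ctrl <- rpart::rpart.control(cp = 0, minsplit = 8, minbucket = 4,
                               maxdepth = maxdepth, xval = 0,
                               maxcompete = 0, maxsurrogate = 0)
  for (m in seq_len(n_trees)) {
    fit <- rpart::rpart(y ~ ., data = df, weights = w, method = "class",
                        control = ctrl)
    pred <- as.integer(as.character(stats::predict(fit, df, type = "class")))
    err <- sum(w * (pred != y)) / sum(w)
    if (err <= 0) { trees <- c(trees, list(fit)); alphas <- c(alphas, 6); break }
    if (err >= 0.5) {
      if (!length(trees)) { trees <- list(fit); alphas <- 1e-6 }
      break
    }
    alpha <- 0.5 * log((1 - err) / err)
    trees <- c(trees, list(fit)); alphas <- c(alphas, alpha)
    w <- w * exp(alpha * ifelse(pred != y, 1, -1))
    w <- w / sum(w)
  }
  list(trees = trees, alphas = alphas)
}

predict_adaboost <- function(model, x) {
  df <- data.frame(x)
  score <- rep(0, nrow(df))
  for (i in seq_along(model$trees)) {
    p <- as.integer(as.character(
      stats::predict(model$trees[[i]], df, type = "class")))
    score <- score + model$alphas[i] * (2 * p - 1)
  }
  as.integer(score >= 0)          # tie -> positive class
}

#' Train one classifier and predict test labels
#'
#' Deterministic given the spec and the data (the boosted ensemble uses
#' reweighting, not resampling).  Logistic regression assigns the positive
#' class when the model output is at or above 0.5 (an output of exactly
#' 0.5 goes to the positive class).  Training sets containing a single
#' class predict that class everywhere.
#'
#' @param spec an `hds_classifier_spec`.
#' @param x_train,y_train training features (matrix, selected columns only)
#'   and binary labels.
#' @param x_test feature matrix to predict.
#' @return Integer vector of predicted 0/1 labels, one per test row.
#' @export
fit_predict <- function(spec, x_train, y_train, x_test) {
  if (!inherits(spec, "hds_classifier_spec"))
    stop("unknown classifier spec", call. = FALSE)
  x_train <- as.matrix(x_train); x_test <- as.matrix(x_test)
  y_train <- as.integer(y_train)
  if (length(unique(y_train)) < 2L)
    return(rep(y_train[1], nrow(x_test)))
  p <- ncol(x_train)
  if (spec$family == "svm") {
    args <- switch(spec$kernel,
                   linear = list(kernel = "linear"),
                   quadratic = list(kernel = "polynomial", degree = 2,
                                    gamma = 1, coef0 = 1),
                   gaussian_medium = list(kernel = "radial", gamma = 1 / p))
    fit <- do.call(e1071::svm,
                   c(list(x = x_train, y = factor(y_train, levels = c(0, 1)),
                          cost = spec$cost, scale = FALSE), args))
    return(as.integer(as.character(stats::predict(fit, x_test))))
  }
  if (spec$family == "logistic") {
    fit <- suppressWarnings(
      stats::glm.fit(cbind(1, x_train), y_train,
                     family = stats::binomial()))
    co <- fit$coefficients
    co[is.na(co)] <- 0                    # aliased columns contribute nothing
    eta <- cbind(1, x_test) %*% co
    prob <- 1 / (1 + exp(-eta))
    return(as.integer(prob >= 0.5))
  }
  colnames(x_train) <- paste0("f", seq_len(p))
  colnames(x_test) <- paste0("f", seq_len(p))
  if (spec$family == "tree") {
    df <- data.frame(x_train)
    df$y <- factor(y_train, levels = c(0, 1))
    fit <- fit_pruned_tree(df, max_splits_for(spec$complexity))
    return(as.integer(as.character(
      stats::predict(fit, data.frame(x_test), type = "class"))))
  }
  model <- fit_adaboost(x_train, y_train, spec$n_trees)
  predict_adaboost(model, x_test)
}
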