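#' Stepwise forward feature selection by partial F-test
#'
#' Greedy forward entry on nested linear models of the binary outcome: at
#' each step the candidate whose partial F-test (for adding it to the
#' current model) has the smallest p-value enters, provided that p-value is
#' below `p_enter`; selection stops when no candidate qualifies.  If the
#' very first step admits nothing at `p_enter`, the whole selection is
#' rerun at the relaxed threshold `p_fallback`.  Exact p-value ties are
#' broken in favour of the lower column index.
#'
#' The partial F for adding one column is computed from the partial
#' correlation of the response and the candidate after projecting out the
#' current model, which is algebraically identical to the nested-model
#' F-test but lets all candidates be scored with two matrix products per
#' step.
#'
#' @param x numeric feature matrix (columns named); should be normalized
#'   and free of missing values.
#' @param y binary outcome (0/1 or logical).
#' @param p_enter entry threshold (default 0.05).
#' @param p_fallback relaxed threshold used when the first step selects
#'   nothing (default 0.1).
#' @param force_entry if `TRUE`, a selection that is still empty after the
#'   fallback admits the single best candidate regardless of its p-value,
#'   guaranteeing a non-empty feature set (used by the cross-validation
#'   layer, which always needs a predictor); default `FALSE`.
#' @return Data frame with columns `feature`, `index` and `p_value` in
#'   entry order (zero rows if nothing qualifies even at `p_fallback`,
#'   unless `force_entry`).
#' @export
stepwise_select <- function(x, y, p_enter = 0.05, p_fallback = 0.1,
                            force_entry = FALSE) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (length(unique(y)) < 2L) stop("single-class labels", call. = FALSE)
  if (anyNA(x)) stop("'x' must not contain missing values", call. = FALSE)
  n <- nrow(x)
  run <- function(alpha, force = FALSE) {
    sel <- integer(0); pv <- numeric(0)
    repeat {
      p_model <- length(sel) + 1L           # intercept + selected
      df2 <- n - p_model - 1L
      if (df2 < 1L) break
      qr_cur <- qr(cbind(1, x[, sel, drop = FALSE]))
      ry <- qr.resid(qr_cur, y)
      cand <- setdiff(seq_len(ncol(x)), sel)
      if (!length(cand)) break
      rx <- qr.resid(qr_cur, x[, cand, drop = FALSE])
      ss_x <- colSums(rx^2)
      ss_y <- sum(ry^2)
      num <- as.vector(crossprod(rx, ry))
      r2 <- ifelse(ss_x > 1e-12 * n & ss_y > 0,
                   pmin(1, num^2 / (ss_x * ss_y)), 0)
      Fst <- r2 * df2 / pmax(1 - r2, 1e-300)
      pval <- stats::pf(Fst, 1, df2, lower.tail = FALSE)
      pval[ss_x <= 1e-12 * n] <- 1
      best <- which(pval == min(pval))[1L]
      if (pval[best] >= alpha && !(force && !length(sel))) break
      sel <- c(sel, cand[best])
      pv <- c(pv, pval[best])
      if (pval[best] >= alpha) break      # forced single entry only
    }
    list(sel = sel, pv = pv)
  }
  res <- run(p_enter)
  if (!length(res$sel)) res <- run(p_fallback, force = force_entry)
  nm <- colnames(x)
  if (is.null(nm)) nm <- paste0("x", seq_len(ncol(x)))
  data.frame(feature = nm[res$sel], index = res$sel, p_value = res$pv,
             stringsAsFactors = FALSE)
}
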