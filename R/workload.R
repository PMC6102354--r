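#' Within-subject main effect of one cause on one workload outcome
#'
#' Repeated-measures main-effect test for a two-level within-subject
#' factor: each participant's outcome is averaged within each factor level
#' (collapsing scenarios, and sessions where the factor is
#' session-constant), and the main-effect F with (1, n-1) degrees of
#' freedom is computed; for a two-level within factor this F is exactly
#' the square of the paired t statistic on the per-participant level
#' means, and the two-sided p-value is reported.
#'
#' @param tlx data frame with one row per scenario: `participant`, the
#'   binary factor column, and the outcome column.
#' @param factor_name name of the binary factor column (e.g. `"phone"`).
#' @param outcome name of the outcome column (e.g. `"tlx_mental"`).
#' @return List with `F`, `p`, `df` (c(1, n-1)) and `n` (complete
#'   participants).  Participants missing a factor level are excluded with
#'   a warning; fewer than 3 complete participants is an error.
#' @export
rm_main_effect <- function(tlx, factor_name, outcome) {
  if (!all(c("participant", factor_name, outcome) %in% names(tlx)))
    stop("'tlx' must contain 'participant', '", factor_name, "' and '",
         outcome, "'", call. = FALSE)
  f <- tlx[[factor_name]]
  m0 <- tapply(tlx[[outcome]][f == 0], tlx$participant[f == 0], mean)
  m1 <- tapply(tlx[[outcome]][f == 1], tlx$participant[f == 1], mean)
  ids <- intersect(names(m0)[!is.na(m0)], names(m1)[!is.na(m1)])
  all_ids <- unique(as.character(tlx$participant))
  dropped <- setdiff(all_ids, ids)
  if (length(dropped))
    warning("excluding participant(s) missing a factor level: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  n <- length(ids)
  if (n < 3L)
    stop("fewer than 3 participants with both factor levels", call. = FALSE)
  d <- m1[ids] - m0[ids]
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    if (mean(d) == 0) return(list(F = 0, p = 1, df = c(1, n - 1L), n = n))
    return(list(F = Inf, p = 0, df = c(1, n - 1L), n = n))
  }
  tstat <- mean(d) / (sd_d / sqrt(n))
  Fstat <- tstat^2
  p <- stats::pf(Fstat, 1, n - 1L, lower.tail = FALSE)
  list(F = Fstat, p = p, df = c(1, n - 1L), n = n)
}

#' Workload-validation table: every cause against every NASA-TLX outcome
#'
#' Runs [rm_main_effect()] for each of the four causes on the six TLX
#' subscales and the overall score, mirroring the study's
#' workload-validation layout (7 outcomes x 4 factors of significance
#' levels).
#'
#' @param tlx the per-scenario TLX data frame (e.g.
#'   `study$questionnaires$tlx`).
#' @param digits rounding for the p-values (default 3).
#' @return Data frame of p-values, one row per outcome, one column per
#'   cause.
#' @export
tlx_effect_table <- function(tlx, digits = 3) {
  outcomes <- c("tlx_mental", "tlx_physical", "tlx_temporal",
                "tlx_performance", "tlx_effort", "tlx_frustration",
                "tlx_overall")
  causes <- hds_causes()
  out <- matrix(NA_real_, length(outcomes), length(causes),
                dimnames = list(outcomes, causes))
  for (oc in outcomes)
    for (cz in causes)
      out[oc, cz] <- round(rm_main_effect(tlx, cz, oc)$p, digits)
  as.data.frame(out)
}
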