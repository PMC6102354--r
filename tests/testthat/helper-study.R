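# Small study configurations used across tests; durations are kept short so
# the suite runs quickly, which only shortens epochs (counts and structure
# are unchanged).
tiny_design <- function(n_participants = 2, dur = 30, seed = 1) {
  study_design(n_participants = n_participants, scenario_duration = dur,
               baseline_duration = dur, seed = seed)
}

tiny_study <- function(n_participants = 2, dur = 30, seed = 1,
                       effects = effect_config()) {
  simulate_study(tiny_design(n_participants, dur, seed), effects)
}

# Memoised expensive fixtures (built once per test run).
.fixture_env <- new.env(parent = emptyenv())
fixture <- function(key, builder) {
  if (!exists(key, envir = .fixture_env)) assign(key, builder(), .fixture_env)
  get(key, envir = .fixture_env)
}

# Brute-force stepwise oracle: nested linear models compared with anova().
stepwise_oracle <- function(x, y, alpha) {
  sel <- integer(0); pv <- numeric(0)
  repeat {
    cand <- setdiff(seq_len(ncol(x)), sel)
    if (!length(cand)) break
    ps <- vapply(cand, function(j) {
      d0 <- data.frame(y = y, x[, sel, drop = FALSE])
      d1 <- data.frame(y = y, x[, c(sel, j), drop = FALSE])
      stats::anova(stats::lm(y ~ ., d0), stats::lm(y ~ ., d1))$`Pr(>F)`[2]
    }, numeric(1))
    if (min(ps) >= alpha) break
    sel <- c(sel, cand[which.min(ps)])
    pv <- c(pv, min(ps))
  }
  list(sel = sel, pv = pv)
}

# Band power of an unevenly sampled series by direct periodogram on a
# resampled grid (independent of the package's spectrum code path).
oracle_band_power <- function(times, values, lo, hi, fs = 4) {
  grid <- seq(min(times), max(times), by = 1 / fs)
  y <- stats::approx(times, values, xout = grid)$y
  y <- y - mean(y)
  sp <- stats::spec.pgram(stats::ts(y, frequency = fs), plot = FALSE,
                          detrend = TRUE, taper = 0)
  sum(sp$spec[sp$freq >= lo & sp$freq <= hi])
}
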