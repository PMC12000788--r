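# Shared in-code fixtures. Small cohorts are cached per session so several
# test files can reuse one simulation.

.fixture_env <- new.env(parent = emptyenv())

tiny_cohort <- function(n = 6L, seed = 303L, minutes = FALSE) {
  key <- paste0("cohort_", n, "_", seed, "_", minutes)
  if (is.null(.fixture_env[[key]])) {
    tabs <- c("participants", "sleep_periods", "morning_survey",
              "evening_survey", "advice")
    if (minutes) tabs <- c(tabs, "minutes")
    .fixture_env[[key]] <- simulate_cohort(
      cohort_config(n_participants = n), seed = seed, tables = tabs)
  }
  .fixture_env[[key]]
}

tiny_daily <- function(n = 6L, seed = 303L, minutes = FALSE) {
  key <- paste0("daily_", n, "_", seed, "_", minutes)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- daily_features(tiny_cohort(n, seed, minutes))
  .fixture_env[[key]]
}

ts_utc <- function(x) as.POSIXct(x, tz = "UTC")

# A planted binary-classification problem with one driving feature.
planted_problem <- function(n = 240L, p = 12L, driver = 3L, seed = 99L,
                            strength = 2.2, prevalence_shift = -1.6) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  colnames(x) <- paste0("f", seq_len(p))
  y <- rbinom(n, 1L, plogis(strength * x[, driver] + prevalence_shift))
  list(x = x, y = y, driver = colnames(x)[driver])
}
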