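# Shared fixtures: small simulated cohorts, cached per test session.

.cohort_cache <- new.env(parent = emptyenv())

quiet_cohort <- function(config) {
  suppressWarnings(simulate_cohort(config))
}

# Filtered cohort of moderate size, cached by (n, seed, alpha signature).
test_cohort <- function(n = 250, seed = 101, alpha = default_alpha(),
                        othercause = 0.002, censoring = 0.003) {
  key <- paste0("c", n, "_", seed, "_",
                paste(round(alpha, 4), collapse = "_"), "_",
                othercause, "_", censoring)
  if (!is.null(.cohort_cache[[key]])) return(.cohort_cache[[key]])
  cfg <- sim_config(
    n_subjects = n, seed = seed, censoring_rate = censoring,
    survival_params = survival_params(alpha = alpha,
                                      othercause_hazard = othercause))
  co <- quiet_cohort(cfg)
  flt <- suppressMessages(apply_inclusion_filter(co$subjects, co$series))
  out <- list(subjects = flt$subjects, series = flt$series,
              truth = co$truth, raw = co)
  .cohort_cache[[key]] <- out
  out
}

# Full trial-sized cohort at defaults (cached; used by several files).
test_full_cohort <- function() {
  if (is.null(.cohort_cache$full))
    .cohort_cache$full <- quiet_cohort(sim_config(seed = 7))
  .cohort_cache$full
}

# Hand-built toy series for filter/schedule tests.
toy_series <- function(id, times, marker = "Hb", value = 13) {
  data.frame(id = id, marker = marker, time_months = times, value = value)
}
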