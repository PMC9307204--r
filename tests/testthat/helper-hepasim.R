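# Shared helpers: reduced-scale configurations and summary shortcuts.

quick_cfg <- function(system = "vculture", compound = "vC1", fu = 1,
                      dose = 2000L, n_ts = 500L, n_mc = 1L, seed = 1L, ...) {
  experiment_config(system, compound, fu, dose_total = dose, n_ts = n_ts,
                    n_mc = n_mc, base_seed = seed, ...)
}

# mean of a per-execution entry-rate summary over the MC replicates
entry_stat <- function(res, mode, scope = "all") {
  mean(vapply(res$records, function(r) {
    smooth_and_summarize(series_extract(r, "entry_rate", scope), mode = mode)
  }, numeric(1)))
}

# binomial three-standard-error band check
expect_binomial <- function(successes, trials, p, label = "frequency") {
  se <- sqrt(p * (1 - p) / trials)
  expect_lt(abs(successes / trials - p), 3 * se + 1e-12, label = label)
}
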