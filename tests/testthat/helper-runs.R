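# Shared scaled-down scenario runs: built once per test session, reused by the
# summary/cutoff tests.  n_sim = 50 trials per subscenario, fixed master seed.
run_cache <- new.env(parent = emptyenv())

cached_run <- function(name, builder) {
  if (is.null(run_cache[[name]])) run_cache[[name]] <- builder()
  run_cache[[name]]
}

scaled_run <- function(scenario, n_sim = 50, seed = 20240509, ...) {
  cached_run(paste(scenario, n_sim, seed, sep = "_"), function() {
    run_scenario(build_design_grid(scenario_spec(scenario, ...)),
                 n_sim = n_sim, seed = seed)
  })
}

significant_pool <- function(replicates) {
  replicates[replicates$status == "significant", ]
}

# one small calibrated design for cheap single-trial tests
toy_design <- function(design_hr = 0.5, med_c = 12, power = 0.8) {
  cached_run(paste("design", design_hr, med_c, power, sep = "_"), function() {
    g <- build_design_grid(scenario_spec("standard", design_hr = design_hr,
                                         med_c = med_c, power = power))
    as.list(g[1, ])
  })
}

# patient-level tibble from explicit vectors (both-arm toy trials)
toy_trial <- function(time_c, event_c, time_t, event_t) {
  tibble::tibble(
    arm = factor(rep(c("control", "treatment"),
                     c(length(time_c), length(time_t))),
                 levels = c("control", "treatment")),
    time = c(time_c, time_t),
    event = as.logical(c(event_c, event_t)))
}
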