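# Shared cache of reduced-scale assembly runs (300 events, seeds 1..5 per
# scenario family).  The trend and stability checks all draw on the same
# runs, so each is computed once per test session.

.run_cache <- new.env(parent = emptyenv())

reduced_run <- function(preset_name, seed, n_events = 300) {
  key <- paste(preset_name, seed, n_events, sep = "|")
  if (!exists(key, envir = .run_cache)) {
    pre <- scenario_preset(preset_name, n_events = n_events, seed = seed,
                           params = glv_params(t_max = 5000))
    assign(key, run_assembly(pre$config), envir = .run_cache)
  }
  get(key, envir = .run_cache)
}

reduced_family <- function(preset_name, seeds = 1:5, n_events = 300) {
  lapply(seeds, function(s) reduced_run(preset_name, s, n_events))
}

family_glance <- function(runs) {
  dplyr::bind_rows(lapply(runs, glance))
}
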