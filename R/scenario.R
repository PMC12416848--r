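#' Named scenario presets
#'
#' The scenario families studied by the simulator, each mapped to an
#' [assembly_config()] with the reference defaults: half-normal interaction
#' strengths with `sigma = 0.2`, cost `delta = 0.01`, mutation budget
#' `delta_mut = 5`, handling times `0.1`, extinction threshold `1e-6`,
#' invader connection probability uniform on `[0.05, 0.5]`, 5 founders, 1000
#' events, 15 replicates, metrics aggregated every 50 events.
#'
#' Available presets: `"Evo"`, `"Inv"`, `"Evo-No-M"`, `"Inv-No-M"`,
#' `"Inv-High-M"`, `"Inv-switch-on"`, `"Inv-switch-off"`, `"Mixed-0.2"`,
#' `"Mixed-0.5"`, `"Mixed-0.8"` (the number is the invasion share),
#' `"Evo-abundance-weighted"` and `"fast-assembly"` (assembly every
#' `fixed_interval` time units, before equilibrium is reached).
#'
#' @param name Preset name.
#' @param n_events,n_replicates,record_every Scale of the runs; defaults are
#'   the full reference scale.
#' @param seed Master seed; per-replicate seeds are spawned from it.
#' @param ... Overrides forwarded to [assembly_config()] (e.g. `sigma`,
#'   `delta_mut`, `fixed_interval`, `params`).
#' @return A list of class `scenario_preset` with elements `name`, `config`,
#'   `n_replicates`, `record_every`.
#' @export
scenario_preset <- function(name, n_events = 1000, n_replicates = 15,
                            record_every = 50, seed = 1, ...) {
  base <- switch(name,
    "Evo" = list(scenario = "evolution", mutualism = "free"),
    "Inv" = list(scenario = "invasion", mutualism = "free"),
    "Evo-No-M" = list(scenario = "evolution", mutualism = "none"),
    "Inv-No-M" = list(scenario = "invasion", mutualism = "none"),
    "Inv-High-M" = list(scenario = "invasion", mutualism = "high"),
    "Inv-switch-on" = list(scenario = "invasion", mutualism = "switch_on"),
    "Inv-switch-off" = list(scenario = "invasion", mutualism = "switch_off"),
    "Mixed-0.2" = list(scenario = "mixed", p_invasion = 0.2),
    "Mixed-0.5" = list(scenario = "mixed", p_invasion = 0.5),
    "Mixed-0.8" = list(scenario = "mixed", p_invasion = 0.8),
    "Evo-abundance-weighted" = list(scenario = "evolution",
                                    parent_weighting = "abundance"),
    "fast-assembly" = list(scenario = "evolution",
                           event_timing = "fixed_interval"),
    stop("unknown preset: ", name))
  args <- utils::modifyList(c(base, list(n_events = n_events, seed = seed)),
                            list(...))
  structure(list(name = name,
                 config = do.call(assembly_config, args),
                 n_replicates = as.integer(n_replicates),
                 record_every = as.integer(record_every)),
            class = "scenario_preset")
}

#' Spawn per-replicate seeds from a master seed
#'
#' Fixed rule: seed R's RNG with the master seed and draw `n` integers
#' without replacement from `1..1e8`.
#'
#' @param master_seed Integer master seed.
#' @param n Number of replicate seeds.
#' @return Integer vector of length `n`.
#' @export
spawn_seeds <- function(master_seed, n) {
  set.seed(master_seed)
  sample.int(1e8L, n)
}

#' Run a scenario across replicates
#'
#' Runs [run_assembly()] once per replicate seed and aggregates the
#' trajectories at every `record_every` events: mean and standard error
#' (sd / sqrt(n)) of each metric across replicates.
#'
#' @param preset A [scenario_preset()].
#' @param n_replicates Number of replicates (defaults to the preset's).
#' @param seeds Explicit replicate seeds (defaults to
#'   [spawn_seeds()] from the preset config's seed).
#' @return An object of class `scenario_result`: list with `name`, `runs`
#'   (list of `assembly_run`), `trajectories` (tibble with a `replicate`
#'   column), `aggregate` (tibble of per-stride means and SEs), `errors`
#'   (per-replicate error messages, if any) and `preset`.
#' @export
run_scenario <- function(preset, n_replicates = preset$n_replicates,
                         seeds = spawn_seeds(preset$config$seed,
                                             n_replicates)) {
  stopifnot(inherits(preset, "scenario_preset"),
            length(seeds) == n_replicates)
  runs <- vector("list", n_replicates)
  errors <- character(0)
  for (i in seq_len(n_replicates)) {
    cfg <- preset$config
    cfg$seed <- as.integer(seeds[i])
    runs[[i]] <- tryCatch(run_assembly(cfg), error = function(e) {
      warning(sprintf("replicate %d failed: %s", i, conditionMessage(e)))
      e
    })
    if (inherits(runs[[i]], "error"))
      errors <- c(errors, sprintf("replicate %d: %s", i,
                                  conditionMessage(runs[[i]])))
  }
  ok <- !vapply(runs, inherits, logical(1), "error")
  trajectories <- dplyr::bind_rows(lapply(which(ok), function(i) {
    dplyr::mutate(runs[[i]]$trajectory, replicate = i, seed = seeds[i])
  }))
  aggregate <- aggregate_trajectories(trajectories, preset$record_every)
  structure(list(name = preset$name, runs = runs[ok],
                 trajectories = trajectories, aggregate = aggregate,
                 errors = errors, preset = preset),
            class = "scenario_result")
}

#' Aggregate replicate trajectories at a fixed event stride
#'
#' @param trajectories Tibble of per-event records with a `replicate` column.
#' @param record_every Event stride at which to evaluate.
#' @return A long tibble: `event`, `metric`, `mean`, `se`, `n`.
#' @export
aggregate_trajectories <- function(trajectories, record_every = 50) {
  metrics <- c("S", "C", "SC", "prop_comp", "prop_cons", "prop_mut",
               "mean_abundance")
  trajectories |>
    dplyr::filter(.data$event %% record_every == 0) |>
    tidyr::pivot_longer(dplyr::all_of(metrics), names_to = "metric",
                        values_to = "value") |>
    dplyr::group_by(.data$event, .data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value),
      se = if (dplyr::n() > 1) stats::sd(.data$value) / sqrt(dplyr::n())
           else 0,
      n = dplyr::n(),
      .groups = "drop")
}

#' Final-state richness/connectance table
#'
#' One row per replicate with the final richness and connectance, supporting
#' the comparison of outcome diversity across scenarios and the sign of the
#' richness-connectance association.
#'
#' @param results A `scenario_result` or a list of them.
#' @return A tibble with columns `scenario`, `replicate`, `S`, `C`.
#' @export
final_state_scatter <- function(results) {
  if (inherits(results, "scenario_result")) results <- list(results)
  purrr::map_dfr(results, function(res) {
    purrr::imap_dfr(res$runs, function(run, i) {
      tibble::tibble(scenario = res$name, replicate = i,
                     S = n_species(run$community),
                     C = connectance(run$community))
    })
  })
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> %s: %d replicate(s), %d events each\n",
              x$name, length(x$runs), x$preset$config$n_events))
  if (length(x$errors)) cat("  failed:", length(x$errors), "replicate(s)\n")
  invisible(x)
}

#' @export
print.scenario_preset <- function(x, ...) {
  cat(sprintf("<scenario_preset> %s (%s, mutualism %s): %d events x %d replicates\n",
              x$name, x$config$scenario, x$config$mutualism,
              x$config$n_events, x$n_replicates))
  invisible(x)
}
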