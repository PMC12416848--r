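#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an assembly run into its per-event trajectory
#' @param x An `assembly_run`.
#' @param ... Unused.
#' @return The trajectory tibble, one row per assembly event.
#' @export
tidy.assembly_run <- function(x, ...) x$trajectory

#' One-row summary of an assembly run's final state
#' @param x An `assembly_run`.
#' @param ... Unused.
#' @return A one-row tibble: scenario, seed, events performed, final
#'   richness, connectance, complexity, type proportions, mean abundance.
#' @export
glance.assembly_run <- function(x, ...) {
  co <- x$community
  tp <- type_proportions(co)
  tibble::tibble(scenario = x$config$scenario,
                 mutualism = x$config$mutualism,
                 seed = x$config$seed,
                 n_events = x$config$n_events,
                 S = n_species(co),
                 C = connectance(co),
                 SC = n_species(co) * connectance(co),
                 prop_comp = tp[["prop_comp"]],
                 prop_cons = tp[["prop_cons"]],
                 prop_mut = tp[["prop_mut"]],
                 mean_abundance = if (n_species(co) > 0) mean(co$x) else 0)
}

#' Plot the trajectory of an assembly run
#' @param object An `assembly_run`.
#' @param metrics Metric columns to facet (default richness, connectance,
#'   complexity, mutualism proportion).
#' @param ... Unused.
#' @return A faceted ggplot of metric against assembly event.
#' @export
autoplot.assembly_run <- function(object,
                                  metrics = c("S", "C", "SC", "prop_mut"),
                                  ...) {
  df <- tidyr::pivot_longer(object$trajectory, dplyr::all_of(metrics),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$event, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "assembly event", y = NULL) +
    ggplot2::theme_minimal()
}

#' Tidy a scenario result into its aggregate trajectory
#' @param x A `scenario_result`.
#' @param ... Unused.
#' @return The aggregate tibble: per-stride per-metric mean, se and n.
#' @export
tidy.scenario_result <- function(x, ...) x$aggregate

#' One-row-per-replicate summary of a scenario result
#' @param x A `scenario_result`.
#' @param ... Unused.
#' @return A tibble of final-state summaries across replicates.
#' @export
glance.scenario_result <- function(x, ...) {
  dplyr::mutate(dplyr::bind_rows(lapply(x$runs, glance.assembly_run)),
                scenario = x$name, replicate = dplyr::row_number())
}

#' Plot mean trajectories with standard errors for a scenario
#' @param object A `scenario_result`.
#' @param metrics Metrics to facet.
#' @param ... Unused.
#' @return A faceted ggplot of per-stride means with SE error bars.
#' @export
autoplot.scenario_result <- function(object,
                                     metrics = c("S", "C", "SC", "prop_mut"),
                                     ...) {
  df <- dplyr::filter(object$aggregate, .data$metric %in% metrics)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$event, y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$se,
                                          ymax = .data$mean + .data$se),
                             size = 0.2) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "assembly event", y = NULL,
                  title = object$name) +
    ggplot2::theme_minimal()
}
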