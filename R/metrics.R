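#' Undirected typed pair graph of a community
#'
#' One unweighted edge per interacting unordered species pair, labelled with
#' the pair's unique interaction type (`competition`, `consumer_resource` or
#' `mutualism`).  Consumer/resource direction is ignored; only the presence
#' of links matters for the network metrics.
#'
#' @param community A `glv_community`.
#' @return An `igraph` graph with vertex attribute `name` (species ids) and
#'   edge attribute `type`.
#' @export
community_graph <- function(community) {
  net <- community$net
  S <- n_species(community)
  comp <- net$c > 0
  mut <- net$m > 0
  cons <- net$pplus > 0 | t(net$pminus) > 0
  cons <- cons | t(cons)
  if (any((comp & mut) | (comp & cons) | (mut & cons)))
    stop("pair with inconsistent interaction-type evidence")
  adj <- comp | mut | cons
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$name <- community$species_ids
  el <- igraph::as_edgelist(g, names = FALSE)
  if (nrow(el) > 0) {
    type <- character(nrow(el))
    for (k in seq_len(nrow(el))) {
      i <- el[k, 1]; j <- el[k, 2]
      type[k] <- if (comp[i, j]) "competition"
                 else if (mut[i, j]) "mutualism"
                 else "consumer_resource"
    }
    igraph::E(g)$type <- type
  }
  g
}

as_pair_graph <- function(x) {
  if (inherits(x, "glv_community")) community_graph(x)
  else if (inherits(x, "igraph")) x
  else stop("expected a glv_community or an igraph graph")
}

#' Connectance of a community or graph
#'
#' Fraction of realized unordered species pairs: `L / (S (S - 1) / 2)`.
#' Defined as 0 for fewer than two species.
#'
#' @param x A `glv_community` or an `igraph` graph.
#' @return A number in `[0, 1]`.
#' @export
connectance <- function(x) {
  g <- as_pair_graph(x)
  S <- igraph::vcount(g)
  if (S < 2) return(0)
  igraph::ecount(g) / (S * (S - 1) / 2)
}

#' Degree entropy of a community or graph
#'
#' Shannon entropy (natural log) of the empirical degree distribution of the
#' unweighted pair graph: `H = -sum_k P(k) ln P(k)` with `0 ln 0 := 0`.
#' Degenerate (k-regular, including edgeless) graphs have entropy 0.
#'
#' @param x A `glv_community` or an `igraph` graph.
#' @return Entropy in nats.
#' @export
degree_entropy <- function(x) {
  g <- as_pair_graph(x)
  if (igraph::vcount(g) == 0) stop("degree entropy of an empty graph")
  p <- tabulate(igraph::degree(g) + 1L) / igraph::vcount(g)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Modularity via seeded Louvain optimization
#'
#' Maximizes `Mod = sum_c (L_c / m - eps (k_c / 2m)^2)` over node partitions
#' with the Louvain greedy algorithm; the best of `n_restarts` restarts is
#' reported to stabilize the estimate.  The Louvain heuristic consumes R's
#' RNG stream, so results are deterministic under a fixed seed.
#'
#' @param x A `glv_community` or an `igraph` graph with at least one edge.
#' @param resolution Resolution parameter `eps` (default 1).
#' @param n_restarts Louvain restarts (default 5).
#' @return The maximized modularity.
#' @export
graph_modularity <- function(x, resolution = 1, n_restarts = 5) {
  g <- as_pair_graph(x)
  if (igraph::ecount(g) == 0) stop("modularity of an edgeless graph")
  best <- -Inf
  for (k in seq_len(n_restarts)) {
    cl <- igraph::cluster_louvain(g, resolution = resolution)
    mod <- igraph::modularity(g, igraph::membership(cl),
                              resolution = resolution)
    if (mod > best) best <- mod
  }
  best
}

#' Effective increase of a metric over Erdős–Rényi baselines
#'
#' The metric on the observed graph minus its mean over `n_random`
#' Erdős–Rényi `G(S, p = C)` graphs with the same size and connectance.
#' Random draws on which the metric is undefined (e.g. edgeless graphs for
#' modularity) are skipped.
#'
#' @param x A `glv_community` or an `igraph` graph with at least 2 nodes.
#' @param metric_fn Function from graph to number (e.g. [degree_entropy()],
#'   [graph_modularity()]).
#' @param n_random Number of random baseline graphs (default 50).
#' @return `metric_fn(x)` minus the baseline mean.
#' @export
effective_increase <- function(x, metric_fn, n_random = 50) {
  g <- as_pair_graph(x)
  S <- igraph::vcount(g)
  if (S < 2) stop("effective increase needs at least 2 species")
  p <- connectance(g)
  vals <- rep(NA_real_, n_random)
  for (k in seq_len(n_random)) {
    gr <- igraph::sample_gnp(S, p)
    vals[k] <- tryCatch(metric_fn(gr), error = function(e) NA_real_)
  }
  if (all(is.na(vals)))
    stop("metric undefined on every random baseline graph")
  metric_fn(g) - mean(vals, na.rm = TRUE)
}

#' Interaction-type proportions
#'
#' Counts interacting unordered pairs by type and normalizes by the total;
#' all zero for an edgeless community.
#'
#' @param x A `glv_community` or a typed pair graph.
#' @return Named numeric vector `(prop_comp, prop_cons, prop_mut)`.
#' @export
type_proportions <- function(x) {
  g <- as_pair_graph(x)
  L <- igraph::ecount(g)
  if (L == 0)
    return(c(prop_comp = 0, prop_cons = 0, prop_mut = 0))
  type <- igraph::E(g)$type
  c(prop_comp = sum(type == "competition") / L,
    prop_cons = sum(type == "consumer_resource") / L,
    prop_mut = sum(type == "mutualism") / L)
}

#' Full metric report for a community
#'
#' Richness, connectance, complexity, type proportions, mean abundance,
#' degree entropy and Louvain modularity, optionally with their effective
#' increases over Erdős–Rényi baselines.
#'
#' @param community A `glv_community`.
#' @param baselines Also compute `degree_entropy_increase` and
#'   `modularity_increase` (default `TRUE`).
#' @param n_random Baseline sample size (default 50).
#' @return A one-row tibble.
#' @export
community_metrics <- function(community, baselines = TRUE, n_random = 50) {
  g <- community_graph(community)
  S <- n_species(community)
  base <- tibble::as_tibble(as.list(trajectory_metrics(community)))
  base$degree_entropy <- if (S > 0) degree_entropy(g) else NA_real_
  base$modularity <- if (igraph::ecount(g) > 0) graph_modularity(g)
                     else NA_real_
  if (baselines && S >= 2 && igraph::ecount(g) > 0) {
    base$degree_entropy_increase <-
      effective_increase(g, degree_entropy, n_random)
    base$modularity_increase <-
      effective_increase(g, graph_modularity, n_random)
  } else {
    base$degree_entropy_increase <- NA_real_
    base$modularity_increase <- NA_real_
  }
  base
}
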