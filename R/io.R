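#' Write a community snapshot to JSON
#'
#' Serializes abundances, ids, traits, the four interaction matrices, the
#' speciation genealogy and the event counter; [read_community_json()]
#' restores an identical community.
#'
#' @param community A `glv_community`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_community_json <- function(community, path) {
  payload <- list(
    species_ids = community$species_ids,
    x = community$x,
    r = community$traits$r,
    s = community$traits$s,
    c = community$net$c,
    pplus = community$net$pplus,
    pminus = community$net$pminus,
    m = community$net$m,
    parent_of = as.list(community$parent_of),
    event_index = community$event_index
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a community snapshot from JSON
#' @param path File written by [write_community_json()].
#' @return A validated `glv_community`.
#' @export
read_community_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  S <- length(p$x)
  as_mat <- function(m) {
    m <- matrix(as.numeric(unlist(m)), nrow = S, byrow = FALSE)
    m
  }
  parent_of <- unlist(p$parent_of)
  if (is.null(parent_of)) parent_of <- stats::setNames(character(0),
                                                       character(0))
  community(x = p$x, r = p$r, s = p$s,
            c = as_mat(p$c), pplus = as_mat(p$pplus),
            pminus = as_mat(p$pminus), m = as_mat(p$m),
            species_ids = p$species_ids, parent_of = parent_of,
            event_index = p$event_index)
}

#' Write a community as a typed edge list (CSV)
#'
#' One row per interacting unordered pair with columns `source_id`,
#' `target_id`, `type`, `weight_ij` (effect of target on source) and
#' `weight_ji`.  For consumer-resource pairs the source is the consumer, so
#' `weight_ij` is the consumer's gain and `weight_ji` the resource's loss.
#'
#' @param community A `glv_community`.
#' @param path Output CSV path.
#' @return The edge-list tibble, invisibly.
#' @export
write_community_edgelist <- function(community, path) {
  g <- community_graph(community)
  el <- igraph::as_edgelist(g, names = FALSE)
  ids <- community$species_ids
  net <- community$net
  rows <- lapply(seq_len(nrow(el)), function(k) {
    i <- el[k, 1]; j <- el[k, 2]
    type <- igraph::E(g)$type[k]
    if (type == "consumer_resource" && net$pplus[j, i] > 0) {
      tmp <- i; i <- j; j <- tmp    # source is the consumer
    }
    w_ij <- switch(type, competition = net$c[i, j],
                   mutualism = net$m[i, j],
                   consumer_resource = net$pplus[i, j])
    w_ji <- switch(type, competition = net$c[j, i],
                   mutualism = net$m[j, i],
                   consumer_resource = net$pminus[j, i])
    tibble::tibble(source_id = ids[i], target_id = ids[j], type = type,
                   weight_ij = w_ij, weight_ji = w_ji)
  })
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(source_id = character(0), target_id = character(0),
                   type = character(0), weight_ij = numeric(0),
                   weight_ji = numeric(0))
  readr::write_csv(out, path)
  invisible(out)
}

#' Export the typed pair graph as GraphML
#' @param community A `glv_community`.
#' @param path Output `.graphml` path.
#' @return `path`, invisibly.
#' @export
write_community_graphml <- function(community, path) {
  g <- community_graph(community)
  igraph::V(g)$abundance <- community$x
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write a per-event trajectory to CSV
#' @param run An `assembly_run` (or its trajectory tibble).
#' @param path Output CSV path.
#' @return The trajectory tibble, invisibly.
#' @export
write_trajectory_csv <- function(run, path) {
  tr <- if (inherits(run, "assembly_run")) run$trajectory else
    tibble::as_tibble(run)
  readr::write_csv(tr, path)
  invisible(tr)
}

#' Write an eigenspectrum as (re, im) CSV rows
#' @param spectrum An [eigenspectrum()].
#' @param path Output CSV path.
#' @return The tidied tibble, invisibly.
#' @export
write_eigenspectrum_csv <- function(spectrum, path) {
  df <- tidy.eigenspectrum(spectrum)
  readr::write_csv(df, path)
  invisible(df)
}
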