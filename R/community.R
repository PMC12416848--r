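#' Construct a community object
#'
#' A community bundles the abundance vector, species identities, per-species
#' traits (intrinsic growth `r`, intraspecific competition `s`) and the four
#' interaction matrices: `c` (competition), `pplus` (benefit to the consumer),
#' `pminus` (loss to the resource) and `m` (mutualism).  All matrices are
#' non-negative with zero diagonals; entry `[i, j]` is the effect of species
#' `j` on species `i`.
#'
#' Structural invariants enforced by [validate_community()]:
#' * consumer-resource pairing: `pplus[i, j] > 0` iff `pminus[j, i] > 0`;
#' * consumer bound: `pplus[i, j] <= pminus[j, i]` (conversion efficiency
#'   at most 1);
#' * support symmetry of `m` and `c`;
#' * at most one interaction type per unordered species pair.
#'
#' @param x Numeric vector of abundances (length S).
#' @param r,s Numeric trait vectors (length S); `s` must be positive.
#' @param c,pplus,pminus,m S x S interaction matrices (default all-zero).
#' @param species_ids Character vector of stable lineage labels.
#' @param parent_of Named character vector mapping offspring id to parent id.
#' @param event_index Number of successful assembly events so far.
#' @param validate Check invariants on construction (default `TRUE`).
#' @return An object of class `glv_community`.
#' @seealso [make_community()] for an edge-list constructor,
#'   [validate_community()], [remove_species()].
#' @export
#' @examples
#' co <- community(x = c(0.1, 0.1), r = c(0.1, 0.1), s = c(1, 1),
#'                 m = matrix(c(0, 0.2, 0.2, 0), 2))
#' co
community <- function(x, r, s,
                      c = zero_mat(length(x)),
                      pplus = zero_mat(length(x)),
                      pminus = zero_mat(length(x)),
                      m = zero_mat(length(x)),
                      species_ids = paste0("sp", seq_along(x)),
                      parent_of = stats::setNames(character(0), character(0)),
                      event_index = 0L,
                      validate = TRUE) {
  S <- length(x)
  if (length(r) == 1) r <- rep(r, S)
  if (length(s) == 1) s <- rep(s, S)
  obj <- structure(
    list(
      x = as.numeric(x),
      species_ids = as.character(species_ids),
      traits = list(r = as.numeric(r), s = as.numeric(s)),
      net = list(c = unname(as.matrix(c)), pplus = unname(as.matrix(pplus)),
                 pminus = unname(as.matrix(pminus)), m = unname(as.matrix(m))),
      parent_of = parent_of,
      event_index = as.integer(event_index)
    ),
    class = "glv_community"
  )
  if (validate) validate_community(obj)
  obj
}

zero_mat <- function(n) matrix(0, n, n)

#' Number of species in a community
#' @param community A `glv_community`.
#' @return Integer richness S.
#' @export
n_species <- function(community) length(community$x)

#' Validate the structural invariants of a community
#'
#' Checks dimensions, non-negativity, zero diagonals, consumer-resource
#' pairing and bound, support symmetry of competition and mutualism, and
#' exclusivity (one interaction type per unordered pair).
#'
#' @param community A `glv_community`.
#' @return The community, invisibly; errors with a descriptive message on the
#'   first violated invariant.
#' @export
validate_community <- function(community) {
  S <- length(community$x)
  net <- community$net
  tr <- community$traits
  if (length(community$species_ids) != S)
    stop("species_ids length does not match abundance vector")
  if (anyDuplicated(community$species_ids))
    stop("species_ids must be unique")
  if (length(tr$r) != S || length(tr$s) != S)
    stop("trait vectors must have length S")
  if (any(!is.finite(tr$r)) || any(!is.finite(tr$s)))
    stop("traits must be finite")
  if (any(tr$s <= 0))
    stop("intraspecific competition s must be positive")
  if (any(community$x < 0))
    stop("abundances must be non-negative")
  for (nm in names(net)) {
    M <- net[[nm]]
    if (!is.matrix(M) || any(dim(M) != c(S, S)))
      stop(sprintf("interaction matrix '%s' must be %d x %d", nm, S, S))
    if (any(!is.finite(M)))
      stop(sprintf("interaction matrix '%s' contains non-finite entries", nm))
    if (any(M < 0))
      stop(sprintf("interaction matrix '%s' has negative entries", nm))
    if (S > 0 && any(diag(M) != 0))
      stop(sprintf("interaction matrix '%s' must have a zero diagonal", nm))
  }
  if (S > 0) {
    if (!identical(net$pplus > 0, t(net$pminus) > 0))
      stop("consumer-resource pairing violated: pplus[i,j] > 0 iff pminus[j,i] > 0")
    if (any(net$pplus > t(net$pminus)))
      stop("consumer bound violated: pplus[i,j] must not exceed pminus[j,i]")
    if (!identical(net$m > 0, t(net$m) > 0))
      stop("mutualism support must be symmetric")
    if (!identical(net$c > 0, t(net$c) > 0))
      stop("competition support must be symmetric")
    occupied <- (net$c > 0) + (net$m > 0) + (net$pplus > 0 | t(net$pminus) > 0)
    if (any(occupied + t(occupied) > 2))
      stop("pair exclusivity violated: a species pair carries more than one interaction type")
  }
  invisible(community)
}

#' Build a community from species and link tables
#'
#' Convenience constructor used throughout the test fixtures: species are
#' given as a data frame and typed links as an edge list.  For
#' `consumer_resource` links, `from` is the consumer; `w_ft` is the benefit
#' to the consumer (`pplus[from, to]`) and `w_tf` the loss to the resource
#' (`pminus[to, from]`).  For `competition` and `mutualism`, `w_ft` is the
#' effect of `to` on `from` and `w_tf` the reverse.
#'
#' @param species Data frame with columns `id`, `r`, `s`, `x0`.
#' @param links Data frame with columns `from`, `to`,
#'   `type` (`"competition"`, `"consumer_resource"` or `"mutualism"`),
#'   `w_ft`, `w_tf`; may be `NULL` for a non-interacting community.
#' @return A validated `glv_community`; errors describe the violated
#'   invariant if the tables are inconsistent.
#' @export
#' @examples
#' sp <- data.frame(id = c("a", "b"), r = 0.1, s = 1, x0 = 0.1)
#' lk <- data.frame(from = "a", to = "b", type = "mutualism",
#'                  w_ft = 0.2, w_tf = 0.25)
#' make_community(sp, lk)
make_community <- function(species, links = NULL) {
  stopifnot(all(c("id", "r", "s", "x0") %in% names(species)))
  ids <- as.character(species$id)
  S <- length(ids)
  cmat <- zero_mat(S); pp <- zero_mat(S); pm <- zero_mat(S); mm <- zero_mat(S)
  if (!is.null(links) && nrow(links) > 0) {
    stopifnot(all(c("from", "to", "type", "w_ft", "w_tf") %in% names(links)))
    fi <- match(as.character(links$from), ids)
    ti <- match(as.character(links$to), ids)
    if (anyNA(fi) || anyNA(ti)) stop("links reference unknown species ids")
    for (k in seq_len(nrow(links))) {
      i <- fi[k]; j <- ti[k]
      if (i == j) stop("self-links are not allowed")
      switch(as.character(links$type[k]),
        competition = {
          cmat[i, j] <- links$w_ft[k]; cmat[j, i] <- links$w_tf[k]
        },
        mutualism = {
          mm[i, j] <- links$w_ft[k]; mm[j, i] <- links$w_tf[k]
        },
        consumer_resource = {
          pp[i, j] <- links$w_ft[k]; pm[j, i] <- links$w_tf[k]
        },
        stop("unknown link type: ", links$type[k])
      )
    }
  }
  community(x = species$x0, r = species$r, s = species$s,
            c = cmat, pplus = pp, pminus = pm, m = mm, species_ids = ids)
}

#' Count the beneficial positive interactions of a species
#'
#' Counts the links through which species `i` gains: partners it consumes
#' (`pplus[i, j] > 0`) and mutualistic partners (`m[i, j] > 0`).  Being
#' consumed is not counted.  The per-interaction cost term in the growth rate
#' is `delta` times this count.
#'
#' @param i Species index (1-based).
#' @param net List of interaction matrices (a community's `$net`).
#' @return Non-negative integer.
#' @export
positive_interaction_count <- function(i, net) {
  S <- nrow(net$m)
  if (!is.numeric(i) || length(i) != 1 || is.na(i) || i < 1 || i > S)
    stop("species index out of range")
  sum(net$m[i, ] > 0) + sum(net$pplus[i, ] > 0)
}

# vectorized count for all species; drives the delta-cost term
positive_interaction_counts <- function(net) {
  rowSums(net$m > 0) + rowSums(net$pplus > 0)
}

#' Remove species from a community
#'
#' Drops the given species: all four interaction matrices lose the matching
#' rows and columns, abundance and trait vectors shrink, and survivors keep
#' their identifiers.  Used for extinctions and for purging species left
#' without any interactions.
#'
#' @param community A `glv_community`.
#' @param ids Character vector of species ids to remove.
#' @return The reduced community (possibly with zero species).
#' @export
remove_species <- function(community, ids) {
  if (length(ids) == 0) return(community)
  idx <- match(ids, community$species_ids)
  if (anyNA(idx)) stop("unknown species id(s): ",
                       paste(ids[is.na(idx)], collapse = ", "))
  keep <- setdiff(seq_along(community$x), idx)
  community$x <- community$x[keep]
  community$species_ids <- community$species_ids[keep]
  community$traits$r <- community$traits$r[keep]
  community$traits$s <- community$traits$s[keep]
  community$net <- lapply(community$net, function(M) M[keep, keep, drop = FALSE])
  community
}

# ids of species with no interactions at all (zero degree in the pair graph)
disconnected_ids <- function(community) {
  net <- community$net
  deg <- rowSums(net$c > 0) + rowSums(net$m > 0) +
    rowSums(net$pplus > 0) + colSums(net$pminus > 0)
  community$species_ids[deg == 0]
}

#' @export
print.glv_community <- function(x, ...) {
  S <- n_species(x)
  cat(sprintf("<glv_community> S = %d, event_index = %d\n", S, x$event_index))
  if (S > 0) {
    tp <- type_proportions(x)
    cat(sprintf("  connectance %.3f | pairs: comp %.2f, cons %.2f, mut %.2f\n",
                connectance(x), tp[["prop_comp"]], tp[["prop_cons"]],
                tp[["prop_mut"]]))
    cat(sprintf("  mean abundance %.4g\n", mean(x$x)))
  }
  invisible(x)
}
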