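#' Assembly scenario configuration
#'
#' Full specification of an assembly simulation: how candidate species are
#' generated (speciation with inheritance, invasion with random interactions,
#' or a mixture), the interaction-strength and trait distributions, the
#' mutualism regime, and the bookkeeping rules.
#'
#' @param scenario `"evolution"`, `"invasion"` or `"mixed"`.
#' @param p_invasion Probability that a scheduled assembly event is an
#'   invasion (used when `scenario = "mixed"`).
#' @param delta_mut Mutation budget: an offspring differs from its parent by
#'   1 to `delta_mut` interactions.
#' @param rho1,rho2 Bounds of the uniform draw of an invader's connection
#'   probability.
#' @param sigma Scale of the half-normal draw of new interaction strengths.
#' @param mu_r Mean intrinsic growth rate; `r ~ Normal(mu_r, (0.1 mu_r)^2)`.
#' @param s_meanlog,s_sdlog Log-scale mean and sd of the lognormal whose
#'   inverse gives the intraspecific competition strength `s`.
#' @param mutualism Mutualism regime: `"free"` (types unconstrained),
#'   `"none"`, `"high"` (invader mutualism share uniform on \[0.8, 1\]),
#'   `"switch_on"` (none before `switch_at`, free after) or `"switch_off"`
#'   (free before, none after).
#' @param switch_at Event index at which `switch_on`/`switch_off` regimes
#'   flip (default: halfway through `n_events`).
#' @param n_events Number of successful assembly events to perform.
#' @param n_init Number of non-interacting founder species.
#' @param init_abund_hi Upper bound of the uniform founder-abundance draw.
#' @param parent_weighting `"uniform"` or `"abundance"`: how speciation
#'   parents are sampled.
#' @param event_timing `"at_equilibrium"` (assemble once the community has
#'   converged) or `"fixed_interval"` (assemble every `fixed_interval` time
#'   units regardless of convergence).
#' @param fixed_interval Time units between events for
#'   `event_timing = "fixed_interval"`.
#' @param disconnect_removal_after Event index from which species without any
#'   interactions are purged after each event.
#' @param seed RNG seed making the whole run reproducible.
#' @param max_proposals Cap on rejected candidates per event; exceeding it is
#'   an error naming the event.
#' @param params A [glv_params()] object.
#' @return A list of class `assembly_config`.
#' @export
assembly_config <- function(scenario = c("evolution", "invasion", "mixed"),
                            p_invasion = 0,
                            delta_mut = 5,
                            rho1 = 0.05, rho2 = 0.5,
                            sigma = 0.2,
                            mu_r = 0.1,
                            s_meanlog = 0.1, s_sdlog = 0.5,
                            mutualism = c("free", "none", "high",
                                          "switch_on", "switch_off"),
                            switch_at = NULL,
                            n_events = 1000,
                            n_init = 5,
                            init_abund_hi = 0.02,
                            parent_weighting = c("uniform", "abundance"),
                            event_timing = c("at_equilibrium",
                                             "fixed_interval"),
                            fixed_interval = 100,
                            disconnect_removal_after = 20,
                            seed = 1,
                            max_proposals = 10000,
                            params = glv_params()) {
  scenario <- match.arg(scenario)
  mutualism <- match.arg(mutualism)
  parent_weighting <- match.arg(parent_weighting)
  event_timing <- match.arg(event_timing)
  stopifnot(p_invasion >= 0, p_invasion <= 1, delta_mut >= 1,
            rho1 > 0, rho1 <= rho2, rho2 <= 1, sigma > 0, mu_r > 0,
            s_sdlog > 0, n_events >= 0, n_init >= 1, init_abund_hi > 0,
            fixed_interval > 0, disconnect_removal_after >= 0,
            max_proposals >= 1, inherits(params, "glv_params"))
  if (is.null(switch_at)) switch_at <- floor(n_events / 2)
  structure(list(scenario = scenario, p_invasion = p_invasion,
                 delta_mut = as.integer(delta_mut), rho1 = rho1, rho2 = rho2,
                 sigma = sigma, mu_r = mu_r,
                 s_meanlog = s_meanlog, s_sdlog = s_sdlog,
                 mutualism = mutualism, switch_at = as.integer(switch_at),
                 n_events = as.integer(n_events), n_init = as.integer(n_init),
                 init_abund_hi = init_abund_hi,
                 parent_weighting = parent_weighting,
                 event_timing = event_timing, fixed_interval = fixed_interval,
                 disconnect_removal_after =
                   as.integer(disconnect_removal_after),
                 seed = as.integer(seed),
                 max_proposals = as.integer(max_proposals),
                 params = params),
            class = "assembly_config")
}

#' Draw interaction strengths
#'
#' Strengths of newly created interactions are half-normal: `|Normal(0,
#' sigma^2)|`, so the mean is `sigma * sqrt(2/pi)`.
#'
#' @param sigma Scale (standard deviation of the underlying normal); must be
#'   positive.
#' @param n Number of draws.
#' @return Non-negative numeric vector of length `n`.
#' @export
draw_interaction_strength <- function(sigma, n = 1) {
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be positive")
  abs(stats::rnorm(n, 0, sigma))
}

#' Enforce the consumer bound on a consumer-resource link
#'
#' The benefit to the consumer may not exceed the loss to the resource
#' (biomass conversion efficiency at most 1): if the drawn consumer gain is
#' larger, it is set equal to the resource loss.
#'
#' @param pplus_ij Benefit to the consumer.
#' @param pminus_ji Loss to the resource.
#' @return The (possibly reduced) consumer gain, `min(pplus_ij, pminus_ji)`.
#' @export
enforce_consumer_bound <- function(pplus_ij, pminus_ji) {
  pmin(pplus_ij, pminus_ji)
}

#' Draw species traits
#'
#' Intrinsic growth `r ~ Normal(mu_r, (0.1 mu_r)^2)` (untruncated; a rare
#' negative draw simply fails to grow) and intraspecific competition
#' `s = 1 / L` with `L ~ LogNormal(s_meanlog, s_sdlog)`.  Traits are drawn
#' fresh for every new species and never inherited.
#'
#' @param mu_r Mean intrinsic growth rate.
#' @param s_meanlog,s_sdlog Parameters of the lognormal on the log scale.
#' @param n Number of species to draw.
#' @return A list with numeric vectors `r` and `s`.
#' @export
draw_traits <- function(mu_r = 0.1, s_meanlog = 0.1, s_sdlog = 0.5, n = 1) {
  stopifnot(mu_r > 0)
  list(r = stats::rnorm(n, mu_r, 0.1 * mu_r),
       s = 1 / stats::rlnorm(n, s_meanlog, s_sdlog))
}

# mutualism regime in force at a given (1-based) event number
effective_mutualism <- function(config, event_number) {
  switch(config$mutualism,
         free = "free", none = "none", high = "high",
         switch_on = if (event_number <= config$switch_at) "none" else "free",
         switch_off = if (event_number <= config$switch_at) "free" else "none")
}

#' Schedule assembly-event origins
#'
#' Draws, for each scheduled assembly event, whether it proceeds by
#' speciation or by invasion.  Pure scenarios are degenerate; mixed scenarios
#' flip a `p_invasion` coin once per event (all rejected proposals within an
#' event keep its origin).
#'
#' @param config An [assembly_config()].
#' @param n Number of events to schedule.
#' @return Character vector of `"speciation"` / `"invasion"`.
#' @export
draw_event_origins <- function(config, n = 1) {
  p <- switch(config$scenario, evolution = 0, invasion = 1,
              mixed = config$p_invasion)
  ifelse(stats::runif(n) < p, "invasion", "speciation")
}

# --- candidate construction ------------------------------------------------
# A candidate's links are rows (partner_id, type, w1, w2) with, from the
# candidate's viewpoint:
#   competition: w1 = c[cand, p], w2 = c[p, cand]
#   mutualism:   w1 = m[cand, p], w2 = m[p, cand]
#   consumer:    w1 = pplus[cand, p] (gain), w2 = pminus[p, cand] (their loss)
#   resource:    w1 = pminus[cand, p] (loss), w2 = pplus[p, cand] (their gain)

empty_links <- function() {
  data.frame(partner = character(0), type = character(0),
             w1 = numeric(0), w2 = numeric(0), stringsAsFactors = FALSE)
}

# extract a resident's links in candidate-link form
resident_links <- function(community, idx) {
  net <- community$net
  ids <- community$species_ids
  out <- list()
  add <- function(j, type, w1, w2)
    out[[length(out) + 1]] <<- data.frame(partner = ids[j], type = type,
                                          w1 = w1, w2 = w2,
                                          stringsAsFactors = FALSE)
  for (j in which(net$c[idx, ] > 0)) add(j, "competition",
                                         net$c[idx, j], net$c[j, idx])
  for (j in which(net$m[idx, ] > 0)) add(j, "mutualism",
                                         net$m[idx, j], net$m[j, idx])
  for (j in which(net$pplus[idx, ] > 0)) add(j, "consumer",
                                             net$pplus[idx, j],
                                             net$pminus[j, idx])
  for (j in which(net$pminus[idx, ] > 0)) add(j, "resource",
                                              net$pminus[idx, j],
                                              net$pplus[j, idx])
  if (length(out) == 0) empty_links() else do.call(rbind, out)
}

# allowed types for newly created links (candidate perspective)
allowed_link_types <- function(mut_mode) {
  types <- c("competition", "consumer", "resource")
  if (mut_mode != "none") types <- c(types, "mutualism")
  types
}

# draw weights for one newly created link of the given type
draw_link_weights <- function(type, sigma) {
  w <- draw_interaction_strength(sigma, 2)
  if (type == "consumer") w[1] <- enforce_consumer_bound(w[1], w[2])
  if (type == "resource") w[2] <- enforce_consumer_bound(w[2], w[1])
  list(w1 = w[1], w2 = w[2])
}

#' Propose an offspring species by speciation
#'
#' The offspring inherits the parent's interactions, then differs by `d`
#' links with `d` uniform on `{1, ..., delta_mut}` (restricted to feasible
#' values): a uniformly chosen feasible split of `d` into removals of
#' inherited links and creations of links to unoccupied partners.  Inherited
#' weights are perturbed by `Normal(0, (0.05 w)^2)` noise, clamped at zero,
#' with the consumer bound re-enforced.  Traits are drawn fresh.  Created
#' links connect to residents the offspring is not already linked to,
#' excluding the parent (the offspring takes over the parent's network
#' position); a lone linkless parent therefore admits no feasible mutation.
#'
#' @param community A `glv_community`.
#' @param parent_id Id of the parent species.
#' @param config An [assembly_config()].
#' @param mut_mode Mutualism regime in force (`"free"`, `"none"`, `"high"`).
#' @return A candidate list (`traits`, `links`, `origin`, `parent`), or
#'   `NULL` when no feasible mutation exists (the skip-event signal).
#' @export
propose_offspring <- function(community, parent_id, config,
                              mut_mode = "free") {
  idx <- match(parent_id, community$species_ids)
  if (is.na(idx)) stop("unknown parent id: ", parent_id)
  links <- resident_links(community, idx)
  L <- nrow(links)
  unocc <- setdiff(community$species_ids, c(parent_id, links$partner))
  U <- length(unocc)
  d_max <- min(config$delta_mut, L + U)
  if (d_max < 1) return(NULL)
  d <- sample.int(d_max, 1)
  # feasible splits (n_remove, n_create): n_remove <= L, n_create <= U
  n_rem_opts <- max(0, d - U):min(L, d)
  n_rem <- if (length(n_rem_opts) == 1) n_rem_opts else sample(n_rem_opts, 1)
  n_cre <- d - n_rem

  if (n_rem > 0)
    links <- links[-sample.int(L, n_rem), , drop = FALSE]
  if (nrow(links) > 0) {
    noise1 <- stats::rnorm(nrow(links), 0, 0.05 * links$w1)
    noise2 <- stats::rnorm(nrow(links), 0, 0.05 * links$w2)
    links$w1 <- pmax(links$w1 + noise1, 0)
    links$w2 <- pmax(links$w2 + noise2, 0)
    cons <- links$type == "consumer"
    links$w1[cons] <- enforce_consumer_bound(links$w1[cons], links$w2[cons])
    res <- links$type == "resource"
    links$w2[res] <- enforce_consumer_bound(links$w2[res], links$w1[res])
  }
  if (n_cre > 0) {
    partners <- sample(unocc, n_cre)
    types <- sample(allowed_link_types(mut_mode), n_cre, replace = TRUE)
    new_rows <- lapply(seq_len(n_cre), function(k) {
      w <- draw_link_weights(types[k], config$sigma)
      data.frame(partner = partners[k], type = types[k],
                 w1 = w$w1, w2 = w$w2, stringsAsFactors = FALSE)
    })
    links <- rbind(links, do.call(rbind, new_rows))
  }
  tr <- draw_traits(config$mu_r, config$s_meanlog, config$s_sdlog, 1)
  list(traits = tr, links = links, origin = "speciation", parent = parent_id)
}

# draw interaction-type proportions (q_comp, q_cons, q_mut) for an invader
draw_type_proportions <- function(mut_mode) {
  switch(mut_mode,
    free = {
      e <- stats::rexp(3)      # Dirichlet(1,1,1): uniform on the 2-simplex
      q <- e / sum(e)
      c(comp = q[1], cons = q[2], mut = q[3])
    },
    none = {
      u <- stats::runif(1)     # uniform on the 1-simplex
      c(comp = u, cons = 1 - u, mut = 0)
    },
    high = {
      qm <- stats::runif(1, 0.8, 1)
      c(comp = (1 - qm) / 2, cons = (1 - qm) / 2, mut = qm)
    },
    stop("unknown mutualism mode: ", mut_mode))
}

#' Propose an invading species with random interactions
#'
#' The invader's connection probability is drawn uniformly from
#' `[rho1, rho2]`; each resident becomes a partner independently with that
#' probability.  Interaction-type proportions are drawn per the mutualism
#' regime (uniform on the simplex when free), each link's type is multinomial
#' in those proportions, consumer/resource roles are assigned uniformly, and
#' weights are half-normal with the consumer bound enforced.
#'
#' @inheritParams propose_offspring
#' @return A candidate list (`traits`, `links`, `origin`); zero-link invaders
#'   are allowed.
#' @export
propose_invader <- function(community, config, mut_mode = "free") {
  rho <- stats::runif(1, config$rho1, config$rho2)
  sel <- stats::runif(n_species(community)) < rho
  links <- empty_links()
  if (any(sel)) {
    partners <- community$species_ids[sel]
    q <- draw_type_proportions(mut_mode)
    base <- sample(c("competition", "consumer_resource", "mutualism"),
                   length(partners), replace = TRUE, prob = q)
    types <- ifelse(base == "consumer_resource",
                    ifelse(stats::runif(length(partners)) < 0.5,
                           "consumer", "resource"),
                    base)
    rows <- lapply(seq_along(partners), function(k) {
      w <- draw_link_weights(types[k], config$sigma)
      data.frame(partner = partners[k], type = types[k],
                 w1 = w$w1, w2 = w$w2, stringsAsFactors = FALSE)
    })
    links <- do.call(rbind, rows)
  }
  tr <- draw_traits(config$mu_r, config$s_meanlog, config$s_sdlog, 1)
  list(traits = tr, links = links, origin = "invasion", parent = NA_character_)
}

#' Test whether a candidate species can establish
#'
#' Temporarily places the candidate at abundance `x_ext` in the resident
#' community (assumed at equilibrium) and evaluates its instantaneous
#' per-capita growth rate, including its `delta` cost and its own `s * x_ext`
#' term; establishment requires a strictly positive rate.
#'
#' @param candidate A candidate list from [propose_offspring()] or
#'   [propose_invader()].
#' @param community The resident `glv_community` at equilibrium.
#' @param params A [glv_params()] object.
#' @param resident_intake Optional precomputed `pplus %*% x` of the
#'   residents (an optimization for repeated proposals).
#' @return `TRUE` if the candidate's per-capita growth at `x_ext` is
#'   positive.
#' @export
can_establish <- function(candidate, community, params = glv_params(),
                          resident_intake = NULL) {
  x_ext <- params$x_ext
  links <- candidate$links
  g <- candidate$traits$r[1] - candidate$traits$s[1] * x_ext
  if (nrow(links) > 0) {
    if (is.null(resident_intake))
      resident_intake <- drop(community$net$pplus %*% community$x)
    idx <- match(links$partner, community$species_ids)
    if (anyNA(idx)) stop("candidate links reference unknown species")
    xp <- community$x[idx]
    n_pos <- sum(links$type %in% c("mutualism", "consumer"))
    g <- g - params$delta * n_pos
    for (k in seq_len(nrow(links))) {
      j <- idx[k]
      switch(links$type[k],
        competition = { g <- g - links$w1[k] * xp[k] },
        mutualism = NULL,     # saturated gains handled jointly below
        consumer = NULL,
        resource = {
          # loss saturated by the consumer's total intake incl. the candidate
          Dj <- 1 + params$h_p * (resident_intake[j] + links$w2[k] * x_ext)
          g <- g - links$w1[k] * xp[k] / Dj
        })
    }
    mut <- links$type == "mutualism"
    if (any(mut)) {
      Mc <- sum(links$w1[mut] * xp[mut])
      g <- g + Mc / (1 + params$h_m * Mc)
    }
    cons <- links$type == "consumer"
    if (any(cons)) {
      Ac <- sum(links$w1[cons] * xp[cons])
      g <- g + Ac / (1 + params$h_p * Ac)
    }
  }
  g > 0
}

# insert an accepted candidate at abundance x_ext; returns the new community
insert_candidate <- function(community, candidate, new_id, params) {
  S <- n_species(community)
  net <- community$net
  grow <- function(M) {
    out <- zero_mat(S + 1)
    if (S > 0) out[seq_len(S), seq_len(S)] <- M
    out
  }
  cmat <- grow(net$c); pp <- grow(net$pplus)
  pm <- grow(net$pminus); mm <- grow(net$m)
  n <- S + 1
  links <- candidate$links
  if (nrow(links) > 0) {
    idx <- match(links$partner, community$species_ids)
    for (k in seq_len(nrow(links))) {
      j <- idx[k]
      switch(links$type[k],
        competition = { cmat[n, j] <- links$w1[k]; cmat[j, n] <- links$w2[k] },
        mutualism = { mm[n, j] <- links$w1[k]; mm[j, n] <- links$w2[k] },
        consumer = { pp[n, j] <- links$w1[k]; pm[j, n] <- links$w2[k] },
        resource = { pm[n, j] <- links$w1[k]; pp[j, n] <- links$w2[k] })
    }
  }
  parent_of <- community$parent_of
  if (!is.na(candidate$parent)) parent_of[new_id] <- candidate$parent
  community(x = c(community$x, params$x_ext),
            r = c(community$traits$r, candidate$traits$r[1]),
            s = c(community$traits$s, candidate$traits$s[1]),
            c = cmat, pplus = pp, pminus = pm, m = mm,
            species_ids = c(community$species_ids, new_id),
            parent_of = parent_of,
            event_index = community$event_index,
            validate = FALSE)
}

# choose a speciation parent per the configured weighting
choose_parent <- function(community, config) {
  S <- n_species(community)
  if (config$parent_weighting == "abundance") {
    community$species_ids[sample.int(S, 1, prob = community$x)]
  } else {
    community$species_ids[sample.int(S, 1)]
  }
}

#' Perform one assembly event
#'
#' Repeatedly proposes candidate species of the event's scheduled origin
#' until one establishes (positive per-capita growth at `x_ext`) or
#' `max_proposals` is exhausted.  The accepted species is inserted at
#' `x_ext`, the community is integrated to its next equilibrium (or for a
#' fixed interval), and, once `event_index >= disconnect_removal_after`,
#' species without any interactions are purged.
#'
#' @param community A `glv_community` at its assembly baseline.
#' @param config An [assembly_config()].
#' @param origin `"speciation"` or `"invasion"`; defaults to a fresh draw
#'   from the scenario's schedule.
#' @param next_id Identifier to give the new species.
#' @return A list: `community` (updated), `record` (a one-row data frame of
#'   trajectory metrics for the event).
#' @export
assembly_event <- function(community, config,
                           origin = draw_event_origins(config, 1),
                           next_id = NULL) {
  if (n_species(community) == 0)
    stop("cannot assemble into an empty community")
  params <- config$params
  event_number <- community$event_index + 1L
  mut_mode <- effective_mutualism(config, event_number)
  if (is.null(next_id))
    next_id <- paste0("s", config$n_init + event_number)
  resident_intake <- drop(community$net$pplus %*% community$x)

  accepted <- NULL
  n_rejected <- 0L
  for (trial in seq_len(config$max_proposals)) {
    cand <- if (origin == "invasion") {
      propose_invader(community, config, mut_mode)
    } else {
      propose_offspring(community, choose_parent(community, config),
                        config, mut_mode)
    }
    if (is.null(cand)) { n_rejected <- n_rejected + 1L; next }
    if (can_establish(cand, community, params, resident_intake)) {
      accepted <- cand
      break
    }
    n_rejected <- n_rejected + 1L
  }
  if (is.null(accepted))
    stop(sprintf("max_proposals (%d) exceeded at assembly event %d",
                 config$max_proposals, event_number))

  community <- insert_candidate(community, accepted, next_id, params)
  eq <- if (config$event_timing == "fixed_interval") {
    equilibrate(community, params,
                n_windows = max(1, round(config$fixed_interval /
                                           params$t_check)))
  } else {
    equilibrate(community, params)
  }
  community <- eq$community
  community$event_index <- event_number
  if (event_number >= config$disconnect_removal_after &&
      n_species(community) > 0) {
    community <- remove_species(community, disconnected_ids(community))
  }

  rec <- cbind(
    data.frame(event = event_number, origin = accepted$origin,
               stringsAsFactors = FALSE),
    as.data.frame(as.list(trajectory_metrics(community))),
    data.frame(n_rejected = n_rejected,
               n_extinct = length(eq$extinct_ids),
               converged = isTRUE(eq$converged))
  )
  list(community = community, record = rec)
}

# fast per-event metric row (no random baselines)
trajectory_metrics <- function(community) {
  S <- n_species(community)
  C <- connectance(community)
  tp <- type_proportions(community)
  c(S = S, C = C, SC = S * C,
    prop_comp = tp[["prop_comp"]], prop_cons = tp[["prop_cons"]],
    prop_mut = tp[["prop_mut"]],
    mean_abundance = if (S > 0) mean(community$x) else 0)
}

#' Run a full assembly simulation
#'
#' Initializes `n_init` non-interacting founders with abundances uniform on
#' `[0, init_abund_hi]`, integrates to equilibrium, then performs `n_events`
#' assembly events, recording one trajectory row per event.  Fully
#' reproducible from `config$seed`.
#'
#' @param config An [assembly_config()].
#' @param quiet Suppress the non-convergence warnings (default `TRUE`).
#' @return An object of class `assembly_run`: a list with `community` (final
#'   state), `trajectory` (tibble, one row per event) and `config`.
#' @export
run_assembly <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "assembly_config"))
  params <- config$params
  set.seed(config$seed)
  tr <- draw_traits(config$mu_r, config$s_meanlog, config$s_sdlog,
                    config$n_init)
  x0 <- stats::runif(config$n_init, 0, config$init_abund_hi)
  comm <- community(x = pmax(x0, 0), r = tr$r, s = tr$s,
                    species_ids = paste0("s", seq_len(config$n_init)))
  # founders drawn below the extinction threshold never lived
  comm <- remove_species(comm, comm$species_ids[comm$x < params$x_ext])
  eq <- if (config$event_timing == "fixed_interval") {
    equilibrate(comm, params,
                n_windows = max(1, round(config$fixed_interval /
                                           params$t_check)))
  } else {
    equilibrate(comm, params)
  }
  comm <- eq$community
  if (!quiet && identical(eq$converged, FALSE))
    warning("founder community did not converge before t_max")

  records <- vector("list", config$n_events)
  n_ev <- config$n_events
  if (n_ev > 0) {
    origins <- draw_event_origins(config, n_ev)
    for (k in seq_len(n_ev)) {
      step <- assembly_event(comm, config, origin = origins[k])
      comm <- step$community
      records[[k]] <- step$record
      if (!quiet && !step$record$converged)
        warning(sprintf("event %d did not converge before t_max", k))
    }
  }
  trajectory <- if (n_ev > 0) {
    tibble::as_tibble(do.call(rbind, records))
  } else {
    tibble::tibble(event = integer(0), origin = character(0), S = numeric(0),
                   C = numeric(0), SC = numeric(0), prop_comp = numeric(0),
                   prop_cons = numeric(0), prop_mut = numeric(0),
                   mean_abundance = numeric(0), n_rejected = integer(0),
                   n_extinct = integer(0), converged = logical(0))
  }
  structure(list(community = comm, trajectory = trajectory, config = config),
            class = "assembly_run")
}

#' @export
print.assembly_run <- function(x, ...) {
  cat(sprintf("<assembly_run> %s scenario, %d events, seed %d\n",
              x$config$scenario, x$config$n_events, x$config$seed))
  print(x$community)
  invisible(x)
}
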