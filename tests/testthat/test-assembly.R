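test_that("interaction strengths are half-normal with the expected mean", {
  set.seed(501)
  w <- draw_interaction_strength(0.2, 1e5)
  expect_true(all(w >= 0))
  expect_equal(mean(w), 0.2 * sqrt(2 / pi), tolerance = 0.01)
  expect_error(draw_interaction_strength(0), "positive")
  expect_error(draw_interaction_strength(-1), "positive")
})

test_that("trait draws follow the stated distributions and are positive where required", {
  set.seed(502)
  tr <- draw_traits(n = 1e5)
  expect_equal(mean(tr$r), 0.1, tolerance = 0.02)
  expect_equal(sd(tr$r), 0.01, tolerance = 0.02)
  expect_true(all(tr$s > 0))
  # 1/s is lognormal(0.1, 0.5): mean exp(0.1 + 0.5^2/2)
  expect_equal(mean(1 / tr$s), exp(0.1 + 0.5^2 / 2), tolerance = 0.02)
})

test_that("the consumer bound clamps the gain to the resource's loss", {
  expect_equal(enforce_consumer_bound(0.3, 0.2), 0.2)
  expect_equal(enforce_consumer_bound(0.1, 0.2), 0.1)
  expect_equal(enforce_consumer_bound(0.0, 0.2), 0.0)
})

test_that("offspring differ from their parent by 1..delta_mut links", {
  set.seed(503)
  co <- random_community(8, p_link = 0.5)
  cfg <- assembly_config("evolution", n_events = 1)

  link_set <- function(links) paste(links$partner, links$type)
  for (k in 1:200) {
    parent <- sample(co$species_ids, 1)
    pidx <- match(parent, co$species_ids)
    inherited <- ecoassembly:::resident_links(co, pidx)
    cand <- propose_offspring(co, parent, cfg)
    removed <- setdiff(link_set(inherited), link_set(cand$links))
    created <- setdiff(link_set(cand$links), link_set(inherited))
    d <- length(removed) + length(created)
    expect_gte(d, 1)
    expect_lte(d, cfg$delta_mut)
    # one interaction type per pair: partners never repeat
    expect_true(all(!duplicated(cand$links$partner)))
  }

  # a mutation budget of 1 changes exactly one link
  cfg1 <- assembly_config("evolution", delta_mut = 1, n_events = 1)
  for (k in 1:50) {
    parent <- sample(co$species_ids, 1)
    pidx <- match(parent, co$species_ids)
    inherited <- ecoassembly:::resident_links(co, pidx)
    cand <- propose_offspring(co, parent, cfg1)
    d <- length(setdiff(link_set(inherited), link_set(cand$links))) +
      length(setdiff(link_set(cand$links), link_set(inherited)))
    expect_identical(d, 1L)
  }

  # a lone, linkless species has no feasible mutation: skip-event signal
  lone <- community(x = 0.1, r = 0.1, s = 1, species_ids = "a")
  expect_null(propose_offspring(lone, "a", cfg))
})

test_that("inherited weights carry multiplicative 5% noise", {
  set.seed(504)
  # parent 'a' holds one competition link of weight 0.2; third species keeps
  # the (0 removals, 1 creation) split feasible so the link is often retained
  co <- make_community(
    data.frame(id = c("a", "b", "z"), r = 0.1, s = 1, x0 = 0.1),
    data.frame(from = "a", to = "b", type = "competition",
               w_ft = 0.2, w_tf = 0.2))
  cfg <- assembly_config("evolution", delta_mut = 1, n_events = 1)
  w <- replicate(1e4, {
    cand <- propose_offspring(co, "a", cfg)
    kept <- cand$links$partner == "b" & cand$links$type == "competition" &
      abs(cand$links$w1 - 0.2) < 0.05
    if (any(kept)) cand$links$w1[kept][1] else NA_real_
  })
  expect_equal(sd(w[!is.na(w)] - 0.2), 0.05 * 0.2, tolerance = 0.05)
})

test_that("invaders obey the drawn connectance and mutualism regime", {
  set.seed(505)
  co <- random_community(10, p_link = 0.3)
  cfg <- assembly_config("invasion", n_events = 1)

  # certain assignment: rho1 = rho2 = 1 links to every resident
  cfg_full <- assembly_config("invasion", rho1 = 1, rho2 = 1, n_events = 1)
  cand <- propose_invader(co, cfg_full)
  expect_identical(sort(cand$links$partner), sort(co$species_ids))

  # no-mutualism regime never creates a mutualistic link
  muts <- replicate(300, {
    sum(propose_invader(co, cfg, mut_mode = "none")$links$type == "mutualism")
  })
  expect_true(all(muts == 0))

  # high-mutualism regime: mean mutualism share of links ~ E[U(0.8, 1)] = 0.9
  shares <- replicate(1e4, {
    l <- propose_invader(co, cfg_full, mut_mode = "high")$links
    mean(l$type == "mutualism")
  })
  expect_equal(mean(shares), 0.9, tolerance = 0.02)

  # consumer bound holds on every consumer-resource link drawn
  for (k in 1:100) {
    l <- propose_invader(co, cfg_full, mut_mode = "free")$links
    cons <- l[l$type == "consumer", ]
    expect_true(all(cons$w1 <= cons$w2))
    res <- l[l$type == "resource", ]
    expect_true(all(res$w2 <= res$w1))
  }
})

test_that("establishment requires positive per-capita growth at the threshold", {
  p <- glv_params()
  res <- community(x = 0.3, r = 0.1, s = 1, species_ids = "cons")
  tr <- list(r = 0.1, s = 1)

  # no links: grows at r - s*x_ext > 0
  free <- list(traits = tr, links = ecoassembly:::empty_links(),
               origin = "invasion", parent = NA_character_)
  expect_true(can_establish(free, res, p))

  # resource of an abundant consumer with unsaturated loss 0.5 * 0.3 > r
  p0 <- glv_params(h_p = 0)
  doomed <- list(traits = tr,
                 links = data.frame(partner = "cons", type = "resource",
                                    w1 = 0.5, w2 = 0.4,
                                    stringsAsFactors = FALSE),
                 origin = "invasion", parent = NA_character_)
  expect_false(can_establish(doomed, res, p0))

  # the flag agrees with a scalar evaluation on the augmented community
  set.seed(506)
  co <- random_community(6, p_link = 0.5)
  co$x <- pmax(co$x, 0.01)
  cfg <- assembly_config("invasion", n_events = 1)
  for (k in 1:50) {
    cand <- propose_invader(co, cfg, "free")
    aug <- ecoassembly:::insert_candidate(co, cand, "cand", p)
    g_aug <- scalar_rhs(aug$x, aug$net, aug$traits, p)
    g_cand <- g_aug[n_species(aug)] / p$x_ext
    expect_identical(can_establish(cand, co, p), g_cand > 0)
  }

  # accepted species enter at exactly the threshold abundance
  aug <- ecoassembly:::insert_candidate(co, free, "new", p)
  expect_identical(aug$x[n_species(aug)], p$x_ext)
  expect_silent(validate_community(aug))
})

test_that("the event scheduler honours the scenario's invasion probability", {
  set.seed(507)
  cfg <- assembly_config("mixed", p_invasion = 0.2, n_events = 1)
  origins <- draw_event_origins(cfg, 1e4)
  expect_equal(mean(origins == "invasion"), 0.2, tolerance = 0.1)

  cfg0 <- assembly_config("mixed", p_invasion = 0, n_events = 1)
  expect_true(all(draw_event_origins(cfg0, 1000) == "speciation"))
  cfg1 <- assembly_config("invasion", n_events = 1)
  expect_true(all(draw_event_origins(cfg1, 1000) == "invasion"))
})

test_that("a degenerate mixed scenario reproduces pure evolution exactly", {
  cfg_mix <- assembly_config("mixed", p_invasion = 0, n_events = 12, seed = 9,
                             params = glv_params(t_max = 2000))
  cfg_evo <- assembly_config("evolution", n_events = 12, seed = 9,
                             params = glv_params(t_max = 2000))
  run_mix <- run_assembly(cfg_mix)
  run_evo <- run_assembly(cfg_evo)
  expect_equal(dplyr::select(run_mix$trajectory, -"origin"),
               dplyr::select(run_evo$trajectory, -"origin"))
  expect_identical(run_mix$community$x, run_evo$community$x)
})

test_that("full runs are reproducible and keep their books in order", {
  cfg <- assembly_config("evolution", n_events = 40, seed = 21,
                         params = glv_params(t_max = 2000))
  run1 <- run_assembly(cfg)
  run2 <- run_assembly(cfg)
  expect_identical(run1$trajectory, run2$trajectory)

  tr <- run1$trajectory
  expect_identical(tr$event, 1:40)
  # richness can rise by at most the one accepted species per event
  expect_true(all(diff(tr$S) <= 1))
  expect_silent(validate_community(run1$community))
  expect_identical(run1$community$event_index, 40L)

  # an empty schedule returns the equilibrated founders
  cfg0 <- assembly_config("evolution", n_events = 0, seed = 21)
  run0 <- run_assembly(cfg0)
  expect_identical(nrow(run0$trajectory), 0L)
  expect_lte(n_species(run0$community), cfg0$n_init)
})

test_that("mutualism switch regimes gate link creation by event index", {
  cfg_on <- assembly_config("invasion", mutualism = "switch_on",
                            switch_at = 10, n_events = 20)
  expect_identical(ecoassembly:::effective_mutualism(cfg_on, 5), "none")
  expect_identical(ecoassembly:::effective_mutualism(cfg_on, 10), "none")
  expect_identical(ecoassembly:::effective_mutualism(cfg_on, 11), "free")
  cfg_off <- assembly_config("invasion", mutualism = "switch_off",
                             switch_at = 10, n_events = 20)
  expect_identical(ecoassembly:::effective_mutualism(cfg_off, 5), "free")
  expect_identical(ecoassembly:::effective_mutualism(cfg_off, 11), "none")

  # before the switch-on point the run carries no mutualisms at all
  run <- run_assembly(assembly_config("invasion", mutualism = "switch_on",
                                      switch_at = 8, n_events = 12, seed = 3,
                                      params = glv_params(t_max = 2000)))
  expect_true(all(run$trajectory$prop_mut[run$trajectory$event <= 8] == 0))
})
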