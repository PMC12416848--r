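test_that("presets carry the reference parameter values field-for-field", {
  pre <- scenario_preset("Evo")
  cfg <- pre$config
  expect_identical(cfg$scenario, "evolution")
  expect_equal(cfg$sigma, 0.2)
  expect_equal(cfg$params$delta, 0.01)
  expect_identical(cfg$delta_mut, 5L)
  expect_equal(cfg$params$h_m, 0.1)
  expect_equal(cfg$params$h_p, 0.1)
  expect_equal(cfg$params$x_ext, 1e-6)
  expect_equal(cfg$params$eq_rel_tol, 1e-4)   # 0.01% relative change
  expect_equal(cfg$rho1, 0.05)
  expect_equal(cfg$rho2, 0.5)
  expect_identical(cfg$n_init, 5L)
  expect_equal(cfg$init_abund_hi, 0.02)
  expect_identical(cfg$n_events, 1000L)
  expect_identical(cfg$disconnect_removal_after, 20L)
  expect_identical(pre$n_replicates, 15L)
  expect_identical(pre$record_every, 50L)
  expect_equal(cfg$mu_r, 0.1)

  inv <- scenario_preset("Inv")$config
  expect_identical(inv$scenario, "invasion")
  expect_identical(scenario_preset("Inv-No-M")$config$mutualism, "none")
  expect_identical(scenario_preset("Inv-High-M")$config$mutualism, "high")
  sw <- scenario_preset("Inv-switch-on")$config
  expect_identical(sw$mutualism, "switch_on")
  expect_identical(sw$switch_at, 500L)        # halfway through 1000 events
  expect_equal(scenario_preset("Mixed-0.2")$config$p_invasion, 0.2)
  expect_equal(scenario_preset("Mixed-0.8")$config$p_invasion, 0.8)
  expect_identical(scenario_preset("Evo-abundance-weighted")$config$parent_weighting,
                   "abundance")
  expect_identical(scenario_preset("fast-assembly")$config$event_timing,
                   "fixed_interval")
  expect_error(scenario_preset("nope"), "unknown preset")
})

test_that("scenario aggregation reports means and standard errors by stride", {
  pre <- scenario_preset("Evo", n_events = 10, n_replicates = 2,
                         record_every = 5, seed = 5,
                         params = glv_params(t_max = 2000))
  res <- run_scenario(pre)
  agg <- tidy(res)
  # 2 strides x 7 metrics
  expect_identical(nrow(agg), 14L)
  expect_setequal(unique(agg$event), c(5, 10))

  # SE matches a direct recomputation from the raw trajectories
  raw <- res$trajectories
  s10 <- raw$S[raw$event == 10]
  row <- agg[agg$event == 10 & agg$metric == "S", ]
  expect_equal(row$mean, mean(s10))
  expect_equal(row$se, sd(s10) / sqrt(2))

  # a single replicate has zero standard error everywhere
  pre1 <- scenario_preset("Evo", n_events = 10, n_replicates = 1,
                          record_every = 5, seed = 5,
                          params = glv_params(t_max = 2000))
  res1 <- run_scenario(pre1)
  expect_true(all(tidy(res1)$se == 0))

  # identical preset + seeds give identical aggregates
  res_again <- run_scenario(pre)
  expect_identical(tidy(res_again), agg)

  # final-state scatter: one row per replicate
  fs <- final_state_scatter(res)
  expect_identical(nrow(fs), 2L)
  expect_identical(fs$scenario, rep("Evo", 2))
  expect_identical(fs$S, vapply(res$runs,
                                function(r) n_species(r$community),
                                integer(1)))
})

test_that("replicate seeds spawn deterministically from the master seed", {
  expect_identical(spawn_seeds(42, 5), spawn_seeds(42, 5))
  expect_false(identical(spawn_seeds(42, 5), spawn_seeds(43, 5)))
  expect_true(all(spawn_seeds(1, 100) <= 1e8))
})

test_that("fixed-interval assembly proceeds without waiting for equilibrium", {
  cfg <- assembly_config("evolution", n_events = 8, seed = 13,
                         event_timing = "fixed_interval",
                         fixed_interval = 30,
                         params = glv_params(t_max = 2000))
  run <- run_assembly(cfg)
  expect_identical(nrow(run$trajectory), 8L)
  expect_silent(validate_community(run$community))
})
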