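test_that("a zero-duration run is a single resilient snapshot", {
  cfg <- scenario_config(n_cells = 10, duration = 0, seed = 1)
  traj <- run_simulation(cfg)
  expect_equal(nrow(traj$means), 1)
  expect_equal(traj$phenotypes$RESILIENT, 10)
  expect_equal(survival_curve(traj)$surviving_pct, 100)
})

test_that("identical configs give bitwise-identical trajectories", {
  cfg <- scenario_config(n_cells = 25, duration = 3, dt = 0.02, seed = 77)
  a <- run_simulation(cfg)
  b <- run_simulation(cfg)
  expect_identical(a$means, b$means)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$deaths, b$deaths)
  expect_identical(a$final_state, b$final_state)
})

test_that("without stressors nothing transitions and nothing dies", {
  # homogeneous cells: with parameter scatter a rare corner draw can sit below
  # the activity cutoff from birth even without stress
  cfg <- scenario_config(n_cells = 30, duration = 20, dt = 0.05, seed = 3,
                         heterogeneity_cv = 0)
  traj <- run_simulation(cfg, no_stress_params())
  expect_equal(nrow(traj$deaths), 0)
  expect_true(all(traj$phenotypes$RESILIENT == 30))
  expect_true(all(traj$means$ros < 1e-6))
})

test_that("population means are computed over living cells and stay bounded", {
  traj <- small_tau_run()
  acts <- as.matrix(traj$means[, signature_nodes()])
  expect_true(all(acts >= 0 & acts <= 1, na.rm = TRUE))
  expect_true(all(traj$means$n_alive + traj$phenotypes$DEAD == traj$config$n_cells))
})

test_that("replicate aggregation reduces to the single run and to zero spread", {
  cfg <- scenario_config(n_cells = 15, duration = 2, dt = 0.02, seed = 5,
                         n_replicates = 1)
  one <- run_replicates(cfg)
  single <- run_simulation(cfg)
  end <- dplyr::filter(one$survival, time == max(time))
  expect_equal(end$mean, glance(single)$survival_end)
  expect_equal(nrow(one$replicates), 1)

  # deterministic dynamics (no stressors, cv = 0) -> zero dispersion
  cfg2 <- scenario_config(n_cells = 10, duration = 2, dt = 0.02, seed = 5,
                          n_replicates = 3, heterogeneity_cv = 0)
  agg <- run_replicates(cfg2, no_stress_params())
  expect_true(all(agg$means$sd < 1e-12, na.rm = TRUE))
  expect_true(all(agg$survival$sd == 0))
  expect_warning(run_replicates(cfg2, no_stress_params(), seeds = c(1, 1)),
                 "duplicate")
})

test_that("replicate standard error shrinks roughly as 1/sqrt(n)", {
  # a stressed miniature population in which deaths start almost immediately
  p <- default_parameters()
  p <- set_param(p, "phenotype.ros_threshold", 1e-6)
  p <- set_param(p, "phenotype.tau_threshold", 1e-6)
  p <- set_param(p, "phenotype.death_hazard", 0.8)
  cfg <- scenario_config("custom",
                         node_scales = c(uprmt_hsp60 = 0.1, uprer_bip = 0.1),
                         n_cells = 40, duration = 2, dt = 0.05, seed = 0)
  surv <- vapply(1:64, function(s) {
    cfg$seed <- s
    glance(run_simulation(cfg, p))$survival_end
  }, numeric(1))
  expect_true(var(surv) > 0)
  set.seed(123)
  se_of_mean <- function(k) {
    sd(replicate(300, mean(sample(surv, k, replace = TRUE))))
  }
  ratio_4_16 <- se_of_mean(4) / se_of_mean(16)
  ratio_16_64 <- se_of_mean(16) / se_of_mean(64)
  expect_gt(ratio_4_16, 1.4); expect_lt(ratio_4_16, 2.9)
  expect_gt(ratio_16_64, 1.4); expect_lt(ratio_16_64, 2.9)
})

test_that("halving the step leaves day-20 means essentially unchanged", {
  # deterministic continuous part only (no sampling, no pool stochasticity)
  p <- set_param(default_parameters(), "mito.damage_rate", 1e-12)
  run_dt <- function(dt) {
    cfg <- scenario_config(n_cells = 4, duration = 20, dt = dt, seed = 9,
                           heterogeneity_cv = 0)
    r <- run_simulation(cfg, p)
    unlist(r$means[nrow(r$means), c("ros", "tau", signature_nodes())])
  }
  coarse <- run_dt(0.02)
  fine <- run_dt(0.01)
  expect_lt(max(abs(fine - coarse) / pmax(abs(fine), 1e-6)), 0.01)
})
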