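# minimal hand-built trajectory: two nodes' worth of structure on the full
# nine-node grid, enough to exercise the derived outputs exactly
toy_traj <- function(values_by_time) {
  times <- as.numeric(names(values_by_time))
  means <- dplyr::bind_rows(lapply(values_by_time, function(v) {
    tibble::as_tibble(as.list(setNames(v, signature_nodes())))
  }))
  means <- dplyr::bind_cols(tibble::tibble(time = times, ros = 0.1, tau = 0.1),
                            means,
                            tibble::tibble(damaged_fraction = 0, n_alive = 10))
  ph <- tibble::tibble(time = times, RESILIENT = 10, MT_COMPROMISED = 0,
                       ER_COMPROMISED = 0, DUAL_COMPROMISED = 0,
                       VULNERABLE = 0, DEAD = 0)
  structure(list(means = means, phenotypes = ph,
                 deaths = tibble::tibble(cell = integer(0), time = numeric(0)),
                 config = scenario_config(n_cells = 10, duration = max(times)),
                 seed = 1L),
            class = "population_trajectory")
}

test_that("fold changes are normalised to the reference day", {
  tr <- toy_traj(list(`0` = rep(0.30, 9), `6` = rep(0.60, 9), `11` = rep(0.15, 9)))
  sig <- fold_change_signature(tr)
  expect_equal(unique(sig$fold_change[sig$time == 0]), 1)
  expect_equal(unique(sig$fold_change[sig$time == 6]), 2)
  expect_equal(unique(sig$fold_change[sig$time == 11]), 0.5)
  ms <- attr(sig, "milestones")
  expect_equal(unname(ms$fold_change[ms$group == "mid"]), rep(2, 9))
  expect_equal(unname(ms$fold_change[ms$group == "late"]), rep(0.5, 9))

  const <- toy_traj(list(`0` = rep(0.4, 9), `1` = rep(0.4, 9)))
  expect_true(all(fold_change_signature(const)$fold_change == 1))
})

test_that("fold changes are scale-free and zero references are rejected", {
  tr <- toy_traj(list(`0` = seq(0.1, 0.9, length.out = 9),
                      `6` = seq(0.2, 0.95, length.out = 9),
                      `11` = seq(0.05, 0.5, length.out = 9)))
  sig1 <- fold_change_signature(tr)
  tr2 <- tr
  tr2$means[signature_nodes()] <- sweep(as.matrix(tr$means[signature_nodes()]),
                                        2, runif(9, 0.5, 2), `*`)
  sig2 <- fold_change_signature(tr2)
  expect_equal(sig1$fold_change, sig2$fold_change)

  tr_bad <- toy_traj(list(`0` = c(0, rep(0.5, 8)), `6` = rep(0.5, 9)))
  expect_error(fold_change_signature(tr_bad), "uprmt_hsp60")
  expect_error(fold_change_signature(tr, t_ref = 3.14), "time grid")
})

test_that("phenotype fractions and survival are conserved and monotone", {
  traj <- small_tau_run()
  pf <- phenotype_fractions(traj)
  sums <- tapply(pf$fraction, pf$time, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  dead <- pf$fraction[pf$state == "DEAD"]
  expect_true(all(diff(dead) >= 0))
  expect_equal(pf$fraction[pf$time == 0 & pf$state == "RESILIENT"], 1)

  sc <- survival_curve(traj)
  expect_equal(sc$surviving_pct[1], 100)
  expect_true(all(diff(sc$surviving_pct) <= 0))
  expect_equal(sc$surviving_pct, 100 - 100 * dead)
})

test_that("nematode days extrapolate linearly to human years", {
  expect_identical(extrapolate_to_human_years(12), 60)
  expect_identical(extrapolate_to_human_years(19), 95)
  expect_identical(extrapolate_to_human_years(20), 100)
  a <- runif(1, 0, 10); b <- runif(1, 0, 10)
  expect_equal(extrapolate_to_human_years(a + b),
               extrapolate_to_human_years(a) + extrapolate_to_human_years(b))
  expect_error(extrapolate_to_human_years(-1), "invalid")
  expect_error(extrapolate_to_human_years(5, lifespan_days = 0), "> 0")
})

test_that("identity-line R2 matches the closed form", {
  sim <- tibble::tibble(node = rep(c("a", "b", "c", "d"), 2),
                        group = rep(c("mid", "late"), each = 4),
                        fold_change = c(1.0, 1.5, 2.0, 0.5, 1.2, 0.8, 2.5, 0.4))
  exper <- sim
  exper$fold_change <- c(1.1, 1.4, 2.2, 0.6, 1.0, 1.0, 2.2, 0.5)
  out <- correlation_r2(sim, exper)
  for (g in c("mid", "late")) {
    x <- sim$fold_change[sim$group == g]
    y <- exper$fold_change[exper$group == g]
    r2 <- 1 - sum((y - x)^2) / sum((y - mean(y))^2)
    expect_equal(out$r_squared[out$group == g], r2, tolerance = 1e-12)
  }
  # perfect agreement and degenerate experimental variance
  perfect <- correlation_r2(sim, sim)
  expect_true(all(perfect$r_squared == 1))
  flat <- sim; flat$fold_change <- 1
  out_flat <- correlation_r2(sim, flat)
  expect_true(all(out_flat$degenerate))
  expect_true(all(is.na(out_flat$r_squared)))

  # ordinary least squares variant agrees with lm()
  ols <- correlation_r2(sim, exper, method = "ols")
  g <- "mid"
  d <- data.frame(sim = sim$fold_change[sim$group == g],
                  exp = exper$fold_change[exper$group == g])
  expect_equal(ols$r_squared[ols$group == g], summary(lm(exp ~ sim, d))$r.squared)

  expect_error(correlation_r2(sim[1:2, ], exper[1:2, ]), "fewer than 3")
})
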