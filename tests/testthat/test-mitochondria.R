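test_that("pools are immune to damage without ROS and to events without rates", {
  p <- default_parameters()
  pool <- mito_pool(n_cells = 50)
  set.seed(1)
  cur <- pool
  for (i in 1:50) cur <- step_mitochondria(cur, ros = 0, pink1 = 0.5, bec1 = 0.5,
                                           biogenesis_capacity = 1, dt = 0.1, p)
  expect_true(all(cur$n_damaged == 0))

  p0 <- set_param(set_param(p, "mito.damage_rate", 1e-12), "mito.mitophagy_rate", 1e-12)
  pool2 <- mito_pool(n_cells = 20, n_healthy = 60, n_damaged = 30)
  set.seed(2)
  stepped <- pool2
  for (i in 1:20) stepped <- step_mitochondria(stepped, 1, 1, 1, 1, 0.1, p0)
  expect_equal(stepped$n_healthy, pool2$n_healthy)
  expect_equal(stepped$n_damaged, pool2$n_damaged)

  expect_identical(step_mitochondria(pool2, 1, 1, 1, 1, dt = 0, p), pool2)
})

test_that("pure damage matches its closed-form expectation", {
  p <- default_parameters()
  p <- set_param(p, "mito.mitophagy_rate", 1e-12)
  ros <- 2
  n_steps <- 40
  dt <- 0.1
  # UPR modulation neutralised so the hazard is exactly damage_rate * hill(ros)
  rate <- get_param(p, "mito.damage_rate") *
    (1 - get_param(p, "mito.uprmt_protection")) *
    hill(ros, get_param(p, "mito.damage_K"), get_param(p, "mito.damage_n"))
  expected <- 1 - exp(-rate * n_steps * dt)

  set.seed(33)
  pool <- mito_pool(n_cells = 1000)
  for (i in seq_len(n_steps)) {
    pool <- step_mitochondria(pool, ros, pink1 = 0, bec1 = 0,
                              biogenesis_capacity = 0, dt = dt, p)
  }
  fd <- damaged_fraction(pool)
  se <- sqrt(expected * (1 - expected) / (1000 * 100))
  expect_lt(abs(mean(fd) - expected), 3 * se + 1e-4)
})

test_that("pool invariants hold across many random steps", {
  p <- default_parameters()
  set.seed(44)
  pool <- mito_pool(n_cells = 1000, n_healthy = 70, n_damaged = 20)
  for (i in 1:100) {
    pool <- step_mitochondria(pool, ros = runif(1, 0, 2), pink1 = runif(1),
                              bec1 = runif(1), biogenesis_capacity = runif(1),
                              dt = runif(1, 0.01, 0.1), p,
                              uprmt = runif(1), uprer = runif(1))
    expect_true(all(pool$n_healthy >= 0 & pool$n_damaged >= 0))
    expect_true(all(pool$n_healthy + pool$n_damaged <= pool$capacity))
  }
})

test_that("maximal mitophagy without damage shrinks the damaged fraction", {
  p <- set_param(default_parameters(), "mito.damage_rate", 1e-12)
  set.seed(55)
  pool <- mito_pool(n_cells = 500, n_healthy = 50, n_damaged = 50)
  f0 <- mean(damaged_fraction(pool))
  for (i in 1:10) pool <- step_mitochondria(pool, 0, 1, 1, 1, 0.2, p)
  expect_lt(mean(damaged_fraction(pool)), f0)
})

test_that("damaged_fraction handles boundaries and empty pools", {
  expect_equal(damaged_fraction(mito_pool(1, n_healthy = 100, n_damaged = 0)), 0)
  expect_equal(damaged_fraction(mito_pool(1, capacity = 40, n_healthy = 0,
                                          n_damaged = 40)), 1)
  expect_equal(damaged_fraction(mito_pool(1, n_healthy = 75, n_damaged = 25)), 0.25)
  empty <- mito_pool(1, n_healthy = 0, n_damaged = 0)
  expect_message(f <- damaged_fraction(empty), "fully failed")
  expect_equal(f, 1)
})

test_that("seeded pool trajectories are bitwise reproducible", {
  p <- default_parameters()
  run <- function() {
    set.seed(99)
    pool <- mito_pool(n_cells = 30)
    for (i in 1:30) pool <- step_mitochondria(pool, 1, 0.5, 0.5, 0.8, 0.05, p)
    pool
  }
  expect_identical(run(), run())
})
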