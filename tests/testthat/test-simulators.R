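cfg <- fast_config()
env <- make_environment(cfg)
ac <- function(chi = 0, rho = 0, a_br = 10, c_br = 0.2) {
  model_params("ac", chi = chi, rho = rho, a_br = a_br, c_br = c_br)
}

test_that("AC move probabilities form a probability vector and respect bias", {
  tip <- list(position = c(0.5, 0.5))
  # unbiased: all four moves equal
  p0 <- ac_move_probabilities(tip, env, ac(0, 0), cfg)
  expect_equal(sum(p0), 1, tolerance = 1e-12)
  expect_equal(unname(p0["P1"]), unname(p0["P2"]))
  expect_equal(unname(p0["P3"]), unname(p0["P4"]))
  expect_equal(unname(p0["P1"]), unname(p0["P3"]))
  # chemotaxis up a linear-in-y VEGF field: up beats down, monotonically in chi
  gaps <- vapply(seq(0.1, 1, by = 0.1), function(chi) {
    p <- ac_move_probabilities(tip, env, ac(chi = chi), cfg)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    unname(p["P3"] - p["P4"])
  }, numeric(1))
  expect_true(all(gaps > 0))
  expect_true(all(diff(gaps) >= -1e-12))
  # normalization holds across random sites and parameters
  set.seed(4)
  for (i in 1:50) {
    tipr <- list(position = runif(2))
    p <- ac_move_probabilities(tipr, env,
                               ac(chi = runif(1, 0, 3), rho = runif(1, 0, 3)),
                               cfg)
    expect_true(all(p >= 0) && all(p <= 1))
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
})

test_that("AC moves off the lattice get zero probability", {
  p <- ac_move_probabilities(list(position = c(0, 0)), env, ac(), cfg)
  expect_equal(unname(p["P2"]), 0)  # left, off-lattice
  expect_equal(unname(p["P4"]), 0)  # down, off-lattice
  expect_equal(sum(p), 1, tolerance = 1e-12)
})

test_that("SL velocity decays under pure drag and drifts up with chemotaxis", {
  sl <- function(kappa, sigma) {
    model_params("sl", kappa = kappa, sigma = sigma, a_br = 10, c_br = 0.2)
  }
  # kappa = sigma = 0: deterministic relaxation of |w| towards 0
  tip <- list(position = c(0.5, 0.1), velocity = c(0.03, 0.02))
  norms <- numeric(20)
  set.seed(1)
  for (i in 1:20) {
    tip <- sl_velocity_step(tip, env, sl(0, 0), cfg)
    norms[i] <- sqrt(sum(tip$velocity^2))
  }
  expect_true(all(diff(c(sqrt(0.03^2 + 0.02^2), norms)) < 0))
  # kappa = 0, sigma > 0, zero gradient: stationary mean velocity is 0
  flat <- env
  flat$vegf[] <- 0.5
  flat$gradients <- angiotop:::field_gradient(flat$vegf, cfg)
  set.seed(2)
  tip <- list(position = c(0.5, 0.5), velocity = c(0, 0))
  v <- matrix(0, 10000, 2)
  for (i in 1:10000) {
    st <- angiotop:::sl_step_core(0.5, 0.5, tip$velocity[1], tip$velocity[2],
                                  flat$gradients, 0, 0.01, cfg, cfg$dt,
                                  rnorm(1), rnorm(1))
    tip$velocity <- c(st$vx, st$vy)
    v[i, ] <- tip$velocity
  }
  se <- apply(v, 2, sd) / sqrt(nrow(v) / 20)  # conservative (autocorrelated)
  expect_true(all(abs(colMeans(v)) < 3 * se))
  # kappa > 0, sigma = 0: vertical displacement positive and increasing in
  # kappa, matching the deterministic ODE integrated numerically
  disp <- vapply(c(0.005, 0.01, 0.02), function(kappa) {
    tip <- list(position = c(0.5, 0), velocity = c(0, 0))
    set.seed(3)
    for (i in 1:20) tip <- sl_velocity_step(tip, env, sl(kappa, 0), cfg)
    tip$position[2]
  }, numeric(1))
  expect_true(all(disp > 0))
  expect_true(all(diff(disp) > 0))
  # oracle: explicit Euler of dv/dt = -beta v + kappa, dy/dt = v
  kappa <- 0.01
  v <- 0
  y <- 0
  for (i in 1:20) {
    v <- v + (-cfg$control$sl_drag * v + kappa) * cfg$dt
    y <- y + v * cfg$dt
  }
  tip <- list(position = c(0.5, 0), velocity = c(0, 0))
  for (i in 1:20) tip <- sl_velocity_step(tip, env, sl(kappa, 0), cfg)
  expect_equal(tip$position[2], y, tolerance = 1e-10)
})

test_that("PS turning is symmetric without chemotaxis and conserves speed", {
  ps <- function(d_c, D_r = 0.2) {
    model_params("ps", d_c = d_c, D_r = D_r, a_br = 10, c_br = 0.2)
  }
  dphi <- cfg$control$ps_dphi
  for (phi in seq(-pi, pi, length.out = 25)) {
    r <- angiotop:::ps_turn_rates(phi, 0.2, 0, dphi, cfg$dt)
    expect_equal(r$plus, r$minus, tolerance = 1e-14)
  }
  # speed is constant across any step
  set.seed(5)
  tip <- list(position = c(0.5, 0.2), heading = 0.7, speed = cfg$h)
  for (i in 1:50) {
    before <- tip$position
    tip <- ps_turn_step(tip, env, ps(0.8), cfg)
    expect_equal(sqrt(sum((tip$position - before)^2)), cfg$h * cfg$dt,
                 tolerance = 1e-12)
    expect_equal(tip$speed, cfg$h)
  }
  # chemotactic bias: heading 90 degrees right of vertical, tumour-ward
  # (counter-clockwise) turns must dominate; binomial Monte Carlo against
  # the implemented rates
  phi_right <- -pi / 2
  r <- angiotop:::ps_turn_rates(phi_right, 0.25, 0.8, dphi, cfg$dt)
  expect_gt(r$plus, r$minus)
  set.seed(6)
  n <- 1e5
  u <- runif(n)
  left <- sum(u < r$plus)
  right <- sum(u >= r$plus & u < r$plus + r$minus)
  expect_gt(left - right, 3 * sqrt(left + right))
})

test_that("PS rejects time steps whose turn probabilities exceed one", {
  bad <- model_params("ps", d_c = 1, D_r = 0.3, a_br = 10, c_br = 0.2)
  expect_error(
    ps_turn_step(list(position = c(0.5, 0.5), heading = 0), env, bad, cfg,
                 dt = 5),
    "smaller dt"
  )
})

test_that("branching fires only in the age > a_br and c > c_br quadrant", {
  cfg1 <- fast_config()
  cfg1$control$branch_rate <- 1  # deterministic firing when eligible
  params <- model_params("ac", chi = 0, rho = 0, a_br = 10, c_br = 0.5)
  set.seed(7)
  for (age in c(5, 9.9, 10, 10.1, 20)) {
    for (yy in c(0.1, 0.49, 0.5, 0.51, 0.9)) {   # linear VEGF: c = y
      tip <- list(position = c(0.5, yy), age = age, lineage = 1L)
      daughter <- branch_check(tip, env, params, cfg1)
      should <- age > 10 && yy > 0.5
      expect_identical(!is.null(daughter), should)
      if (should) expect_equal(daughter$age, 0)
    }
  }
})

test_that("anastomosis needs a trail from a different lineage", {
  trail <- tibble::tibble(x = c(0.5, 0.52), y = c(0.5, 0.5), lineage = c(1L, 1L))
  tip_same <- list(position = c(0.5, 0.5), lineage = 1L)
  tip_other <- list(position = c(0.5, 0.5), lineage = 2L)
  expect_false(anastomosis_check(tip_same, trail, cfg))
  expect_true(anastomosis_check(tip_other, trail, cfg))
  expect_false(anastomosis_check(tip_other, trail[0, ], cfg))
  far <- list(position = c(0.9, 0.9), lineage = 2L)
  expect_false(anastomosis_check(far, trail, cfg))
})

test_that("simulations are exactly reproducible from their seed", {
  for (m in c("ac", "sl", "ps")) {
    p <- switch(m,
      ac = model_params("ac", chi = 1, rho = 0.3, a_br = 15, c_br = 0.2),
      sl = model_params("sl", kappa = 0.05, sigma = 0.02, a_br = 15, c_br = 0.2),
      ps = model_params("ps", d_c = 0.5, D_r = 0.1, a_br = 15, c_br = 0.2))
    s1 <- simulate_vessels(p, cfg, seed = 33)
    s2 <- simulate_vessels(p, cfg, seed = 33)
    expect_identical(s1$trail, s2$trail)
    expect_identical(glance(s1), glance(s2))
    s3 <- simulate_vessels(p, cfg, seed = 34)
    expect_false(identical(s1$trail, s3$trail))
  }
})

test_that("simulate_vessels does not disturb the caller's RNG stream", {
  set.seed(123)
  a <- runif(1)
  set.seed(123)
  invisible(simulate_vessels(ac(), cfg, seed = 1))
  b <- runif(1)
  expect_identical(a, b)
})

test_that("chemotaxis pushes the AC trail upward relative to unbiased walks", {
  mean_y <- function(chi) {
    vapply(1:30, function(s) {
      sim <- simulate_vessels(ac(chi = chi, a_br = 1000), cfg, seed = s)
      mean(sim$trail$y)
    }, numeric(1))
  }
  y0 <- mean_y(0)
  y2 <- mean_y(2)
  expect_gt(mean(y2), mean(y0))
  expect_gt(t.test(y2, y0)$statistic, 3)
})

test_that("trail geometry stays inside the domain for all models", {
  for (m in c("ac", "sl", "ps")) {
    p <- switch(m,
      ac = model_params("ac", chi = 2, rho = 1, a_br = 5, c_br = 0.1),
      sl = model_params("sl", kappa = 0.1, sigma = 0.05, a_br = 5, c_br = 0.1),
      ps = model_params("ps", d_c = 1, D_r = 0.3, a_br = 5, c_br = 0.1))
    sim <- simulate_vessels(p, cfg, seed = 2)
    expect_true(all(sim$trail$x >= 0 & sim$trail$x <= 1))
    expect_true(all(sim$trail$y >= 0 & sim$trail$y <= 1))
    expect_gte(sim$n_branches, 0)
    expect_gte(sim$n_anastomoses, 0)
  }
})
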